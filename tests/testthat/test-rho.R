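ref <- mt_reference()

test_that("clock filters keep exactly the clock-eligible mutations", {
  hvs <- clock_rate("hvs_transitions")
  expect_equal(hvs$years_per_mutation, 18845)
  expect_equal(hvs$window, c(16090L, 16365L))
  m <- parse_mutations("16183C 16051 16189 10398G 3571d", ref)
  # transversion excluded, transition outside window excluded
  expect_equal(filter_mutations_for_clock(m, hvs, ref)$token, "16189")
  comp <- clock_rate("complete_genome")
  expect_equal(comp$years_per_mutation, 2585)
  # all substitutions (incl. synonymous), no indels
  # note 10398G is a transition, so its canonical token is bare "10398"
  expect_setequal(filter_mutations_for_clock(m, comp, ref)$token,
                  c("16183C", "16051", "16189", "10398"))
  syn <- clock_rate("coding_synonymous")
  expect_equal(syn$years_per_mutation, 7884)
  msyn <- m[classify_mutation_function(m, ref) == "s", ]
  expect_equal(filter_mutations_for_clock(m, syn, ref)$token, msyn$token)
})

test_that("rho via tip paths equals the branch-weighted form", {
  # printed examples
  g3 <- genealogy_tree(parent = c(0, 1, 1, 1), lmut = c(0, 1, 0, 0))
  expect_equal(compute_rho(g3), 1 / 3)
  expect_equal(round_half_up(compute_rho(g3), 2), 0.33)
  g0 <- genealogy_tree(parent = c(0, 1, 1), lmut = c(0, 0, 0))
  expect_equal(compute_rho(g0), 0)
  # 16 tips with total path length 152 -> 9.50
  g16 <- genealogy_tree(parent = c(0, rep(1, 16)), lmut = c(0, rep(9.5, 16)))
  expect_equal(compute_rho(g16), 9.5)
  # equivalence on random topologies (property)
  for (s in 1:20) {
    g <- simulate_tree_genealogy(n_tips = sample(2:40, 1), rate = 2, seed = s)
    expect_equal(compute_rho(g, "tips"), compute_rho(g, "branches"))
  }
})

test_that("saillard sigma matches its closed forms", {
  g3 <- genealogy_tree(parent = c(0, 1, 1, 1), lmut = c(0, 1, 0, 0))
  expect_equal(saillard_sigma(g3), sqrt(1) / 3)
  # star of N tips each with l private mutations -> sqrt(N*l)/N
  for (N in c(4, 9)) for (l in c(1, 3)) {
    g <- genealogy_tree(parent = c(0, rep(1, N)), lmut = c(0, rep(l, N)))
    expect_equal(saillard_sigma(g), sqrt(N * l) / N)
  }
  # N=4, one internal branch (3 mutations, 2 tips below), no others
  g4 <- genealogy_tree(parent = c(0, 1, 2, 2, 1, 1),
                       lmut = c(0, 3, 0, 0, 0, 0))
  expect_equal(g4$n_tips, 4L)
  expect_equal(saillard_sigma(g4), sqrt(3 * 4) / 4)
})

test_that("rho-to-age conversion reproduces printed rows exactly", {
  comp <- clock_rate("complete_genome")
  syn <- clock_rate("coding_synonymous")
  expect_equal(rho_to_age(9.50, 1.47, comp)$age_kya, 24.56)
  expect_equal(rho_to_age(9.50, 1.47, comp)$age_sigma_kya, 3.80)
  expect_equal(rho_to_age(1.30, 0.56, syn)$age_kya, 10.25)
  expect_equal(rho_to_age(0, 0, comp)$age_kya, 0)
  expect_equal(rho_to_age(2.45, 2.45, comp)$age_sigma_kya, 6.33)
  expect_error(rho_to_age(-1, 0, comp), "negative")
})

test_that("date_haplogroup star fallback reproduces the 3-tip example", {
  tree <- load_haplogroup_tree(reference = ref)
  root <- variant_profile("root", c(1, 16569),
                          parse_mutations(path_motif(tree, "M55b"), ref), ref)
  tips <- fixture_sequences_for_haplogroup(tree, "M55b", n = 3, seed = 4,
                                           reference = ref)
  # add one private transition (clock-eligible) to one tip
  extra <- parse_mutations("11500", ref)
  tips[[1]]$mutations <- rbind(tips[[1]]$mutations, extra)
  est <- date_haplogroup(tips, root, clock_rate("complete_genome"), ref,
                         name = "M55b")
  expect_equal(est$N, 3L)
  expect_equal(est$rho, 1 / 3)
  expect_equal(round_half_up(est$rho, 2), 0.33)
  expect_equal(est$age_kya, 0.86)    # from full-precision rho, not 0.33
  expect_equal(est$age_sigma_kya, 0.86)
  # all tips identical to root -> age 0
  est0 <- date_haplogroup(fixture_sequences_for_haplogroup(
    tree, "M55b", n = 3, seed = 5, reference = ref), root,
    clock_rate("complete_genome"), ref)
  expect_equal(est0$age_kya, 0)
  # excluded mutations do not count toward the distance
  tips2 <- fixture_sequences_for_haplogroup(tree, "M55b", n = 2, seed = 6,
                                            reference = ref)
  tips2[[1]]$mutations <- rbind(tips2[[1]]$mutations,
                                parse_mutations("16519", ref))
  estx <- date_haplogroup(tips2, root, clock_rate("complete_genome"), ref)
  expect_equal(estx$rho, 0)
})

test_that("profiles without clock-eligible coverage are excluded with warning", {
  p_cr <- variant_profile("cr", c(16024, 407),
                          parse_mutations("16189", ref), ref)
  p_cod <- variant_profile("cod", c(3000, 4000),
                           parse_mutations(character(), ref), ref)
  expect_warning(
    est <- date_haplogroup(list(p_cr, p_cod), NULL,
                           clock_rate("hvs_transitions"), ref),
    "excluded")
  expect_equal(est$N, 1L)
  expect_equal(est$n_excluded, 1L)
})

test_that("genealogies round-trip through Newick with mutation counts", {
  g <- simulate_tree_genealogy(n_tips = 8, rate = 2, seed = 11)
  tf <- withr::local_tempfile(fileext = ".nwk")
  write_genealogy_newick(g, tf)
  g2 <- read_genealogy_newick(tf)
  expect_equal(g2$n_tips, g$n_tips)
  expect_equal(compute_rho(g2), compute_rho(g))
  expect_equal(saillard_sigma(g2), saillard_sigma(g))
})

test_that("every printed age is consistent with its rho under the stated rates", {
  # complete-genome and synonymous columns agree within +/-0.05 kya,
  # attributable to the table's rounding of rho (the HVS column does not,
  # see the acceptance suite)
  tab <- published_ages()
  comp <- clock_rate("complete_genome")
  syn <- clock_rate("coding_synonymous")
  for (i in seq_len(nrow(tab))) {
    a <- rho_to_age(tab$rho_c[i], tab$sig_c[i], comp)
    expect_lt(abs(a$age_kya - tab$age_c[i]), 0.05 + 1e-9, label = tab$hap[i])
    expect_lt(abs(a$age_sigma_kya - tab$agesig_c[i]), 0.05 + 1e-9,
              label = tab$hap[i])
    if (!is.na(tab$rho_s[i])) {
      b <- rho_to_age(tab$rho_s[i], tab$sig_s[i], syn)
      expect_lt(abs(b$age_kya - tab$age_s[i]), 0.05 + 1e-9, label = tab$hap[i])
      expect_lt(abs(b$age_sigma_kya - tab$agesig_s[i]), 0.05 + 1e-9,
                label = tab$hap[i])
    }
  }
})
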