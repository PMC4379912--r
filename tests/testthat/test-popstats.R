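ref <- mt_reference()

test_that("frequency tables normalise counts and keep the Unassigned column", {
  mk <- function(hg, anc) list(haplogroup = hg, ancestry = anc)
  asg <- c(replicate(3, mk("D4", "EastEurasian"), simplify = FALSE),
           replicate(2, mk("Unassigned", "Unassigned"), simplify = FALSE),
           replicate(5, mk("M45", "SouthAsian"), simplify = FALSE))
  ft <- build_frequency_table(asg, rep(c("P1", "P2"), each = 5))
  expect_true("Unassigned" %in% ft$haplogroups)
  expect_equal(sum(ft$counts), 10)
  expect_true(all(abs(rowSums(ft$freq) - 1) < 1e-9))
  expect_error(build_frequency_table(list(), character()), "no assignments")
  # one population, one haplogroup -> frequency 1
  ft1 <- build_frequency_table(list(mk("D4", "EastEurasian")), "P1")
  expect_equal(unname(ft1$freq[1, 1]), 1)
})

test_that("population CSV round-trips", {
  cnt <- rbind(P1 = c(a = 5L, b = 5L), P2 = c(a = 2L, b = 8L))
  ft <- frequency_table(cnt, lat = c(20, 22), lon = c(95, 97),
                        group = c("g1", "g2"))
  tf <- withr::local_tempfile(fileext = ".csv")
  write_population_csv(ft, tf)
  ft2 <- read_population_csv(tf)
  expect_equal(ft2$counts, ft$counts)
  expect_equal(ft2$lat, ft$lat)
  expect_equal(ft2$group, ft$group)
})

test_that("frequency PCA matches an eigen oracle and handles rank edge cases", {
  # identical populations: zero variance, defined output
  same <- frequency_table(rbind(P1 = c(5L, 5L), P2 = c(5L, 5L)))
  p0 <- pca_frequencies(same)
  expect_equal(sum(p0$percent_variance), 0)
  expect_equal(p0$scores[1, ], p0$scores[2, ])
  # variation along a single axis: PC1 explains 100%
  ax <- frequency_table(rbind(P1 = c(10L, 10L), P2 = c(15L, 5L),
                              P3 = c(5L, 15L)))
  p1 <- pca_frequencies(ax)
  expect_equal(p1$percent_variance[1], 100)
  # random 10 x 8 table vs independent eigen decomposition
  set.seed(8)
  cnt <- matrix(rpois(80, 20) + 1L, 10, 8)
  ft <- frequency_table(cnt)
  p <- pca_frequencies(ft)
  ev <- eigen(stats::cov(scale(ft$freq, center = TRUE, scale = FALSE)) *
                (nrow(cnt) - 1), symmetric = TRUE)$values
  expect_equal(p$percent_variance, 100 * ev / sum(ev), tolerance = 1e-8)
  expect_equal(sum(p$percent_variance), 100)
})

test_that("Nei dA has its closed-form values and metric-like properties", {
  ft <- frequency_table(rbind(P1 = c(5L, 5L, 0L), P2 = c(10L, 0L, 0L),
                              P3 = c(0L, 0L, 10L), P4 = c(5L, 5L, 0L)))
  expect_equal(nei_da(ft, "P1", "P4"), 0)
  expect_equal(nei_da(ft, "P2", "P3"), 1)          # disjoint support
  expect_equal(nei_da(ft, "P1", "P2"), 1 - sqrt(0.5))
  # symmetry and bounds over all pairs
  for (i in 1:4) for (j in 1:4) {
    expect_equal(nei_da(ft, i, j), nei_da(ft, j, i))
    expect_gte(nei_da(ft, i, j), 0 - 1e-12)
    expect_lte(nei_da(ft, i, j), 1)
  }
  expect_error(nei_da(ft, "P1", "nope"), "unknown")
})

test_that("AMOVA matches the brute-force oracle and its invariants", {
  # 3-population toy, 2 groups, hand-checkable counts
  cnt <- rbind(P1 = c(h1 = 4L, h2 = 1L, h3 = 0L),
               P2 = c(h1 = 1L, h2 = 4L, h3 = 0L),
               P3 = c(h1 = 0L, h2 = 1L, h3 = 4L))
  ft <- frequency_table(cnt, group = c("g1", "g1", "g2"))
  a <- amova(ft, permutations = 0, seed = 1)
  # oracle: explicit individuals, explicit distance matrix
  D2 <- (1 - diag(3))^2
  ind_hap <- rep(rep(1:3, times = 3), times = as.vector(t(cnt)))
  ind_pop <- rep(rep(rownames(cnt), each = 3), times = as.vector(t(cnt)))
  ss <- amova_ss_oracle(ind_hap, ind_pop,
                        c(P1 = "g1", P2 = "g1", P3 = "g2"), D2)
  expect_equal(unname(a$ssd[1:3]), unname(ss[1:3]), tolerance = 1e-9)
  expect_equal(unname(a$ssd["total"]), unname(ss["total"]), tolerance = 1e-9)
  # components sum to the total variance; percentages sum to 100
  expect_equal(sum(a$percent), 100, tolerance = 1e-6)
  # two groups fixed for different haplogroups -> Phi_ST = 1
  fix <- frequency_table(rbind(A1 = c(10L, 0L), A2 = c(10L, 0L),
                               B1 = c(0L, 10L), B2 = c(0L, 10L)),
                         group = c("g1", "g1", "g2", "g2"))
  af <- amova(fix, permutations = 49, seed = 2)
  expect_equal(unname(af$phi["PhiST"]), 1)
  expect_lte(af$p_values["PhiCT"], 1)
  # user-supplied distance matrix overrides the 0/1 default
  D <- matrix(c(0, 2, 2, 0), 2)
  ad <- amova(fix, permutations = 0, seed = 3, distance = D)
  expect_equal(unname(ad$phi["PhiST"]), 1)
  # doubling all distances scales the variance components by d^2 = 4
  a01 <- amova(fix, permutations = 0, seed = 3)
  expect_equal(sum(ad$components), 4 * sum(a01$components), tolerance = 1e-9)
  expect_error(amova(fix, permutations = 0, seed = 1,
                     grouping = c(A1 = "g1", A2 = "g1", B1 = "g1", B2 = "g1")),
               ">= 2 groups")
  expect_error(amova(ft, permutations = 10), "seed")
})

test_that("WLS admixture recovers mixtures and respects the simplex", {
  P <- cbind(A = c(0.7, 0.2, 0.1, 0), B = c(0, 0.1, 0.2, 0.7),
             C = c(0.25, 0.25, 0.25, 0.25))
  # hybrid equal to one parent
  wA <- wls_admixture(P[, "A"], P)
  expect_equal(unname(wA$proportions), c(1, 0, 0), tolerance = 1e-9)
  # exact two-way mixture
  h <- 0.3 * P[, "A"] + 0.7 * P[, "B"]
  w <- wls_admixture(h, P[, c("A", "B")])
  expect_equal(unname(w$proportions), c(0.3, 0.7), tolerance = 1e-9)
  expect_lt(w$rss, 1e-18)
  # exact three-way mixture
  h3 <- P %*% c(0.2, 0.5, 0.3)
  w3 <- wls_admixture(as.vector(h3), P)
  expect_equal(unname(w3$proportions), c(0.2, 0.5, 0.3), tolerance = 1e-9)
  # hybrid outside the hull: solution stays on the simplex boundary
  out <- wls_admixture(c(1, 0, 0, 0), P[, c("A", "B")])
  expect_equal(sum(out$proportions), 1)
  expect_true(all(out$proportions >= 0))
  expect_equal(unname(out$proportions["B"]), 0)
  # noisy mixture recovered within 0.05 (sigma = 0.01)
  set.seed(12)
  hn <- 0.5 * P[, "A"] + 0.5 * P[, "B"] + rnorm(4, 0, 0.01)
  wn <- wls_admixture(hn, P[, c("A", "B")])
  expect_lt(max(abs(wn$proportions - 0.5)), 0.05)
  # rank deficiency is flagged
  Pr <- cbind(A = c(0.5, 0.5), B = c(0.5, 0.5))
  expect_true(wls_admixture(c(0.5, 0.5), Pr)$non_unique)
  # weights change the objective
  ww <- wls_admixture(c(1, 0, 0, 0), P[, c("A", "B")], weights = c(10, 1, 1, 1))
  expect_true(all(ww$proportions >= 0) && abs(sum(ww$proportions) - 1) < 1e-12)
})
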