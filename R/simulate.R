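## Seeded synthetic-data generators emulating the study's data structures:
## star/tree genealogies with Poisson mutation counts, haplogroup-motif
## fixture sequences, and multi-population frequency tables with optional
## geographic clines.

EXCLUDED_SITES <- c(303:315, 515:522, 16182L, 16183L, 16193L, 16519L)

clock_eligible_positions <- function(clock, reference = mt_reference()) {
  key <- paste0("eligible_", clock$class)
  if (!is.null(.ref_cache[[key]])) return(.ref_cache[[key]])
  pos <- switch(clock$class,
    complete_genome = setdiff(seq_len(MT_LENGTH), EXCLUDED_SITES),
    hvs_transitions = setdiff(clock$window[1]:clock$window[2], EXCLUDED_SITES),
    coding_synonymous = {
      cand <- setdiff(577:16023, EXCLUDED_SITES)
      m <- new_mutations(cand, reference$bases[cand],
                        transition_partner(reference$bases[cand]), "transition")
      cand[classify_mutation_function(m, reference) == "s"]
    })
  .ref_cache[[key]] <- pos
  pos
}

#' Simulate a star genealogy with Poisson private mutations
#'
#' Each of `n_tips` tips receives `Poisson(lambda)` transitions at distinct
#' positions drawn uniformly from the clock-eligible sites (the standard
#' exclusion list is avoided). Deterministic under `seed`.
#'
#' @param n_tips number of tips.
#' @param lambda expected mutations per tip.
#' @param clock a [clock_rate()] determining eligible sites.
#' @param seed RNG seed (mandatory).
#' @param reference an [mt_reference()].
#' @param profiles logical; also build [variant_profile()]s (default TRUE;
#'   FALSE returns only the genealogy, for large simulation studies).
#' @return list with `genealogy` (a [genealogy_tree()]), `profiles` (list or
#'   NULL), `lambda`, `seed`.
#' @export
#' @examples
#' s <- simulate_star_genealogy(3, 0, seed = 1)
#' compute_rho(s$genealogy) # 0
simulate_star_genealogy <- function(n_tips, lambda,
                                    clock = clock_rate("complete_genome"),
                                    seed, reference = mt_reference(),
                                    profiles = TRUE) {
  if (missing(seed)) stop("seed is mandatory")
  if (lambda < 0) stop("lambda must be >= 0")
  eligible <- clock_eligible_positions(clock, reference)
  if (lambda > length(eligible) / 2)
    stop("lambda too large for the eligible site pool")
  set.seed(seed)
  counts <- stats::rpois(n_tips, lambda)
  pos_list <- lapply(counts, function(k)
    if (k == 0) integer() else sort(sample(eligible, k)))
  g <- genealogy_tree(parent = c(0L, rep(1L, n_tips)),
                      lmut = c(0, counts),
                      labels = c("root", paste0("tip", seq_len(n_tips))))
  prof <- NULL
  if (profiles) {
    prof <- lapply(seq_len(n_tips), function(i) {
      p <- pos_list[[i]]
      m <- if (length(p) == 0) empty_mutations() else
        new_mutations(p, reference$bases[p],
                      transition_partner(reference$bases[p]), "transition")
      variant_profile(paste0("tip", i), c(1L, MT_LENGTH), m, reference)
    })
  }
  list(genealogy = g, profiles = prof, lambda = lambda, seed = seed)
}

#' Simulate a random bifurcating (Yule-style) genealogy
#'
#' Topology grows by repeatedly splitting a uniformly chosen tip. Each
#' branch gets an exponential(1) duration `t_b`, an expected mutation count
#' `mu_b = rate * t_b`, and an observed count `l_b ~ Poisson(mu_b)`. The
#' expectations are stored so mutation counts can be re-drawn on the fixed
#' topology with [redraw_branch_mutations()].
#'
#' @param n_tips number of tips (>= 2).
#' @param rate expected mutations per unit branch duration.
#' @param seed RNG seed (mandatory).
#' @return a [genealogy_tree()] with an extra `mu` field.
#' @export
simulate_tree_genealogy <- function(n_tips, rate = 1, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (n_tips < 2) stop("need >= 2 tips")
  set.seed(seed)
  parent <- c(0L, 1L, 1L)
  tips <- c(2L, 3L)
  while (length(tips) < n_tips) {
    split_tip <- tips[sample.int(length(tips), 1)]
    id <- length(parent) + c(1L, 2L)
    parent <- c(parent, split_tip, split_tip)
    tips <- c(setdiff(tips, split_tip), id)
  }
  mu <- c(0, rate * stats::rexp(length(parent) - 1))
  lmut <- c(0, stats::rpois(length(parent) - 1, mu[-1]))
  g <- genealogy_tree(parent, lmut)
  g$mu <- mu
  g
}

#' @rdname simulate_tree_genealogy
#' @param g a genealogy from [simulate_tree_genealogy()].
#' @export
redraw_branch_mutations <- function(g, seed) {
  if (is.null(g$mu)) stop("genealogy carries no branch expectations")
  set.seed(seed)
  g$lmut <- c(0, stats::rpois(length(g$mu) - 1, g$mu[-1]))
  g
}

#' Simulate multi-population haplogroup frequency tables
#'
#' Per-population counts are multinomial draws from the supplied frequency
#' profile(s); an optional linear cline tilts one haplogroup's expected
#' frequency along longitude. Populations are placed on an equally spaced
#' west-to-east transect unless coordinates are given.
#'
#' @param n_pops number of populations.
#' @param n_per_pop sample size per population (recycled).
#' @param profile baseline haplogroup frequency vector (a simplex point), or
#'   a matrix with one row per population.
#' @param cline_slope total change in the clined haplogroup's expected
#'   frequency from the western to the eastern end (default 0).
#' @param cline_haplogroup index of the clined haplogroup (default 1).
#' @param lat,lon optional coordinates (default: lat 20, lon spaced 92-102).
#' @param group optional group labels.
#' @param seed RNG seed (mandatory).
#' @return a [frequency_table()].
#' @export
simulate_population_frequencies <- function(n_pops, n_per_pop, profile,
                                            cline_slope = 0,
                                            cline_haplogroup = 1,
                                            lat = NULL, lon = NULL,
                                            group = NULL, seed) {
  if (missing(seed)) stop("seed is mandatory")
  prof <- if (is.matrix(profile)) profile else
    matrix(profile, n_pops, length(profile), byrow = TRUE)
  if (nrow(prof) != n_pops) stop("profile dimension mismatch")
  if (any(prof < 0) || any(abs(rowSums(prof) - 1) > 1e-8))
    stop("profiles must be simplex points")
  n_per_pop <- rep_len(n_per_pop, n_pops)
  lon <- lon %||% seq(92, 102, length.out = n_pops)
  lat <- lat %||% rep(20, n_pops)
  set.seed(seed)
  if (cline_slope != 0) {
    t <- (lon - min(lon)) / max(1e-12, diff(range(lon)))
    for (i in seq_len(n_pops)) {
      p <- prof[i, ]
      target <- min(0.99, max(0.01, p[cline_haplogroup] +
                                cline_slope * (t[i] - 0.5)))
      rest <- sum(p[-cline_haplogroup])
      p[-cline_haplogroup] <- p[-cline_haplogroup] *
        (1 - target) / ifelse(rest == 0, 1, rest)
      p[cline_haplogroup] <- target
      prof[i, ] <- p / sum(p)
    }
  }
  counts <- t(vapply(seq_len(n_pops), function(i)
    as.integer(stats::rmultinom(1, n_per_pop[i], prof[i, ])),
    integer(ncol(prof))))
  rownames(counts) <- paste0("pop", seq_len(n_pops))
  colnames(counts) <- colnames(prof) %||% paste0("hg", seq_len(ncol(prof)))
  frequency_table(counts, lat = lat, lon = lon, group = group)
}

#' Generate fixture sequences carrying a clade's cumulative motif
#'
#' Each profile carries the cumulative motif of `name` plus
#' `Poisson(mean_private)` private transitions at positions away from every
#' defining site of the whole tree (and the standard exclusion list), so
#' round-trip classification is unambiguous.
#'
#' @param tree a [load_haplogroup_tree()] tree.
#' @param name clade name.
#' @param n number of profiles.
#' @param mean_private expected private mutations per profile.
#' @param seed RNG seed (mandatory).
#' @param reference an [mt_reference()].
#' @param covered covered intervals for the profiles (default full genome).
#' @return list of [variant_profile()]s.
#' @export
fixture_sequences_for_haplogroup <- function(tree, name, n = 1,
                                             mean_private = 0, seed,
                                             reference = mt_reference(),
                                             covered = c(1L, MT_LENGTH)) {
  if (missing(seed)) stop("seed is mandatory")
  if (!name %in% tree$nodes$Name) stop("unknown clade: ", name)
  motif <- parse_mutations(path_motif(tree, name), reference)
  defining <- unique(unlist(lapply(tree$nodes$Name, function(nm) {
    toks <- tree$motifs[[nm]]
    if (length(toks) == 0) return(integer())
    parse_mutations(toks, reference)$position
  })))
  pool <- setdiff(covered_positions(covered), c(defining, EXCLUDED_SITES))
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    k <- stats::rpois(1, mean_private)
    m <- motif
    if (k > 0) {
      p <- sort(sample(pool, k))
      m <- rbind(m, new_mutations(p, reference$bases[p],
                                  transition_partner(reference$bases[p]),
                                  "transition"))
    }
    m <- m[order(m$position, m$insertion_index), , drop = FALSE]
    rownames(m) <- NULL
    variant_profile(paste0(name, "_", i), covered, m, reference)
  })
}
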