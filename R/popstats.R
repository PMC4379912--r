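## Haplogroup frequency tables and population-level statistics: PCA, Nei dA,
## hierarchical AMOVA with Phi statistics, WLS admixture.

#' Construct a population x haplogroup frequency table
#'
#' @param counts integer matrix, populations x haplogroups (dimnames
#'   required).
#' @param lat,lon optional per-population coordinates (decimal degrees).
#' @param group optional per-population group labels (for AMOVA).
#' @param language optional per-population language-family labels.
#' @return object of class `frequency_table`: `counts`, `freq` (rows sum to
#'   1), `n`, `populations`, `haplogroups`, `lat`, `lon`, `group`,
#'   `language`.
#' @export
frequency_table <- function(counts, lat = NULL, lon = NULL, group = NULL,
                            language = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("pop", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("hg", seq_len(ncol(counts)))
  n <- rowSums(counts)
  if (any(n == 0)) stop("population with zero individuals")
  if (!is.null(lat) && any(lat < -90 | lat > 90)) stop("latitude out of range")
  if (!is.null(lon) && any(lon < -180 | lon > 180)) stop("longitude out of range")
  structure(list(counts = counts, freq = counts / n, n = n,
                 populations = rownames(counts),
                 haplogroups = colnames(counts),
                 lat = lat, lon = lon, group = group, language = language),
            class = "frequency_table")
}

#' @export
print.frequency_table <- function(x, ...) {
  cat("frequency_table: ", nrow(x$counts), " populations x ",
      ncol(x$counts), " haplogroups, n = ", sum(x$n), "\n", sep = "")
  invisible(x)
}

#' Build a frequency table from haplogroup assignments
#'
#' Unassigned samples form an explicit `"Unassigned"` column.
#'
#' @param assignments list of [assign_haplogroup()] results.
#' @param populations character vector of population labels, one per
#'   assignment.
#' @param ... passed to [frequency_table()] (lat, lon, group, language).
#' @return a [frequency_table()].
#' @export
build_frequency_table <- function(assignments, populations, ...) {
  if (length(assignments) == 0) stop("no assignments")
  if (length(populations) != length(assignments))
    stop("one population label per assignment required")
  hg <- vapply(assignments, function(a) a$haplogroup, "")
  tab <- table(factor(populations, levels = unique(populations)),
               factor(hg, levels = unique(hg)))
  frequency_table(unclass(as.matrix(tab)), ...)
}

#' Read / write the population CSV dialect
#'
#' Columns: `Population, Group, Lat, Lon, n`, then one count column per
#' haplogroup.
#'
#' @param path file path.
#' @return `read_population_csv`: a [frequency_table()].
#' @export
read_population_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  fixed <- c("Population", "Group", "Lat", "Lon", "n")
  if (!all(fixed %in% names(d)))
    stop("population CSV needs columns ", paste(fixed, collapse = ", "))
  hg <- setdiff(names(d), fixed)
  counts <- as.matrix(d[, hg, drop = FALSE])
  rownames(counts) <- d$Population
  if (any(abs(rowSums(counts) - d$n) > 0))
    stop("count columns do not sum to n")
  frequency_table(counts, lat = d$Lat, lon = d$Lon, group = d$Group)
}

#' @rdname read_population_csv
#' @param ft a [frequency_table()].
#' @export
write_population_csv <- function(ft, path) {
  d <- data.frame(Population = ft$populations,
                  Group = ft$group %||% "",
                  Lat = ft$lat %||% NA, Lon = ft$lon %||% NA,
                  n = ft$n, check.names = FALSE)
  d <- cbind(d, as.data.frame(ft$counts, check.names = FALSE))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' PCA on haplogroup frequencies
#'
#' Column-mean-centred (uncentred scale: frequencies share a unit) singular
#' value decomposition. Percent variance per component is `lambda_i /
#' sum(lambda)`; loadings are the haplogroup contributions.
#'
#' @param ft a [frequency_table()] (>= 2 populations).
#' @param n_components number of components to return (default all).
#' @param scale. logical; standardise columns (correlation mode), default
#'   `FALSE`.
#' @return list with `scores`, `loadings`, `percent_variance` (sums to 100,
#'   over all components), `sdev`.
#' @export
pca_frequencies <- function(ft, n_components = NULL, scale. = FALSE) {
  x <- ft$freq
  if (nrow(x) < 2) stop("need at least 2 populations")
  xc <- scale(x, center = TRUE, scale = scale.)
  if (scale.) xc[, attr(xc, "scaled:scale") == 0] <- 0
  s <- svd(xc)
  lambda <- s$d^2
  pct <- if (sum(lambda) == 0) rep(0, length(lambda)) else 100 * lambda / sum(lambda)
  k <- min(n_components %||% length(lambda), length(lambda))
  scores <- s$u %*% diag(s$d, length(s$d))
  rownames(scores) <- ft$populations
  rownames(s$v) <- ft$haplogroups
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  list(scores = scores[, seq_len(k), drop = FALSE],
       loadings = s$v[, seq_len(k), drop = FALSE],
       percent_variance = pct,
       sdev = s$d / sqrt(max(1, nrow(x) - 1)))
}

#' Nei's dA distance between two populations
#'
#' Single-locus, Bhattacharyya-type form on the haplogroup panel:
#' `dA = 1 - sum_h sqrt(x_h * y_h)`.
#'
#' @param ft a [frequency_table()].
#' @param popA,popB population names or indices.
#' @return distance in `[0, 1]`.
#' @export
#' @examples
#' # x=(0.5,0.5,0), y=(1,0,0) -> 1 - sqrt(0.5)
nei_da <- function(ft, popA, popB) {
  if (is.character(popA)) popA <- match(popA, ft$populations)
  if (is.character(popB)) popB <- match(popB, ft$populations)
  if (anyNA(c(popA, popB))) stop("unknown population")
  1 - sum(sqrt(ft$freq[popA, ] * ft$freq[popB, ]))
}

## ---- AMOVA -----------------------------------------------------------------

# Sum over unordered pairs within one set of d^2, divided by set size:
# with haplogroup count vector c and squared-distance matrix D2 this is
# c' D2 c / (2 n).
.ss_from_counts <- function(cnt, D2) {
  n <- sum(cnt)
  as.numeric(cnt %*% D2 %*% cnt) / (2 * n)
}

.amova_phi <- function(hap, pop, grp_of_pop, D2) {
  pops <- names(grp_of_pop)
  P <- length(pops); G <- length(unique(grp_of_pop)); N <- length(hap)
  H <- nrow(D2)
  cnt_pop <- vapply(pops, function(p) as.numeric(tabulate(hap[pop == p], H)),
                    numeric(H))
  n_p <- colSums(cnt_pop)
  grp_levels <- unique(grp_of_pop)
  cnt_grp <- vapply(grp_levels, function(g)
    rowSums(cnt_pop[, grp_of_pop == g, drop = FALSE]), numeric(H))
  n_g <- colSums(cnt_grp)
  cnt_tot <- rowSums(cnt_pop)
  ss_tot <- .ss_from_counts(cnt_tot, D2)
  ss_wp <- sum(vapply(seq_len(P), function(i) .ss_from_counts(cnt_pop[, i], D2), 0))
  ss_wg <- sum(vapply(seq_along(grp_levels), function(i)
    .ss_from_counts(cnt_grp[, i], D2), 0))
  ssd_ag <- ss_tot - ss_wg
  ssd_ap <- ss_wg - ss_wp
  ssd_wp <- ss_wp
  df_ag <- G - 1; df_ap <- P - G; df_wp <- N - P
  ms_ag <- ssd_ag / df_ag
  ms_ap <- if (df_ap > 0) ssd_ap / df_ap else 0
  ms_wp <- ssd_wp / df_wp
  sum_npg <- sum(vapply(grp_levels, function(g) {
    sel <- grp_of_pop == g
    sum(n_p[sel]^2) / sum(n_p[sel])
  }, 0))
  n1 <- if (df_ap > 0) (N - sum_npg) / df_ap else 1
  n2 <- (sum_npg - sum(n_p^2) / N) / df_ag
  n3 <- (N - sum(n_g^2) / N) / df_ag
  sig_c <- ms_wp
  sig_b <- if (df_ap > 0) (ms_ap - sig_c) / n1 else 0
  sig_a <- (ms_ag - sig_c - n2 * sig_b) / n3
  tot <- sig_a + sig_b + sig_c
  list(sigma = c(among_groups = sig_a, among_pops_within_groups = sig_b,
                 within_pops = sig_c),
       ssd = c(among_groups = ssd_ag, among_pops_within_groups = ssd_ap,
               within_pops = ssd_wp, total = ss_tot),
       df = c(df_ag, df_ap, df_wp),
       phi = c(PhiCT = if (tot == 0) 0 else sig_a / tot,
               PhiSC = if (sig_b + sig_c == 0) 0 else sig_b / (sig_b + sig_c),
               PhiST = if (tot == 0) 0 else (sig_a + sig_b) / tot))
}

#' Hierarchical AMOVA on haplogroup profiles
#'
#' Individuals carry a haplogroup each; the default distance between two
#' individuals is 0/1 (distinct haplogroups), overridable by a haplogroup x
#' haplogroup distance matrix. Variance components for among-groups,
#' among-populations-within-groups and within-populations follow the
#' standard sums-of-squares decomposition; significance is assessed by
#' permutation (populations across groups for Phi_CT, individuals across
#' populations within groups for Phi_SC, individuals across all populations
#' for Phi_ST).
#'
#' @param ft a [frequency_table()].
#' @param grouping named character vector mapping population name -> group
#'   (default `ft$group`).
#' @param permutations number of permutations (default 1000; 0 skips the
#'   tests).
#' @param seed RNG seed (mandatory for reproducibility).
#' @param distance optional haplogroup distance matrix (entries d, the
#'   decomposition uses d^2).
#' @param tests which Phi statistics to permutation-test (default all
#'   three); restricting saves time in large simulation studies.
#' @return object of class `amova_result`: `components` (variance
#'   components), `percent`, `phi`, `ssd`, `df`, `p_values`, `permutations`,
#'   `seed`.
#' @export
amova <- function(ft, grouping = NULL, permutations = 1000, seed,
                  distance = NULL, tests = c("PhiCT", "PhiSC", "PhiST")) {
  if (missing(seed)) stop("seed is mandatory")
  grouping <- grouping %||% stats::setNames(ft$group, ft$populations)
  if (is.null(grouping)) stop("no grouping supplied")
  grouping <- grouping[ft$populations]
  if (anyNA(grouping)) stop("grouping must cover every population")
  if (length(unique(grouping)) < 2) stop("need >= 2 groups")
  H <- length(ft$haplogroups)
  D <- distance %||% (1 - diag(H))
  D2 <- as.matrix(D)^2
  # individual-level encoding
  hap <- rep(rep(seq_len(H), times = nrow(ft$counts)), times = as.vector(t(ft$counts)))
  pop <- rep(rep(ft$populations, each = H), times = as.vector(t(ft$counts)))
  obs <- .amova_phi(hap, pop, grouping, D2)
  p_values <- c(PhiCT = NA_real_, PhiSC = NA_real_, PhiST = NA_real_)
  if (permutations > 0) {
    set.seed(seed)
    ge_ct <- ge_sc <- ge_st <- 0L
    for (b in seq_len(permutations)) {
      if ("PhiCT" %in% tests) {
        perm_grp <- stats::setNames(sample(grouping), names(grouping))
        ge_ct <- ge_ct + (.amova_phi(hap, pop, perm_grp, D2)$phi["PhiCT"] >=
                            obs$phi["PhiCT"] - 1e-12)
      }
      if ("PhiST" %in% tests) {
        perm_pop_st <- sample(pop)
        ge_st <- ge_st + (.amova_phi(hap, perm_pop_st, grouping, D2)$phi["PhiST"] >=
                            obs$phi["PhiST"] - 1e-12)
      }
      if ("PhiSC" %in% tests) {
        perm_pop_sc <- pop
        for (g in unique(grouping)) {
          sel <- grouping[pop] == g
          perm_pop_sc[sel] <- sample(pop[sel])
        }
        ge_sc <- ge_sc + (.amova_phi(hap, perm_pop_sc, grouping, D2)$phi["PhiSC"] >=
                            obs$phi["PhiSC"] - 1e-12)
      }
    }
    pp <- function(stat, ge) if (stat %in% tests)
      unname((ge + 1) / (permutations + 1)) else NA_real_
    p_values <- c(PhiCT = pp("PhiCT", ge_ct), PhiSC = pp("PhiSC", ge_sc),
                  PhiST = pp("PhiST", ge_st))
  }
  tot <- sum(obs$sigma)
  structure(list(components = obs$sigma,
                 percent = if (tot == 0) rep(0, 3) else 100 * obs$sigma / tot,
                 phi = obs$phi, ssd = obs$ssd, df = obs$df,
                 p_values = p_values, permutations = permutations,
                 seed = seed),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA (", x$permutations, " permutations):\n", sep = "")
  comp <- data.frame(component = names(x$components),
                     sigma2 = unname(x$components),
                     percent = unname(x$percent))
  print(comp, row.names = FALSE)
  cat(sprintf("PhiCT=%.4f (p=%.4g)  PhiSC=%.4f (p=%.4g)  PhiST=%.4f (p=%.4g)\n",
              x$phi["PhiCT"], x$p_values["PhiCT"], x$phi["PhiSC"],
              x$p_values["PhiSC"], x$phi["PhiST"], x$p_values["PhiST"]))
  invisible(x)
}

## ---- WLS admixture ---------------------------------------------------------

#' Weighted-least-squares admixture proportions
#'
#' Minimises `sum_h w_h (f_h - sum_p m_p f_ph)^2` subject to `sum m = 1`,
#' `m >= 0`. The equality constraint is enforced by substitution and
#' non-negativity by active-set clipping with renormalisation.
#'
#' @param hybrid hybrid population frequency vector (length = haplogroups).
#' @param parental haplogroup x parental-population frequency matrix.
#' @param weights per-haplogroup weights (default 1).
#' @return object of class `admixture_estimate`: `proportions` (named, sum
#'   to 1), `rss` (weighted residual sum of squares), `non_unique` flag.
#' @export
#' @examples
#' P <- cbind(A = c(0.8, 0.2, 0), B = c(0, 0.2, 0.8))
#' wls_admixture(0.3 * P[, 1] + 0.7 * P[, 2], P)$proportions
wls_admixture <- function(hybrid, parental, weights = NULL) {
  parental <- as.matrix(parental)
  K <- ncol(parental)
  if (K < 2) stop("need >= 2 parental populations")
  if (length(hybrid) != nrow(parental)) stop("haplogroup panels differ")
  w <- weights %||% rep(1, length(hybrid))
  if (is.null(colnames(parental))) colnames(parental) <- paste0("P", seq_len(K))
  non_unique <- qr(sweep(parental, 1, sqrt(w), "*"))$rank < K
  support <- seq_len(K)
  m <- rep(0, K)
  repeat {
    S <- length(support)
    if (S == 1) { m[] <- 0; m[support] <- 1; break }
    Ps <- parental[, support, drop = FALSE]
    # substitute m_S = 1 - sum(others)
    B <- Ps[, -S, drop = FALSE] - Ps[, S]
    y <- hybrid - Ps[, S]
    BW <- sweep(B, 1, w, "*")
    xtx <- crossprod(BW, B)
    xty <- crossprod(BW, y)
    sol <- tryCatch(solve(xtx, xty), error = function(e) {
      # singular normal equations: minimum-norm solution via the SVD
      sv <- svd(xtx)
      keep <- sv$d > max(sv$d) * 1e-12
      as.vector(sv$v[, keep, drop = FALSE] %*%
                  (crossprod(sv$u[, keep, drop = FALSE], xty) / sv$d[keep]))
    })
    ms <- c(sol, 1 - sum(sol))
    if (all(ms >= -1e-10)) {
      m[] <- 0
      m[support] <- pmax(ms, 0)
      m <- m / sum(m)
      break
    }
    drop_i <- support[which.min(ms)]
    support <- setdiff(support, drop_i)
  }
  fit <- as.vector(parental %*% m)
  structure(list(proportions = stats::setNames(m, colnames(parental)),
                 rss = sum(w * (hybrid - fit)^2),
                 non_unique = non_unique),
            class = "admixture_estimate")
}

#' @export
print.admixture_estimate <- function(x, ...) {
  cat("admixture proportions (rss ", format(x$rss, digits = 4),
      if (x$non_unique) ", non-unique" else "", "):\n", sep = "")
  print(round(x$proportions, 4))
  invisible(x)
}
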