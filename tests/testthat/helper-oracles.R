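# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# --- IUPAC motif matcher (regex-based, independent of Biostrings) -----------
IUPAC_RE <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
              S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
              D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")

iupac_occurrences <- function(motif, seq) {
  re <- paste(IUPAC_RE[strsplit(motif, "")[[1]]], collapse = "")
  starts <- integer()
  L <- nchar(motif)
  for (i in seq_len(nchar(seq) - L + 1))
    if (grepl(paste0("^", re), substr(seq, i, i + L - 1))) starts <- c(starts, i)
  starts
}

# --- all-pairs shortest paths (Floyd-Warshall) ------------------------------
floyd <- function(W) {
  n <- nrow(W)
  D <- W
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], "+"))
  D
}

# --- Dreyfus-Wagner minimum Steiner tree ------------------------------------
# D: all-pairs shortest-path matrix; terminals: node indices. Returns the
# minimum total length of a Steiner tree connecting the terminals.
steiner_min_length <- function(D, terminals) {
  q <- length(terminals)
  if (q <= 1) return(0)
  n <- nrow(D)
  n_sub <- bitwShiftL(1L, q)
  dp <- matrix(Inf, n_sub, n)
  for (i in seq_len(q)) dp[bitwShiftL(1L, i - 1L) + 1L, ] <- D[terminals[i], ]
  popcount <- vapply(0:(n_sub - 1L), function(m) sum(as.integer(intToBits(m))), 0)
  for (S in (0:(n_sub - 1L))[order(popcount)]) {
    if (popcount[S + 1L] < 2) next
    M <- rep(Inf, n)
    sub <- S
    repeat {
      sub <- bitwAnd(sub - 1L, S)
      if (sub == 0L) break
      other <- S - sub
      if (sub < other) next # each split once
      M <- pmin(M, dp[sub + 1L, ] + dp[other + 1L, ])
    }
    dp[S + 1L, ] <- apply(sweep(D, 1, M, "+"), 2, min)
  }
  min(dp[n_sub, ])
}

# Minimum Steiner length over the s-dimensional binary hypercube for a set
# of 0/1 terminal state vectors (rows).
hypercube_steiner <- function(states) {
  if (is.logical(states)) states <- states * 1L
  if (is.character(states)) states <- (states == "1") * 1L
  s <- ncol(states)
  all_vec <- as.matrix(expand.grid(rep(list(0:1), s)))[, s:1, drop = FALSE]
  key <- apply(all_vec, 1, paste, collapse = "")
  D <- matrix(0L, nrow(all_vec), nrow(all_vec))
  for (j in seq_len(s)) D <- D + outer(all_vec[, j], all_vec[, j], "!=")
  term <- match(apply(states, 1, paste, collapse = ""), key)
  steiner_min_length(D, term)
}

# Minimum Steiner length of the observed haplotypes within an mj_network's
# own graph (nodes incl. medians, edge lengths = mutation counts).
network_steiner <- function(net) {
  W <- ifelse(net$adjacency, net$edge_length, Inf)
  diag(W) <- 0
  D <- floyd(W)
  steiner_min_length(D, which(net$observed))
}

# --- literal Moran's I double sum -------------------------------------------
morans_i_oracle <- function(x, w) {
  n <- length(x)
  xb <- mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    num <- num + w[i, j] * (x[i] - xb) * (x[j] - xb)
  (n / sum(w)) * num / sum((x - xb)^2)
}

# --- brute-force AMOVA sums of squares from an explicit distance matrix -----
# ind_hap: per-individual haplogroup index; ind_pop: population label;
# grp_of_pop: named vector population -> group; D2: squared distances.
amova_ss_oracle <- function(ind_hap, ind_pop, grp_of_pop, D2) {
  N <- length(ind_hap)
  dmat <- matrix(0, N, N)
  for (i in seq_len(N)) for (j in seq_len(N))
    dmat[i, j] <- D2[ind_hap[i], ind_hap[j]]
  ss_set <- function(idx) {
    if (length(idx) == 0) return(0)
    s <- 0
    for (a in seq_along(idx)) for (b in seq_along(idx))
      if (a < b) s <- s + dmat[idx[a], idx[b]]
    s / length(idx)
  }
  ss_tot <- ss_set(seq_len(N))
  pops <- names(grp_of_pop)
  ss_wp <- sum(vapply(pops, function(p) ss_set(which(ind_pop == p)), 0))
  groups <- unique(grp_of_pop)
  ss_wg <- sum(vapply(groups, function(g)
    ss_set(which(ind_pop %in% pops[grp_of_pop == g])), 0))
  c(among_groups = ss_tot - ss_wg,
    among_pops_within_groups = ss_wg - ss_wp,
    within_pops = ss_wp, total = ss_tot)
}
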