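## Median-joining haplotype networks (Bandelt-style) with mutation-labelled
## edges.

#' Condense variant profiles into haplotypes over a site panel
#'
#' Profiles with identical states across the panel merge into one haplotype;
#' frequency is the multiplicity and population tags are unioned. Every
#' profile must cover the whole panel.
#'
#' @param profiles list of [variant_profile()]s.
#' @param panel integer vector of 1-based panel positions.
#' @param populations optional character vector of population tags, one per
#'   profile.
#' @return object of class `haplotype_set`: list with `states` (haplotype x
#'   site character matrix; entries are the mutation token at that site or
#'   `""` for the reference state), `freq`, `labels`, `populations`,
#'   `panel`.
#' @export
condense_haplotypes <- function(profiles, panel, populations = NULL) {
  panel <- as.integer(panel)
  states <- t(vapply(profiles, function(p) {
    if (!all(position_in_covered(panel, p$covered)))
      stop("profile ", p$sample_id, " does not cover the site panel")
    s <- rep("", length(panel))
    hit <- p$mutations$position %in% panel
    m <- p$mutations[hit, , drop = FALSE]
    s[match(m$position, panel)] <- m$token
    s
  }, character(length(panel))))
  key <- apply(states, 1, paste, collapse = "|")
  groups <- split(seq_along(profiles), key)
  groups <- groups[order(vapply(groups, min, 1L))] # first-seen order
  st <- states[vapply(groups, min, 1L), , drop = FALSE]
  structure(list(
    states = st,
    freq = unname(vapply(groups, length, 1L)),
    labels = unname(vapply(groups, function(g) profiles[[g[1]]]$sample_id, "")),
    populations = unname(lapply(groups, function(g)
      sort(unique(populations[g])) %||% character())),
    panel = panel), class = "haplotype_set")
}

#' Build a haplotype set directly from a state matrix
#'
#' Convenience constructor used by tests and the CLI for binary/multistate
#' toy data.
#'
#' @param states haplotype x site matrix (character or 0/1 integer).
#' @param freq frequencies (default 1 each).
#' @param labels haplotype labels (default state strings).
#' @return a `haplotype_set`.
#' @export
haplotype_set <- function(states, freq = NULL, labels = NULL) {
  states <- as.matrix(states)
  mode(states) <- "character"
  structure(list(states = states,
                 freq = freq %||% rep(1L, nrow(states)),
                 labels = labels %||% apply(states, 1, paste, collapse = ""),
                 populations = rep(list(character()), nrow(states)),
                 panel = seq_len(ncol(states))),
            class = "haplotype_set")
}

state_key <- function(states) apply(states, 1, paste, collapse = "|")

hamming_matrix <- function(states, weights) {
  n <- nrow(states)
  d <- matrix(0, n, n)
  for (j in seq_len(ncol(states))) {
    dj <- outer(states[, j], states[, j], "!=") * weights[j]
    d <- d + dj
  }
  d
}

# epsilon-relaxed minimum-spanning connectivity (Bandelt): a link (u,v) is
# feasible iff d(u,v) <= dc(u,v) + eps, where dc is the distance level at
# which u and v first join in a Kruskal run that merges whole levels at once.
msn_links <- function(d, eps = 0) {
  n <- nrow(d)
  comp <- seq_len(n)
  dc <- matrix(Inf, n, n)
  for (lev in sort(unique(d[upper.tri(d)]))) {
    newly <- outer(comp, comp, "!=") & d <= lev
    # record connection level for pairs joined at this level
    reach <- matrix(FALSE, n, n)
    adj <- d <= lev
    # components of the graph with all links of weight <= lev
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
    memb <- igraph::components(g)$membership
    same <- outer(memb, memb, "==")
    joined <- same & is.infinite(dc)
    dc[joined] <- lev
    comp <- memb
    if (all(comp == comp[1])) break
  }
  diag(dc) <- 0
  feasible <- d <= dc + eps
  diag(feasible) <- FALSE
  feasible
}

majority_state <- function(a, b, c) {
  ifelse(a == b | a == c, a, ifelse(b == c, b, a))
}

#' Median-joining network
#'
#' Implements the median-joining heuristic: iteratively build the
#' epsilon-relaxed minimum-spanning connectivity over the current haplotype
#' set, propose median (Steiner) vectors from triplets sharing a link,
#' add those whose connection cost is within `epsilon` of the optimum,
#' delete obsolete inferred nodes (unobserved, degree <= 2), and repeat to a
#' fixpoint. Characters are equally weighted by default.
#'
#' @param haps a [haplotype_set()] (>= 2 haplotypes).
#' @param epsilon integer >= 0 relaxation parameter (default 0).
#' @param weights per-site weight vector (default 1 each).
#' @param max_iter safety cap on iterations.
#' @return object of class `mj_network`: list with `states` (all nodes,
#'   observed and median), `freq` (0 for medians), `labels`, `observed`,
#'   `adjacency` (logical matrix of feasible links), `edge_length` matrix,
#'   `epsilon`, `graph` (an igraph with node/edge attributes; edges labelled
#'   with the differing site tokens).
#' @export
#' @examples
#' h <- haplotype_set(rbind(c(0,0,0), c(1,1,0), c(0,1,1)))
#' net <- median_joining_network(h)
#' sum(net$graph_total_length) # minimum Steiner length 3
median_joining_network <- function(haps, epsilon = 0, weights = NULL,
                                   max_iter = 100L) {
  states <- haps$states
  if (nrow(states) < 2) stop("need at least 2 haplotypes")
  weights <- weights %||% rep(1, ncol(states))
  if (length(weights) != ncol(states)) stop("one weight per site required")
  freq <- haps$freq
  labels <- haps$labels
  observed <- rep(TRUE, nrow(states))
  med_count <- 0L
  for (iter in seq_len(max_iter)) {
    d <- hamming_matrix(states, weights)
    if (any(d[upper.tri(d)] == 0) && iter == 1L)
      stop("duplicate haplotypes; condense first")
    adj <- msn_links(d, epsilon)
    # prune obsolete medians: unobserved nodes with degree <= 2
    deg <- rowSums(adj)
    obsolete <- !observed & deg <= 2
    if (any(obsolete)) {
      keep <- !obsolete
      states <- states[keep, , drop = FALSE]
      freq <- freq[keep]; labels <- labels[keep]; observed <- observed[keep]
      next
    }
    # candidate medians from all node triplets (a deliberately wider
    # candidate set than linked triplets only: at epsilon 0 it retains
    # minimum-Steiner connectivity on small binary panels)
    n <- nrow(states)
    existing <- state_key(states)
    cand <- list(); cost <- numeric()
    if (n >= 3) {
      for (u in 1:(n - 2)) for (v in (u + 1):(n - 1)) for (w in (v + 1):n) {
        m <- majority_state(states[u, ], states[v, ], states[w, ])
        k <- paste(m, collapse = "|")
        if (k %in% existing || k %in% names(cand)) next
        cst <- sum(weights * (m != states[u, ])) +
          sum(weights * (m != states[v, ])) +
          sum(weights * (m != states[w, ]))
        cand[[k]] <- m; cost[k] <- cst
      }
    }
    if (length(cand) == 0) break
    lambda <- min(cost)
    add <- names(cand)[cost <= lambda + epsilon]
    if (length(add) == 0) break
    for (k in add) {
      med_count <- med_count + 1L
      states <- rbind(states, cand[[k]])
      freq <- c(freq, 0L)
      labels <- c(labels, paste0("mv", med_count))
      observed <- c(observed, FALSE)
    }
  }
  d <- hamming_matrix(states, weights)
  adj <- msn_links(d, epsilon)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  igraph::V(g)$name <- labels
  igraph::V(g)$label <- labels
  igraph::V(g)$freq <- freq
  igraph::V(g)$observed <- observed
  el <- igraph::as_edgelist(g, names = FALSE)
  elab <- vapply(seq_len(nrow(el)), function(i) {
    diffs <- which(states[el[i, 1], ] != states[el[i, 2], ])
    toks <- ifelse(nzchar(states[el[i, 2], diffs]), states[el[i, 2], diffs],
                   states[el[i, 1], diffs])
    toks[!nzchar(toks)] <- paste0("site", diffs[!nzchar(toks)])
    paste(toks, collapse = ",")
  }, "")
  igraph::E(g)$label <- elab
  igraph::E(g)$weight <- d[el]
  structure(list(states = states, freq = freq, labels = labels,
                 observed = observed, adjacency = adj, edge_length = d,
                 epsilon = epsilon,
                 graph_total_length = sum(d[el]),
                 graph = g),
            class = "mj_network")
}

#' @export
print.mj_network <- function(x, ...) {
  cat("mj_network: ", sum(x$observed), " observed + ", sum(!x$observed),
      " median nodes, ", igraph::ecount(x$graph), " links (epsilon ",
      x$epsilon, ")\n", sep = "")
  invisible(x)
}

#' Export a network to GML or DOT
#'
#' Nodes carry `label` and `freq` (node size) attributes, edges their
#' mutation-token `label`; nodes are written in sorted label order so output
#' is deterministic.
#'
#' @param net an `mj_network` (or any igraph with `label`/`freq`/`label`
#'   attributes via `net$graph`).
#' @param path output file.
#' @param format `"GML"` or `"DOT"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("GML", "DOT")) {
  format <- match.arg(toupper(format[1]), c("GML", "DOT"))
  g <- if (inherits(net, "mj_network")) net$graph else net
  if (igraph::vcount(g) == 0) stop("empty graph")
  ord <- order(igraph::V(g)$label)
  perm <- match(seq_along(ord), ord)
  g <- igraph::permute(g, perm)
  labs <- igraph::V(g)$label
  frq <- igraph::V(g)$freq
  el <- igraph::as_edgelist(g, names = FALSE)
  eord <- order(el[, 1], el[, 2])
  lines <- character()
  if (format == "GML") {
    lines <- c("graph [", "  directed 0")
    for (i in seq_along(labs))
      lines <- c(lines, "  node [", paste0("    id ", i - 1),
                 paste0("    label \"", labs[i], "\""),
                 paste0("    freq ", frq[i]), "  ]")
    for (i in eord)
      lines <- c(lines, "  edge [",
                 paste0("    source ", el[i, 1] - 1),
                 paste0("    target ", el[i, 2] - 1),
                 paste0("    label \"", igraph::E(g)$label[i], "\""), "  ]")
    lines <- c(lines, "]")
  } else {
    lines <- c("graph haplotypes {")
    for (i in seq_along(labs))
      lines <- c(lines, sprintf("  \"%s\" [width=%s];", labs[i], frq[i]))
    for (i in eord)
      lines <- c(lines, sprintf("  \"%s\" -- \"%s\" [label=\"%s\"];",
                                labs[el[i, 1]], labs[el[i, 2]],
                                igraph::E(g)$label[i]))
    lines <- c(lines, "}")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a GML network written by [export_network()]
#'
#' @param path GML file path.
#' @return an igraph object with `label` and `freq` node attributes.
#' @export
import_network_gml <- function(path) {
  igraph::read_graph(path, format = "gml")
}
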