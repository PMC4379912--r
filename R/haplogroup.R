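## Haplogroup definition trees and motif-based assignment.

#' Load a haplogroup definition tree
#'
#' Reads the tree TSV dialect: columns `Name`, `Parent`, `Motif`
#' (space-separated mutation tokens defining the branch leading to the node,
#' `@` prefix for back mutations) and optional `Ancestry` (macro-ancestry
#' label, one of EastEurasian, SouthAsian, WestEurasian, Other, Unassigned).
#' The root row has an empty `Parent`. Lines starting with `#` are comments.
#'
#' The packaged fixture (`system.file("extdata",
#' "haplogroup_tree_fixture.tsv", package = "mtlineage")`) bundles the newly
#' described clades M54a, M55b and M84b with their published defining
#' motifs, plus placeholder definitions for the other basal clades and a few
#' East-Eurasian representatives.
#'
#' @param path file path; default the packaged fixture.
#' @param reference an [mt_reference()] used to validate motif tokens.
#' @return object of class `haplogroup_tree`: list with `nodes` (data.frame
#'   Name, Parent, Ancestry, Depth), `motifs` (named list of token vectors)
#'   and `root`.
#' @export
#' @examples
#' tr <- load_haplogroup_tree()
#' tr$motifs[["M54a"]]
load_haplogroup_tree <- function(path = NULL, reference = mt_reference()) {
  path <- path %||% system.file("extdata", "haplogroup_tree_fixture.tsv",
                                package = "mtlineage")
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  if (!all(c("Name", "Parent", "Motif") %in% names(d)))
    stop("tree file needs columns Name, Parent, Motif")
  if (is.null(d$Ancestry)) d$Ancestry <- ""
  d$Name <- trimws(d$Name); d$Parent <- trimws(d$Parent)
  if (anyDuplicated(d$Name)) stop("duplicate haplogroup names")
  root <- d$Name[!nzchar(d$Parent)]
  if (length(root) != 1) stop("tree must have exactly one root")
  orphan <- nzchar(d$Parent) & !(d$Parent %in% d$Name)
  if (any(orphan)) stop("orphan parent(s): ", paste(d$Parent[orphan], collapse = ", "))
  motifs <- lapply(d$Motif, function(s) {
    toks <- strsplit(trimws(s), "\\s+")[[1]]
    toks <- toks[nzchar(toks)]
    for (t in toks) parse_mutation_token(t, reference) # validates
    toks
  })
  names(motifs) <- d$Name
  nonroot <- d$Name != root
  if (any(lengths(motifs)[nonroot] == 0))
    stop("non-root nodes must have a non-empty motif")
  # depths + cycle check
  depth <- stats::setNames(rep(NA_integer_, nrow(d)), d$Name)
  depth[root] <- 0L
  repeat {
    todo <- is.na(depth) & !is.na(depth[d$Parent])
    if (!any(todo)) break
    depth[d$Name[todo]] <- depth[d$Parent[todo]] + 1L
  }
  if (anyNA(depth)) stop("tree contains a cycle or disconnected node")
  d$Depth <- as.integer(depth[d$Name])
  d$Ancestry[!nzchar(d$Ancestry)] <- "Unassigned"
  tree <- structure(list(nodes = d[, c("Name", "Parent", "Ancestry", "Depth")],
                         motifs = motifs, root = root),
                    class = "haplogroup_tree")
  # cache canonical cumulative-motif tokens per node (assignment hot path)
  tree$path_tokens <- lapply(d$Name, function(n) {
    toks <- canonical_motif_tokens(path_motif(tree, n), reference)
    list(tokens = toks,
         positions = as.integer(sub("^@?([0-9]+).*$", "\\1", toks)))
  })
  names(tree$path_tokens) <- d$Name
  tree
}

#' @export
print.haplogroup_tree <- function(x, ...) {
  cat("haplogroup_tree: ", nrow(x$nodes), " clades, root ", x$root, "\n", sep = "")
  invisible(x)
}

tree_parent <- function(tree, name) {
  tree$nodes$Parent[match(name, tree$nodes$Name)]
}

tree_ancestors <- function(tree, name) { # root ... name, inclusive
  path <- name
  while (name != tree$root) {
    name <- tree_parent(tree, name)
    path <- c(name, path)
  }
  path
}

tree_subtree <- function(tree, name) {
  out <- name
  repeat {
    kids <- tree$nodes$Name[tree$nodes$Parent %in% out & !(tree$nodes$Name %in% out)]
    if (length(kids) == 0) break
    out <- c(out, kids)
  }
  out
}

#' Cumulative motif along the root-to-node path
#'
#' Concatenates branch motifs from the root down to `name`. A back-mutation
#' token (`@pos`) cancels earlier occurrences at the same position (both the
#' original token and the `@` token are removed from the cumulative motif;
#' an uncancelled `@` token is dropped since it is unobservable against the
#' reference).
#'
#' @param tree a [load_haplogroup_tree()] tree.
#' @param name clade name.
#' @return character vector of tokens (empty for the root).
#' @export
path_motif <- function(tree, name) {
  if (!name %in% tree$nodes$Name) stop("unknown haplogroup: ", name)
  toks <- unlist(lapply(tree_ancestors(tree, name), function(n) tree$motifs[[n]]),
                 use.names = FALSE)
  if (is.null(toks)) return(character())
  out <- character()
  out_pos <- integer()
  for (t in toks) {
    if (startsWith(t, "@")) {
      p <- as.integer(sub("^@([ACGT]?)([0-9]+).*$", "\\2", t))
      hit <- out_pos == p
      out <- out[!hit]; out_pos <- out_pos[!hit]
    } else {
      p <- as.integer(sub("^([ACGT]?)([0-9]+).*$", "\\2", t))
      out <- c(out, t); out_pos <- c(out_pos, p)
    }
  }
  out
}

# expand a motif's tokens to canonical per-mutation tokens (ranged deletions
# become one token per deleted position)
canonical_motif_tokens <- function(tokens, reference) {
  if (length(tokens) == 0) return(character())
  parse_mutations(tokens, reference)$token
}

#' Assign a variant profile to a haplogroup
#'
#' Scores every clade as (number of cumulative-motif tokens observed in the
#' profile, restricted to the profile's covered range) minus `w_miss` times
#' (motif tokens inside the covered range but absent from the profile).
#' Motif positions outside the covered range are ignored. Returns the
#' score-maximising clade(s); ties are broken by more matches, then fewer
#' misses, then shallower depth, then name. A best score <= 0 yields
#' `"Unassigned"`.
#'
#' @param p a [variant_profile()].
#' @param tree a [load_haplogroup_tree()] tree.
#' @param w_miss penalty per expected-but-absent defining mutation
#'   (default 1).
#' @param reference an [mt_reference()].
#' @return object of class `haplogroup_assignment`: list with `haplogroup`,
#'   `co_optimal` (all score-maximising clades), `ambiguous`, `score`,
#'   `matched`, `expected_in_range`, `conflicts`, `ancestry`, `sample_id`.
#' @export
#' @examples
#' tr <- load_haplogroup_tree()
#' p <- variant_profile("S1", mutations = paste(path_motif(tr, "M54a"), collapse = " "))
#' assign_haplogroup(p, tr)$haplogroup
assign_haplogroup <- function(p, tree, w_miss = 1,
                              reference = mt_reference()) {
  if (nrow(tree$nodes) == 0) stop("empty tree")
  prof_tok <- profile_tokens(p)
  prof_pos <- p$mutations$position
  nodes <- tree$nodes$Name
  nn <- length(nodes)
  full_cov <- nrow(p$covered) == 1 && p$covered[1, 1] == 1L &&
    p$covered[1, 2] == MT_LENGTH
  matched <- missing <- expected <- conflicts <- integer(nn)
  for (k in seq_len(nn)) {
    n <- nodes[k]
    if (!is.null(tree$path_tokens)) {
      cm <- tree$path_tokens[[n]]$tokens
      cm_pos <- tree$path_tokens[[n]]$positions
    } else {
      cm <- canonical_motif_tokens(path_motif(tree, n), reference)
      cm_pos <- as.integer(sub("^@?([0-9]+).*$", "\\1", cm))
    }
    if (!full_cov) {
      inr <- position_in_covered(cm_pos, p$covered)
      cm_in <- cm[inr]; cm_pos_in <- cm_pos[inr]
    } else {
      cm_in <- cm; cm_pos_in <- cm_pos
    }
    matched[k] <- sum(cm_in %in% prof_tok)
    missing[k] <- length(cm_in) - matched[k]
    expected[k] <- length(cm_in)
    conflicts[k] <- sum(prof_pos %in% cm_pos_in & !(prof_tok %in% cm_in))
  }
  res <- list(name = nodes, score = matched - w_miss * missing,
              matched = matched, missing = missing, expected = expected,
              conflicts = conflicts, depth = tree$nodes$Depth)
  best_score <- max(res$score)
  sel <- which(res$score == best_score)
  ord <- sel[order(-res$matched[sel], res$missing[sel], res$depth[sel],
                   res$name[sel])]
  cand <- lapply(res, function(v) v[ord])
  top <- lapply(cand, function(v) v[1])
  tied <- cand$matched == top$matched & cand$missing == top$missing &
    cand$depth == top$depth
  unassigned <- best_score <= 0
  name <- if (unassigned) "Unassigned" else top$name
  ancestry <- if (unassigned) "Unassigned" else
    tree$nodes$Ancestry[match(top$name, tree$nodes$Name)]
  structure(list(haplogroup = name, co_optimal = cand$name,
                 ambiguous = !unassigned && sum(tied) > 1,
                 score = best_score, matched = top$matched,
                 expected_in_range = top$expected,
                 conflicts = top$conflicts, ancestry = ancestry,
                 sample_id = p$sample_id),
            class = "haplogroup_assignment")
}

#' @export
print.haplogroup_assignment <- function(x, ...) {
  cat("assignment ", x$sample_id, " -> ", x$haplogroup,
      " (score ", x$score, ", ", x$matched, "/", x$expected_in_range,
      " motif sites, ancestry ", x$ancestry, ")\n", sep = "")
  invisible(x)
}

#' Summarise macro-ancestry over a set of assignments
#'
#' @param assignments list of [assign_haplogroup()] results.
#' @return data.frame with `ancestry`, `count`, `percent` (half-up,
#'   2 decimals).
#' @export
#' @examples
#' # 532 of 845 -> 62.96
summarize_ancestry <- function(assignments) {
  if (length(assignments) == 0) stop("no assignments")
  lab <- vapply(assignments, function(a) a$ancestry, "")
  tab <- table(lab)
  out <- data.frame(ancestry = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$percent <- round_half_up(100 * out$count / sum(out$count), 2)
  out[order(-out$count, out$ancestry), , drop = FALSE]
}
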