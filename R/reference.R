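## Reference sequence model and rCRS-relative mutation notation.

.ref_cache <- new.env(parent = emptyenv())

#' Load the packaged mitochondrial reference model
#'
#' Returns the reference sequence plus its gene annotation. The packaged
#' sequence is a deterministic *synthetic stand-in* for the 16,569-bp revised
#' Cambridge reference sequence (the real sequence cannot be redistributed
#' here); real reference bases are pinned at every position the bundled
#' fixtures rely on, and the gene annotation table is the standard public
#' rCRS annotation. Any user-supplied 16,569-bp FASTA (e.g. the real rCRS)
#' can be substituted.
#'
#' @param fasta path to a single-sequence FASTA of length 16,569; default the
#'   packaged synthetic stand-in.
#' @param gene_table path to the gene annotation TSV (columns feature, start,
#'   end, kind, strand); default the packaged table.
#' @return object of class `mt_reference`: list with `bases` (character
#'   vector of length 16,569), `sequence` (single string) and `genes`
#'   (data.frame). The control region is 16024-576 (circular).
#' @export
#' @examples
#' ref <- mt_reference()
#' ref$bases[16189]
mt_reference <- function(fasta = NULL, gene_table = NULL) {
  default <- is.null(fasta) && is.null(gene_table)
  if (default && !is.null(.ref_cache$default)) return(.ref_cache$default)
  fasta <- fasta %||%
    system.file("extdata", "synthetic_rCRS.fasta", package = "mtlineage")
  gene_table <- gene_table %||%
    system.file("extdata", "mt_gene_table.tsv", package = "mtlineage")
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) != 1L || Biostrings::width(seqs)[1] != MT_LENGTH)
    stop("reference FASTA must contain one sequence of length ", MT_LENGTH)
  genes <- utils::read.delim(gene_table, stringsAsFactors = FALSE)
  stopifnot(all(c("feature", "start", "end", "kind", "strand") %in% names(genes)))
  if (any(genes$start < 1 | genes$end > MT_LENGTH))
    stop("annotation intervals outside [1, 16569]")
  seq <- as.character(seqs[[1]])
  ref <- structure(list(bases = strsplit(seq, "")[[1]],
                        sequence = seq, genes = genes),
                   class = "mt_reference")
  if (default) .ref_cache$default <- ref
  ref
}

#' @export
print.mt_reference <- function(x, ...) {
  cat("mt_reference: ", MT_LENGTH, " bp, ", nrow(x$genes),
      " annotated features (control region 16024-576)\n", sep = "")
  invisible(x)
}

## ---- Mutation records ------------------------------------------------------

# Mutations are rows of a data.frame with columns:
#   position (int, 1-based rCRS), ref (chr, "" for insertions),
#   derived (chr, "-" for deletions), kind (transition | transversion |
#   insertion | deletion), back_mutation (lgl), insertion_index (int, 0 if
#   none) and token (canonical printed form).

empty_mutations <- function() {
  data.frame(position = integer(), ref = character(), derived = character(),
             kind = character(), back_mutation = logical(),
             insertion_index = integer(), token = character(),
             stringsAsFactors = FALSE)
}

new_mutations <- function(position, ref, derived, kind, back_mutation = FALSE,
                          insertion_index = 0L) {
  m <- data.frame(position = as.integer(position), ref = ref,
                  derived = derived, kind = kind,
                  back_mutation = back_mutation,
                  insertion_index = as.integer(insertion_index),
                  stringsAsFactors = FALSE)
  m$token <- format_mutation(m)
  m
}

#' Format mutations as phylotree-style tokens
#'
#' Canonical forms: bare position for transitions (`"16172"`), trailing base
#' for transversions (`"16183C"`), `"@pos"` for back mutations, `"posd"` for
#' single-position deletions and `"pos.NX"` for insertions.
#'
#' @param m mutation data.frame (see [parse_mutation_token()]).
#' @return character vector of tokens, one per row.
#' @export
format_mutation <- function(m) {
  if (nrow(m) == 0) return(character())
  vapply(seq_len(nrow(m)), function(i) {
    r <- m[i, ]
    if (r$kind == "insertion")
      return(paste0(r$position, ".", r$insertion_index, r$derived))
    if (r$kind == "deletion") return(paste0(r$position, "d"))
    if (isTRUE(r$back_mutation)) return(paste0("@", r$position))
    if (r$kind == "transition") paste0(r$position)
    else paste0(r$position, r$derived)
  }, "")
}

#' Format a mutation set as a token string, compacting deletion runs
#'
#' Consecutive single-position deletions are written in ranged form
#' (`"8281-8289d"`).
#'
#' @param m mutation data.frame.
#' @return single space-separated token string (empty string if no rows).
#' @export
format_tokens <- function(m) {
  if (nrow(m) == 0) return("")
  m <- m[order(m$position, m$insertion_index), , drop = FALSE]
  toks <- character(0)
  i <- 1
  while (i <= nrow(m)) {
    if (m$kind[i] == "deletion") {
      j <- i
      while (j < nrow(m) && m$kind[j + 1] == "deletion" &&
             m$position[j + 1] == m$position[j] + 1L) j <- j + 1
      toks <- c(toks, if (j > i)
        paste0(m$position[i], "-", m$position[j], "d") else m$token[i])
      i <- j + 1
    } else {
      toks <- c(toks, m$token[i])
      i <- i + 1
    }
  }
  paste(toks, collapse = " ")
}

#' Parse one phylotree-style mutation token
#'
#' Grammar: `[@]? [ACGT]? digits ( "." digits )? ( [ACGT] | "d" )?` plus the
#' ranged deletion form `"a-bd"`. A bare numeric token is a transition to the
#' partner of the reference base; a trailing base letter is a substitution to
#' that base; `"pos.NX"` inserts base X after `pos`; `"@"` marks a back
#' mutation to the reference state; `"a-bd"` expands to one deletion per
#' position. A leading base letter, when present, must match the reference.
#'
#' @param token token string.
#' @param reference an [mt_reference()].
#' @return mutation data.frame (one row, or several for ranged deletions).
#' @export
#' @examples
#' ref <- mt_reference()
#' parse_mutation_token("16193.1C", ref)
#' parse_mutation_token("8281-8289d", ref)
parse_mutation_token <- function(token, reference = mt_reference()) {
  token <- trimws(token)
  # normalize "+" insertion notation (e.g. "16193+C") to ".1" form
  token <- sub("^(@?[ACGT]?[0-9]+)\\+([ACGT]+)$", "\\1.1\\2", token)
  rng <- regmatches(token, regexec("^([0-9]+)-([0-9]+)d$", token))[[1]]
  if (length(rng) == 3) {
    a <- as.integer(rng[2]); b <- as.integer(rng[3])
    if (a > b || b > MT_LENGTH) stop("malformed deletion range: ", token)
    pos <- a:b
    return(new_mutations(pos, reference$bases[pos], "-", "deletion"))
  }
  mm <- regmatches(token, regexec(
    "^(@?)([ACGT]?)([0-9]+)(\\.([0-9]+))?([ACGTd]?)$", token))[[1]]
  if (length(mm) == 0) stop("malformed mutation token: ", token)
  back <- mm[2] == "@"
  lead <- mm[3]
  pos <- as.integer(mm[4])
  ins <- mm[6]
  tail <- mm[7]
  if (pos < 1L || pos > MT_LENGTH)
    stop("position outside [1, 16569]: ", token)
  refb <- reference$bases[pos]
  if (nzchar(lead) && lead != refb)
    stop("token ", token, ": stated reference base ", lead,
         " does not match reference ", refb)
  if (nzchar(ins)) { # insertion
    idx <- as.integer(ins)
    if (!nzchar(tail) || tail == "d" || idx < 1L)
      stop("malformed insertion token: ", token)
    if (back) stop("back mutation undefined for insertions: ", token)
    return(new_mutations(pos, "", tail, "insertion", insertion_index = idx))
  }
  if (tail == "d") {
    if (back) stop("back mutation undefined for deletions: ", token)
    return(new_mutations(pos, refb, "-", "deletion"))
  }
  if (back) {
    if (nzchar(tail) && tail != refb)
      stop("back mutation must restore the reference base: ", token)
    # derived equals the reference state; kind records a transition by
    # convention (the reverted state is not encoded in the token)
    return(new_mutations(pos, refb, refb, "transition", back_mutation = TRUE))
  }
  derived <- if (nzchar(tail)) tail else transition_partner(refb)
  if (derived == refb)
    stop("derived base equals reference without '@': ", token)
  kind <- if (is_transition(refb, derived)) "transition" else "transversion"
  new_mutations(pos, refb, derived, kind)
}

#' Parse a vector (or space-separated string) of mutation tokens
#'
#' @param tokens character vector of tokens, or a single space-separated
#'   string.
#' @param reference an [mt_reference()].
#' @return mutation data.frame.
#' @export
parse_mutations <- function(tokens, reference = mt_reference()) {
  if (length(tokens) == 1 && grepl("\\s", trimws(tokens)))
    tokens <- strsplit(trimws(tokens), "\\s+")[[1]]
  tokens <- tokens[nzchar(trimws(tokens))]
  if (length(tokens) == 0) return(empty_mutations())
  do.call(rbind, lapply(tokens, parse_mutation_token, reference = reference))
}

## ---- VariantProfile --------------------------------------------------------

#' Construct a variant profile
#'
#' The unit flowing through classification and dating: a sample's
#' rCRS-relative mutations plus the sequenced (covered) range(s).
#'
#' @param sample_id sample identifier.
#' @param covered covered intervals: two-column matrix or `c(start, end)`
#'   vector(s); circular wrap allowed (`c(16024, 407)`). Default full genome.
#' @param mutations mutation data.frame (from [parse_mutations()]) or a token
#'   string.
#' @param reference an [mt_reference()] (used when `mutations` is a string).
#' @return object of class `variant_profile`.
#' @export
#' @examples
#' p <- variant_profile("S1", c(16024, 407), "16172 16311")
variant_profile <- function(sample_id, covered = c(1L, MT_LENGTH),
                            mutations = empty_mutations(),
                            reference = mt_reference()) {
  if (is.character(mutations)) mutations <- parse_mutations(mutations, reference)
  covered <- as_intervals(covered)
  if (nrow(mutations) > 0) {
    if (!all(position_in_covered(mutations$position, covered)))
      stop("mutation position outside covered intervals (sample ", sample_id, ")")
    key <- paste(mutations$position, mutations$insertion_index)
    if (anyDuplicated(key))
      stop("duplicate (position, insertion_index) in sample ", sample_id)
  }
  structure(list(sample_id = sample_id, covered = covered,
                 mutations = mutations),
            class = "variant_profile")
}

#' @export
print.variant_profile <- function(x, ...) {
  cat("variant_profile ", x$sample_id, ": ",
      paste(apply(x$covered, 1, paste, collapse = "-"), collapse = ";"),
      " | ", format_tokens(x$mutations), "\n", sep = "")
  invisible(x)
}

profile_tokens <- function(p) p$mutations$token

## ---- variant calling -------------------------------------------------------

# Shift alignment gaps to their 3'-most equivalent position (phylotree
# convention). `a` and `b` are aligned character vectors; gaps in `b` are
# deletions (shift valid while a[i] == a[j+1]), gaps in `a` are insertions
# (shift valid while b[i] == b[j+1]).
shift_gaps_3prime <- function(a, b) {
  shift_one <- function(x, y) { # gaps live in y
    L <- length(x)
    i <- 1
    while (i <= L) {
      if (y[i] == "-" && x[i] != "-") {
        j <- i
        while (j < L && y[j + 1] == "-" && x[j + 1] != "-") j <- j + 1
        while (j < L && y[j + 1] != "-" && x[j + 1] != "-" &&
               x[i] == x[j + 1]) {
          y[i] <- y[j + 1]; y[j + 1] <- "-"
          i <- i + 1; j <- j + 1
        }
        i <- j + 1
      } else i <- i + 1
    }
    list(x = x, y = y)
  }
  s <- shift_one(a, b); a <- s$x; b <- s$y   # deletions (gaps in b)
  s <- shift_one(b, a); b <- s$x; a <- s$y   # insertions (gaps in a)
  list(ref = a, sample = b)
}

#' Call variants against the reference
#'
#' Aligns a sample sequence to the reference over its covered interval(s)
#' (global pairwise alignment per interval, no multiple alignment) and
#' reports all differences as mutation records. Indels are placed at their
#' 3'-most equivalent position. Positions where the sample carries an IUPAC
#' ambiguity code (N, R, Y, ...) are treated as uncovered: no call is made
#' there and they are removed from the profile's covered set.
#'
#' @param sample_seq sample sequence string for the covered span (gaps "-"
#'   allowed), or a named list of one string per covered interval.
#' @param covered covered interval(s), see [variant_profile()].
#' @param reference an [mt_reference()].
#' @param sample_id sample identifier for the returned profile.
#' @return a [variant_profile()].
#' @export
#' @examples
#' ref <- mt_reference()
#' seq <- paste(ref$bases[covered_positions(c(16024, 407))], collapse = "")
#' call_variants(seq, c(16024, 407), ref)$mutations
call_variants <- function(sample_seq, covered = c(1L, MT_LENGTH),
                          reference = mt_reference(), sample_id = "sample") {
  covered <- as_intervals(covered)
  if (is.character(sample_seq) && length(sample_seq) == 1 && nrow(covered) > 1)
    stop("supply one sequence per covered interval")
  seqs <- if (is.list(sample_seq)) sample_seq else as.list(sample_seq)
  if (length(seqs) != nrow(covered))
    stop("need one sequence per covered interval")
  muts <- empty_mutations()
  drop_pos <- integer()
  for (k in seq_len(nrow(covered))) {
    pos_map <- interval_positions(covered[k, ])
    if (length(pos_map) == 0) stop("covered interval empty")
    ref_sub <- paste(reference$bases[pos_map], collapse = "")
    samp <- toupper(gsub("-", "", seqs[[k]]))
    if (grepl("[^ACGTURYSWKMBDHVN]", samp))
      stop("non-IUPAC characters in sample sequence")
    if (nchar(samp) == nchar(ref_sub) && samp == ref_sub) next
    if (nchar(samp) == nchar(ref_sub)) {
      aln <- list(ref = strsplit(ref_sub, "")[[1]],
                  sample = strsplit(samp, "")[[1]])
    } else {
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(samp), Biostrings::DNAString(ref_sub),
        type = "global", gapOpening = 6, gapExtension = 1)
      aln <- list(ref = strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]],
                  sample = strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]])
    }
    aln <- shift_gaps_3prime(aln$ref, aln$sample)
    ri <- 0L            # index into pos_map
    ins_run <- 0L
    for (col in seq_along(aln$ref)) {
      rb <- aln$ref[col]; sb <- aln$sample[col]
      if (rb != "-") { ri <- ri + 1L; ins_run <- 0L }
      if (rb == "-") { # insertion relative to reference
        ins_run <- ins_run + 1L
        anchor <- if (ri >= 1L) pos_map[ri] else pos_map[1] - 1L
        if (sb %in% c("A", "C", "G", "T"))
          muts <- rbind(muts, new_mutations(anchor, "", sb, "insertion",
                                            insertion_index = ins_run))
        next
      }
      pos <- pos_map[ri]
      if (sb == "-") {
        muts <- rbind(muts, new_mutations(pos, rb, "-", "deletion"))
      } else if (!sb %in% c("A", "C", "G", "T")) {
        drop_pos <- c(drop_pos, pos)        # ambiguity: treat as uncovered
      } else if (sb != rb) {
        kind <- if (is_transition(rb, sb)) "transition" else "transversion"
        muts <- rbind(muts, new_mutations(pos, rb, sb, kind))
      }
    }
  }
  if (length(drop_pos)) {
    keep <- setdiff(covered_positions(covered), drop_pos)
    covered <- positions_to_intervals(keep)
  }
  variant_profile(sample_id, covered, muts, reference)
}

# collapse a sorted position vector back into circular intervals
positions_to_intervals <- function(pos) {
  pos <- sort(unique(as.integer(pos)))
  if (length(pos) == 0) stop("no covered positions left")
  breaks <- which(diff(pos) > 1L)
  starts <- pos[c(1L, breaks + 1L)]
  ends <- pos[c(breaks, length(pos))]
  m <- cbind(start = starts, end = ends)
  # rejoin a wrap across 16569/1
  if (nrow(m) > 1 && m[1, 1] == 1L && m[nrow(m), 2] == MT_LENGTH) {
    m[nrow(m), 2] <- m[1, 2]
    m <- m[-1, , drop = FALSE]
  }
  m
}

#' Apply a mutation set to the reference (or to a covered slice of it)
#'
#' Utility used by the simulators and tests: returns the sample sequence
#' implied by a profile over its covered intervals (substitutions, deletions
#' and insertions applied).
#'
#' @param profile a [variant_profile()].
#' @param reference an [mt_reference()].
#' @return list of one sequence string per covered interval.
#' @export
mutate_reference <- function(profile, reference = mt_reference()) {
  lapply(seq_len(nrow(profile$covered)), function(k) {
    pos_map <- interval_positions(profile$covered[k, ])
    chars <- reference$bases[pos_map]
    idx <- match(profile$mutations$position, pos_map)
    keep <- !is.na(idx)
    m <- profile$mutations[keep, , drop = FALSE]
    idx <- idx[keep]
    ins <- m$kind == "insertion"
    chars[idx[m$kind %in% c("transition", "transversion")]] <-
      m$derived[m$kind %in% c("transition", "transversion")]
    chars[idx[m$kind == "deletion"]] <- ""
    if (any(ins)) {
      add <- split(m[ins, , drop = FALSE], idx[ins])
      for (at in rev(as.integer(names(add)))) {
        a <- add[[as.character(at)]]
        a <- a[order(a$insertion_index), ]
        chars[at] <- paste0(chars[at], paste(a$derived, collapse = ""))
      }
    }
    paste(chars, collapse = "")
  })
}
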