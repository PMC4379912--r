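## Functional classification, the standard site-exclusion filter, and
## in-silico RFLP typing.

VERT_MITO_CODE <- NULL # initialised lazily from Biostrings (NCBI table 2)

vert_mito_code <- function() {
  if (is.null(VERT_MITO_CODE))
    utils::assignInMyNamespace("VERT_MITO_CODE", Biostrings::getGeneticCode("2"))
  VERT_MITO_CODE
}

feature_at <- function(pos, reference) {
  g <- reference$genes
  hit <- which(g$start <= pos & g$end >= pos)
  if (length(hit) == 0) return(NULL)
  g[hit[1], ] # overlapping features: first listed wins
}

translate_codon <- function(codon) {
  unname(vert_mito_code()[paste(codon, collapse = "")])
}

# amino acid at `pos` in protein feature `feat` when the base there is `base`
aa_with_base <- function(pos, base, feat, reference) {
  if (feat$strand == "H") {
    off <- pos - feat$start
    c0 <- feat$start + (off %/% 3L) * 3L
    codon <- reference$bases[c0:(c0 + 2L)]
    if (c0 + 2L > feat$end) codon[(feat$end - c0 + 2L):3L] <- "A" # poly-A pad
    codon[pos - c0 + 1L] <- base
  } else {
    off <- feat$end - pos
    c0 <- feat$end - (off %/% 3L) * 3L
    idx <- c(c0, c0 - 1L, c0 - 2L)
    codon <- dna_complement(reference$bases[idx])
    if (c0 - 2L < feat$start) codon[(c0 - feat$start + 2L):3L] <- "A"
    codon[off %% 3L + 1L] <- dna_complement(base)
  }
  translate_codon(codon)
}

#' Classify the functional effect of mutations
#'
#' Substitutions inside the coding span 577-16023 are classified as
#' `s` (synonymous), `ns` (nonsynonymous), `t` (tRNA), `r` (rRNA) or `nc`
#' (intergenic noncoding); protein positions are translated with the
#' vertebrate mitochondrial code, light-strand genes via the reverse
#' complement. Control-region substitutions get class `control`; indels get
#' class `indel` (never `s`/`ns`).
#'
#' @param m mutation data.frame.
#' @param reference an [mt_reference()].
#' @return character vector of classes, one per row of `m`.
#' @export
#' @examples
#' ref <- mt_reference()
#' classify_mutation_function(parse_mutations("10398G 16172", ref), ref)
classify_mutation_function <- function(m, reference = mt_reference()) {
  vapply(seq_len(nrow(m)), function(i) {
    r <- m[i, ]
    if (r$kind %in% c("insertion", "deletion")) return("indel")
    if (in_control_region(r$position)) return("control")
    feat <- feature_at(r$position, reference)
    if (is.null(feat)) return("nc")
    if (feat$kind == "tRNA") return("t")
    if (feat$kind == "rRNA") return("r")
    if (feat$kind == "noncoding") return("nc")
    aa_ref <- aa_with_base(r$position, r$ref, feat, reference)
    aa_alt <- aa_with_base(r$position, r$derived, feat, reference)
    if (identical(aa_ref, aa_alt)) "s" else "ns"
  }, "")
}

#' Apply the standard hypervariable-site exclusion filter
#'
#' Removes the mutations conventionally disregarded in control-region
#' phylogenetics: length polymorphisms of the C stretch in 303-315, AC
#' indels in 515-522, 16182C, 16183C, insertions of C after 16193
#' (16193.1C, 16193.2C, ...) and any variant at 16519. Everything else is
#' preserved in order.
#'
#' @param p a [variant_profile()] or a mutation data.frame.
#' @return object of the same type with the excluded mutations dropped.
#' @export
apply_exclusion_filter <- function(p) {
  m <- if (inherits(p, "variant_profile")) p$mutations else p
  if (nrow(m) > 0) {
    indel <- m$kind %in% c("insertion", "deletion")
    drop <- (indel & m$position >= 303L & m$position <= 315L) |
      (indel & m$position >= 515L & m$position <= 522L) |
      (m$position == 16182L & m$derived == "C") |
      (m$position == 16183L & m$derived == "C") |
      (m$position == 16193L & m$kind == "insertion" & m$derived == "C") |
      m$position == 16519L
    m <- m[!drop, , drop = FALSE]
    rownames(m) <- NULL
  }
  if (inherits(p, "variant_profile")) { p$mutations <- m; p } else m
}

## ---- in-silico RFLP --------------------------------------------------------

#' The coding-region RFLP panel
#'
#' The six enzyme sites conventionally typed alongside the 8281-8289
#' deletion: 4831 HhaI, 5176 AluI, 9820 HinfI, 12406 HpaI, 13262 AluI and
#' 14465 AccI.
#'
#' @return list of `rflp_site` objects.
#' @export
rflp_panel <- function() {
  list(rflp_site("4831HhaI", 4831L, "GCGC"),
       rflp_site("5176AluI", 5176L, "AGCT"),
       rflp_site("9820HinfI", 9820L, "GANTC"),
       rflp_site("12406HpaI", 12406L, "GTTAAC"),
       rflp_site("13262AluI", 13262L, "AGCT"),
       rflp_site("14465AccI", 14465L, "GTMKAC"))
}

#' Construct an RFLP site
#'
#' @param label conventional site label, e.g. `"4831HhaI"`.
#' @param anchor 1-based anchor position.
#' @param recognition enzyme recognition sequence over IUPAC codes
#'   (length >= 4).
#' @return object of class `rflp_site`.
#' @export
rflp_site <- function(label, anchor, recognition) {
  anchor <- as.integer(anchor)
  if (nchar(recognition) < 4L) stop("recognition sequence shorter than 4")
  if (anchor < 1L || anchor > MT_LENGTH) stop("anchor outside [1, 16569]")
  structure(list(label = label, anchor = anchor,
                 recognition = toupper(recognition)),
            class = "rflp_site")
}

#' Type an RFLP site in silico
#'
#' The site is scored `"present"` iff the IUPAC-expanded recognition motif
#' occurs in the sample overlapping the anchor position, `"absent"`
#' otherwise, and `"untyped"` when the +/-10 bp window around the anchor is
#' not fully covered (or contains ambiguity codes).
#'
#' @param sample_seq sample sequence in reference coordinates: either a
#'   full-length (16,569) string or the sequence of `covered`.
#' @param site an [rflp_site()].
#' @param reference an [mt_reference()].
#' @param covered covered interval(s) corresponding to `sample_seq`; default
#'   full genome.
#' @return `"present"`, `"absent"` or `"untyped"`.
#' @export
#' @examples
#' ref <- mt_reference()
#' insilico_rflp(ref$sequence, rflp_panel()[[4]], ref)
insilico_rflp <- function(sample_seq, site, reference = mt_reference(),
                          covered = c(1L, MT_LENGTH)) {
  covered <- as_intervals(covered)
  win_pos <- (site$anchor - 10L):(site$anchor + 10L)
  win_pos <- ((win_pos - 1L) %% MT_LENGTH) + 1L
  if (!all(position_in_covered(win_pos, covered))) return("untyped")
  cov_pos <- covered_positions(covered)
  chars <- strsplit(toupper(sample_seq), "")[[1]]
  if (length(chars) != length(cov_pos))
    stop("sample sequence length does not match covered span")
  win <- chars[match(win_pos, cov_pos)]
  if (any(!win %in% c("A", "C", "G", "T"))) return("untyped")
  hits <- Biostrings::matchPattern(site$recognition,
                                   Biostrings::DNAString(paste(win, collapse = "")),
                                   fixed = FALSE)
  anchor_idx <- 11L
  ok <- any(BiocGenerics::start(hits) <= anchor_idx &
              BiocGenerics::end(hits) >= anchor_idx)
  if (ok) "present" else "absent"
}

## ---- file formats ----------------------------------------------------------

#' Read / write FASTA
#'
#' Thin wrappers over Biostrings, writing 70-column wrapped FASTA.
#'
#' @param path file path.
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(s), names(s))
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  s <- Biostrings::DNAStringSet(seqs)
  names(s) <- names(seqs)
  Biostrings::writeXStringSet(s, path, width = 70L)
  invisible(path)
}

#' Read a variant table
#'
#' Tab-separated with header `SampleID, Range, Variants`: `Range` holds
#' semicolon-separated `a-b` intervals (wrap allowed), `Variants`
#' space-separated mutation tokens. Lines starting with `#` are comments.
#'
#' @param path file path.
#' @param reference an [mt_reference()].
#' @return list of [variant_profile()]s.
#' @export
read_variant_table <- function(path, reference = mt_reference()) {
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  if (!all(c("SampleID", "Range", "Variants") %in% names(d)))
    stop("variant table needs columns SampleID, Range, Variants")
  lapply(seq_len(nrow(d)), function(i) {
    ivs <- do.call(rbind, lapply(strsplit(d$Range[i], ";")[[1]], function(r) {
      as.integer(strsplit(trimws(r), "-")[[1]])
    }))
    variant_profile(d$SampleID[i], ivs,
                    parse_mutations(d$Variants[i], reference), reference)
  })
}

#' @rdname read_variant_table
#' @param profiles list of [variant_profile()]s.
#' @export
write_variant_table <- function(profiles, path) {
  rows <- vapply(profiles, function(p) {
    rng <- paste(apply(p$covered, 1, paste, collapse = "-"), collapse = ";")
    paste(p$sample_id, rng, format_tokens(p$mutations), sep = "\t")
  }, "")
  writeLines(c("SampleID\tRange\tVariants", rows), path, useBytes = TRUE)
  invisible(path)
}
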