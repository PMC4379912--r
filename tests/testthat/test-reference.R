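ref <- mt_reference()

test_that("reference model satisfies its invariants", {
  expect_length(ref$bases, 16569L)
  expect_true(all(ref$bases %in% c("A", "C", "G", "T")))
  expect_true(all(ref$genes$start >= 1 & ref$genes$end <= 16569))
  # 13 protein genes incl. light-strand ND6, 22 tRNA, 2 rRNA
  expect_equal(sum(ref$genes$kind == "protein"), 13L)
  expect_equal(sum(ref$genes$kind == "tRNA"), 22L)
  expect_equal(sum(ref$genes$kind == "rRNA"), 2L)
  expect_equal(ref$genes$strand[ref$genes$feature == "ND6"], "L")
})

test_that("mutation token grammar parses and classifies correctly", {
  m <- parse_mutation_token("16193.1C", ref)
  expect_equal(m$kind, "insertion")
  expect_equal(m$insertion_index, 1L)
  expect_equal(m$derived, "C")

  del <- parse_mutation_token("8281-8289d", ref)
  expect_equal(nrow(del), 9L)
  expect_equal(del$position, 8281:8289)
  expect_true(all(del$kind == "deletion"))

  # bare token: transition to the partner of the reference base
  tr <- parse_mutation_token("16172", ref)
  expect_equal(tr$ref, ref$bases[16172])
  expect_equal(tr$derived, c(A = "G", G = "A", C = "T", T = "C")[[tr$ref]])
  expect_equal(tr$kind, "transition")

  tv <- parse_mutation_token("16183C", ref)
  expect_equal(tv$kind, "transversion")

  back <- parse_mutation_token("@10398", ref)
  expect_true(back$back_mutation)
  expect_equal(back$derived, ref$bases[10398])

  expect_error(parse_mutation_token("17000", ref), "outside")
  expect_error(parse_mutation_token("banana", ref), "malformed")
  # derived equal to reference without '@'
  expect_error(parse_mutation_token(paste0("10398", ref$bases[10398]), ref))
})

test_that("format/parse round-trips over generated grammar-valid tokens", {
  set.seed(42)
  pos <- sample(setdiff(600:16000, 303:522), 120)
  tokens <- c(
    as.character(pos[1:40]),                                   # transitions
    paste0(pos[41:70], ifelse(ref$bases[pos[41:70]] %in% c("A", "G"),
                              ifelse(ref$bases[pos[41:70]] == "A", "C", "T"),
                              "G")),                           # transversions
    paste0("@", pos[71:90]),                                   # back mutations
    paste0(pos[91:105], "d"),                                  # deletions
    paste0(pos[106:120], ".1", sample(c("A", "C", "G", "T"), 15, TRUE)))
  for (tok in tokens) {
    m <- parse_mutation_token(tok, ref)
    expect_identical(format_mutation(m), tok)
    expect_identical(parse_mutation_token(format_mutation(m), ref), m)
  }
  # ranged deletions round-trip through the compact formatter
  expect_identical(format_tokens(parse_mutation_token("8281-8289d", ref)),
                   "8281-8289d")
})

test_that("call_variants recovers exact substitution sets (fuzz)", {
  # identity; a wrapped range reads 16024..16569 then 1..407
  cr <- c(16024:16569, 1:407)
  p0 <- call_variants(paste(ref$bases[cr], collapse = ""), c(16024, 407), ref)
  expect_equal(nrow(p0$mutations), 0L)

  # single transition at 16189
  s <- ref$bases[cr]
  i <- match(16189, cr)
  s[i] <- "C" # ref 16189 is T
  p1 <- call_variants(paste(s, collapse = ""), c(16024, 407), ref)
  expect_equal(p1$mutations$token, "16189")

  # fuzz: random substitution sets away from exclusion regions
  set.seed(7)
  for (rep in 1:10) {
    pos <- sort(sample(setdiff(1000:5000, 303:522), sample(1:8, 1)))
    s <- ref$bases
    s[pos] <- vapply(ref$bases[pos], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    p <- call_variants(paste(s, collapse = ""), c(1, 16569), ref)
    expect_equal(p$mutations$position, pos)
    expect_equal(p$mutations$derived, unname(s[pos]))
  }
})

test_that("call_variants places indels 3'-most and handles ambiguity", {
  # remove 8281-8289 (one copy of the CCCCCTCTA repeat): 3'-most placement
  s <- ref$bases[-(8281:8289)]
  p <- call_variants(paste(s, collapse = ""), c(1, 16569), ref)
  expect_equal(format_tokens(p$mutations), "8281-8289d")

  # ambiguity codes become uncovered positions, not calls
  s <- ref$bases
  s[2000] <- "N"
  s[3000] <- "R"
  p <- call_variants(paste(s, collapse = ""), c(1, 16569), ref)
  expect_equal(nrow(p$mutations), 0L)
  expect_false(any(position_in_covered(c(2000L, 3000L), p$covered)))
  expect_true(position_in_covered(2001L, p$covered))
})

test_that("functional classes follow the annotation and mito code", {
  m <- parse_mutations("10398G", ref)   # ND3 codon first position, A->G
  expect_equal(classify_mutation_function(m, ref), "ns")
  # tRNA and rRNA features
  expect_equal(classify_mutation_function(parse_mutations("600", ref), ref), "t")
  expect_equal(classify_mutation_function(parse_mutations("1000", ref), ref), "r")
  # intergenic positions inside 577-16023 (8270-8294 gap)
  expect_equal(classify_mutation_function(parse_mutations("8272", ref), ref), "nc")
  # control region and indels get their own classes, never s/ns
  expect_equal(classify_mutation_function(parse_mutations("16311", ref), ref),
               "control")
  expect_equal(classify_mutation_function(parse_mutations("3571d", ref), ref),
               "indel")
  # s/ns occur exactly at positions whose (first covering) feature is a
  # protein gene (property over random positions)
  set.seed(11)
  pos <- sample(577:16023, 200)
  m <- parse_mutations(as.character(pos), ref)
  cls <- classify_mutation_function(m, ref)
  first_kind <- vapply(pos, function(p) {
    hit <- which(ref$genes$start <= p & ref$genes$end >= p)
    if (length(hit) == 0) "none" else ref$genes$kind[hit[1]]
  }, "")
  expect_true(all(cls %in% c("s", "ns", "t", "r", "nc")))
  expect_equal(cls %in% c("s", "ns"), first_kind == "protein")
})

test_that("synonymous calls agree with an independent translation oracle", {
  # oracle: translate with Biostrings::translate on the H strand gene copy
  genes <- ref$genes[ref$genes$kind == "protein" & ref$genes$strand == "H", ]
  set.seed(3)
  for (i in 1:25) {
    g <- genes[sample(nrow(genes), 1), ]
    len3 <- (g$end - g$start + 1L) %/% 3L * 3L
    pos <- g$start + sample.int(len3, 1) - 1L
    b <- ref$bases[pos]
    alt <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
    cds <- ref$bases[g$start:(g$start + len3 - 1L)]
    aa0 <- as.character(Biostrings::translate(
      Biostrings::DNAString(paste(cds, collapse = "")),
      genetic.code = Biostrings::getGeneticCode("2")))
    cds[pos - g$start + 1L] <- alt
    aa1 <- as.character(Biostrings::translate(
      Biostrings::DNAString(paste(cds, collapse = "")),
      genetic.code = Biostrings::getGeneticCode("2")))
    m <- parse_mutations(paste0(pos, alt), ref)
    expect_equal(classify_mutation_function(m, ref),
                 if (aa0 == aa1) "s" else "ns",
                 info = paste(g$feature, pos, b, alt))
  }
})

test_that("exclusion filter drops exactly the conventional sites", {
  p <- variant_profile("S", c(16024, 576),
                       "16182C 16183C 16189 16519", ref)
  expect_equal(apply_exclusion_filter(p)$mutations$token, "16189")

  p2 <- variant_profile("S2", c(1, 16569), "309.1C 315.1C 16223", ref)
  expect_equal(apply_exclusion_filter(p2)$mutations$token, "16223")

  p3 <- variant_profile("S3", c(1, 16569), parse_mutations(character(), ref), ref)
  expect_equal(nrow(apply_exclusion_filter(p3)$mutations), 0L)

  # non-excluded indels survive; 16519 dropped regardless of state
  p4 <- variant_profile("S4", c(1, 16569), "8281-8289d 16519 522d", ref)
  expect_equal(format_tokens(apply_exclusion_filter(p4)$mutations),
               "8281-8289d")
})

test_that("in-silico RFLP agrees with an independent IUPAC matcher", {
  # packaged reference at each panel site, both routes
  for (site in rflp_panel()) {
    got <- insilico_rflp(ref$sequence, site, ref)
    win <- paste(ref$bases[(site$anchor - 10):(site$anchor + 10)], collapse = "")
    hits <- iupac_occurrences(site$recognition, win)
    want <- if (any(hits <= 11 & hits + nchar(site$recognition) - 1 >= 11))
      "present" else "absent"
    expect_equal(got, want, info = site$label)
  }
  # the pinned AluI site at 5176 is present and destroyed by 5178A
  alu <- rflp_panel()[[2]]
  expect_equal(insilico_rflp(ref$sequence, alu, ref), "present")
  s <- ref$bases; s[5178] <- "A"
  expect_equal(insilico_rflp(paste(s, collapse = ""), alu, ref), "absent")
  # window not covered -> untyped
  expect_equal(insilico_rflp(paste(ref$bases[1:576], collapse = ""), alu, ref,
                             covered = c(1, 576)), "untyped")
})

test_that("variant table and FASTA round-trip", {
  p1 <- variant_profile("A1", c(16024, 407), "16172 16311", ref)
  p2 <- variant_profile("A2", rbind(c(16024, 16569), c(1, 600)),
                        "16189 73 489", ref)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(list(p1, p2), tf)
  back <- read_variant_table(tf, ref)
  expect_equal(back[[1]]$mutations$token, p1$mutations$token)
  # the writer emits tokens in position order
  expect_setequal(back[[2]]$mutations$token, p2$mutations$token)
  expect_equal(back[[1]]$covered, p1$covered)

  ff <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(c(s1 = "ACGTACGT"), ff)
  expect_equal(unname(read_fasta(ff)), "ACGTACGT")
})
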