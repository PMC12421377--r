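test_that("a hand-countable annotation parses with correct ordinals and strands", {
  dir <- withr::local_tempdir()
  fx <- write_tiny_gff3_fixture(dir)
  parsed <- parse_annotation(fx$gff3, fasta = fx$fasta)
  f <- parsed$features
  expect_equal(nrow(f), 4)
  expect_equal(sum(skip_report(parsed)), 0)
  f <- f[order(f$transcript_id, f$ordinal), ]
  expect_equal(f$transcript_id, c("T1", "T2", "T2", "T3"))
  expect_equal(f$hexamer, c("AAUAAA", "AAUAAA", "AUUAAA", "AACAAA"))
  expect_equal(f$ordinal, c(1L, 1L, 2L, 1L))
  expect_equal(f$n_on_transcript, c(1L, 2L, 2L, 1L))
  # the minus-strand hexamer was read through the reverse complement
  expect_equal(f$strand, c("+", "+", "+", "-"))
})

test_that("minus-strand features reverse-complement plus-strand DNA", {
  dir <- withr::local_tempdir()
  writeLines(c(">chr1", strrep("G", 10), "TTTATTGGGG"),
             file.path(dir, "g.fasta"))
  writeLines(c("##gff-version 3",
               "chr1\ttest\tmRNA\t1\t20\t.\t-\t.\tID=TX",
               "chr1\ttest\tpolyA_signal_sequence\t11\t16\t.\t-\t.\tParent=TX"),
             file.path(dir, "g.gff3"))
  parsed <- parse_annotation(file.path(dir, "g.gff3"),
                             fasta = file.path(dir, "g.fasta"))
  expect_equal(parsed$features$hexamer, "AAUAAA")
})

test_that("census percentages match hand computation on the tiny fixture", {
  dir <- withr::local_tempdir()
  fx <- write_tiny_gff3_fixture(dir)
  tabs <- census(parse_annotation(fx$gff3, fasta = fx$fasta))
  all_t <- tabs$all
  expect_equal(sum(all_t$count), 4)
  expect_equal(all_t$percent[all_t$hexamer == "AAUAAA"], 50)
  expect_equal(all_t$percent[all_t$hexamer == "AUUAAA"], 25)
  expect_equal(all_t$percent[all_t$hexamer == "AACAAA"], 25)
  single <- tabs$single
  expect_equal(sort(single$percent), c(50, 50))
  # a two-signal transcript contributes to first and last, never intermediate
  expect_equal(sum(tabs$first$count), 1)
  expect_equal(sum(tabs$last$count), 1)
  expect_equal(nrow(tabs$intermediate), 0)
  expect_equal(tabs$first$hexamer, "AAUAAA")
  expect_equal(tabs$last$hexamer, "AUUAAA")
})

test_that("census handles empty annotation without error", {
  dir <- withr::local_tempdir()
  writeLines(c(">c1", "ACGTACGT"), file.path(dir, "e.fasta"))
  writeLines("##gff-version 3", file.path(dir, "e.gff3"))
  parsed <- parse_annotation(file.path(dir, "e.gff3"),
                             fasta = file.path(dir, "e.fasta"))
  expect_equal(nrow(parsed$features), 0)
  tabs <- census(parsed)
  expect_equal(sum(tabs$all$count), 0)
})

test_that("generated corpora parse back to their ground truth in both dialects", {
  dir <- withr::local_tempdir()
  spec <- corpus_spec(120, hexamer_probs = hexamer_probs(), seed = 77)
  corp <- generate_corpus(spec, dir)
  pg <- parse_annotation(corp$gff3, fasta = corp$fasta)
  pb <- parse_annotation(corp$genbank)
  cols <- c("transcript_id", "hexamer", "ordinal", "n_on_transcript",
            "chrom", "start", "end", "strand")
  norm <- function(df) {
    df <- df[order(df$transcript_id, df$ordinal), cols]
    rownames(df) <- NULL
    df
  }
  expect_equal(norm(pg$features), norm(corp$truth))
  expect_equal(norm(pb$features), norm(corp$truth))
  # the two dialects of one corpus give identical census tables
  expect_identical(census(pg), census(pb))
  # the same spec regenerates the identical corpus
  corp2 <- generate_corpus(spec, withr::local_tempdir())
  expect_identical(corp$truth, corp2$truth)
})

test_that("census is invariant to annotation record order", {
  dir <- withr::local_tempdir()
  spec <- corpus_spec(60, hexamer_probs = hexamer_probs(), seed = 5)
  corp <- generate_corpus(spec, dir)
  lines <- readLines(corp$gff3)
  body <- lines[!grepl("^#", lines)]
  set.seed(1)
  shuffled <- file.path(dir, "shuffled.gff3")
  writeLines(c("##gff-version 3", sample(body)), shuffled)
  expect_identical(census(parse_annotation(shuffled, fasta = corp$fasta)),
                   census(parse_annotation(corp$gff3, fasta = corp$fasta)))
})

test_that("an all-minus corpus reads entirely through the reverse complement", {
  spec <- corpus_spec(80, hexamer_probs = hexamer_probs(),
                      strand_fraction_minus = 1, seed = 9)
  corp <- generate_corpus(spec, withr::local_tempdir())
  parsed <- parse_annotation(corp$gff3, fasta = corp$fasta)
  expect_true(all(parsed$features$strand == "-"))
  expect_equal(sort(parsed$features$hexamer), sort(corp$truth$hexamer))
})

test_that("the legacy polyA_signal dialect is recognised", {
  spec <- corpus_spec(40, hexamer_probs = hexamer_probs(), seed = 13)
  dir <- withr::local_tempdir()
  corp <- generate_corpus(spec, dir, legacy_dialect = TRUE)
  pg <- parse_annotation(corp$gff3, fasta = corp$fasta)
  pb <- parse_annotation(corp$genbank)
  expect_equal(nrow(pg$features), nrow(corp$truth))
  expect_identical(census(pg), census(pb))
})

test_that("malformed features land in the skip report, not the counts", {
  dir <- withr::local_tempdir()
  fx <- write_tiny_gff3_fixture(dir)
  lines <- readLines(fx$gff3)
  # inject a 5-nt signal and a parentless, uncontained orphan
  writeLines(c(lines,
               "T1\ttest\tregulatory_region\t41\t45\t.\t+\t.\tParent=T1;regulatory_class=polyA_signal_sequence",
               "T1\ttest\tpolyA_signal_sequence\t54\t59\t.\t+\t.\tID=stray"),
             fx$gff3)
  parsed <- parse_annotation(fx$gff3, fasta = fx$fasta)
  rep <- skip_report(parsed)
  expect_equal(unname(rep["length_mismatch"]), 1L)
  expect_equal(unname(rep["orphan"]), 1L)
  # orphans are kept on a synthetic singleton transcript
  expect_equal(nrow(parsed$features), 5)
  expect_true(any(grepl("^orphan_", parsed$features$transcript_id)))
})

test_that("genomic deduplication collapses isoform-shared signals", {
  dir <- withr::local_tempdir()
  writeLines(c(">chr1", strrep("A", 14), "AATAAA", strrep("A", 20)),
             file.path(dir, "d.fasta"))
  writeLines(c("##gff-version 3",
               "chr1\ttest\tmRNA\t1\t40\t.\t+\t.\tID=iso1",
               "chr1\ttest\tmRNA\t5\t40\t.\t+\t.\tID=iso2",
               "chr1\ttest\tpolyA_signal_sequence\t15\t20\t.\t+\t.\tParent=iso1",
               "chr1\ttest\tpolyA_signal_sequence\t15\t20\t.\t+\t.\tParent=iso2"),
             file.path(dir, "d.gff3"))
  per_tx <- parse_annotation(file.path(dir, "d.gff3"),
                             fasta = file.path(dir, "d.fasta"))
  expect_equal(nrow(per_tx$features), 2)
  dedup <- parse_annotation(file.path(dir, "d.gff3"),
                            fasta = file.path(dir, "d.fasta"),
                            dedupe_genomic = TRUE)
  expect_equal(nrow(dedup$features), 1)
  expect_equal(dedup$features$hexamer, "AAUAAA")
})

test_that("first/last strata totals equal the number of multi-signal transcripts", {
  spec <- corpus_spec(150, hexamer_probs = hexamer_probs(), seed = 31)
  corp <- generate_corpus(spec, withr::local_tempdir())
  tabs <- census(parse_annotation(corp$gff3, fasta = corp$fasta))
  n_multi <- length(unique(corp$truth$transcript_id[corp$truth$n_on_transcript >= 2]))
  expect_equal(sum(tabs$first$count), n_multi)
  expect_equal(sum(tabs$last$count), n_multi)
  expect_equal(sum(tabs$all$count), nrow(corp$truth))
  for (t in tabs) if (nrow(t)) expect_equal(sum(t$percent), 100, tolerance = 1e-6)
})
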