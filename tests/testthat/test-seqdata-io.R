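test_that("FASTA reading uppercases, tokenizes headers and validates", {
  tf <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">iso1 extra words", "acgt", ">iso2", "ACGT"), tf)
  rec <- read_locus_fasta(tf, "l1")
  expect_equal(rec$isolate_id, c("iso1", "iso2"))
  expect_equal(rec$sequence, c("ACGT", "ACGT"))

  empty <- withr::local_tempfile(fileext = ".fasta")
  file.create(empty)
  expect_warning(rec0 <- read_locus_fasta(empty, "l1"), "empty")
  expect_equal(nrow(rec0), 0)

  dup <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">a", "ACGT"), dup)
  expect_error(read_locus_fasta(dup, "l1"), class = "mlstkit_duplicate_error")

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACXT"), bad)
  err <- expect_error(read_locus_fasta(bad, "l1"), class = "mlstkit_alphabet_error")
  expect_match(conditionMessage(err), "'X' at position 3.*'a'")
})

test_that("locus FASTA round-trips exactly", {
  withr::with_seed(7, {
    rec <- tibble::tibble(
      isolate_id = sprintf("iso%02d", 1:9),
      locus = "lx",
      sequence = random_alignment(9, 50, n_rate = 0.02)
    )
  })
  tf <- withr::local_tempfile(fileext = ".fasta")
  write_locus_fasta(rec, tf)
  back <- read_locus_fasta(tf, "lx")
  expect_equal(back, rec)
})

test_that("validate_and_trim enforces strict lengths and trims to shortest", {
  loci <- locus_table("l1", 10)
  seqs <- tibble::tibble(
    isolate_id = c("a", "b"), locus = "l1",
    sequence = c("ACGTACGTAC", "ACGTACGTACGT")
  )
  err <- expect_error(
    validate_and_trim(seqs, loci, "strict"),
    class = "mlstkit_length_error"
  )
  expect_match(conditionMessage(err), "b")

  trimmed <- validate_and_trim(seqs, loci, "trim_to_shortest")
  expect_equal(nchar(trimmed$sequence), c(10L, 10L))
  expect_equal(attr(trimmed, "loci")$fragment_length, 10L)

  ok <- validate_and_trim(
    tibble::tibble(isolate_id = "a", locus = "l1", sequence = "ACGTACGTAC"),
    loci, "strict"
  )
  expect_equal(ok$sequence, "ACGTACGTAC")

  short <- tibble::tibble(
    isolate_id = c("a", "b"), locus = "l1",
    sequence = c("ACGTAC", "ACGT")
  )
  expect_error(
    validate_and_trim(short, loci, "trim_to_shortest"),
    class = "mlstkit_degenerate_locus_error"
  )
})

test_that("build_mlst_dataset enforces a complete matrix and drops stragglers", {
  seqs <- tibble::tibble(
    isolate_id = c("a", "b", "c", "a", "b"),
    locus = c("l1", "l1", "l1", "l2", "l2"),
    sequence = c(rep("ATGAAAGGG", 3), rep("ATGCCCTTT", 2))
  )
  expect_warning(d <- build_mlst_dataset(seqs), "incomplete")
  expect_equal(sort(unique(d$sequences$isolate_id)), c("a", "b"))
  expect_equal(attr(d, "rejected"), "c")

  only_one_locus <- dplyr::filter(seqs, isolate_id == "c")
  d2 <- build_mlst_dataset(only_one_locus)
  expect_equal(nrow(d2$loci), 1)

  expect_error(
    build_mlst_dataset(seqs[0, ]),
    class = "mlstkit_empty_dataset"
  )
})

test_that("build_mlst_dataset is invariant to input record order", {
  seqs <- tibble::tibble(
    isolate_id = rep(c("a", "b", "c"), 2),
    locus = rep(c("l1", "l2"), each = 3),
    sequence = c(
      "ATGAAAGGG", "ATGAAAGGC", "ATGAAAGGT",
      "ATGCCCTTT", "ATGCCGTTT", "ATGCCCTTT"
    )
  )
  d1 <- build_mlst_dataset(seqs)
  withr::with_seed(3, shuffled <- seqs[sample(nrow(seqs)), ])
  d2 <- build_mlst_dataset(shuffled)
  expect_equal(d1$sequences, d2$sequences)
  expect_equal(d1$loci, d2$loci)
})

test_that("frame offsets are auto-detected from stop-free frames", {
  # ATG AAA TAA in frame 0 has a stop; prepending one base shifts to a
  # stop-free frame 1
  seqs <- tibble::tibble(
    isolate_id = c("a", "b"), locus = "l1",
    sequence = c("GATGAAACCCT", "GATGAAACCGT")
  )
  d <- build_mlst_dataset(seqs)
  expect_equal(d$loci$frame_offset, detect_frame_offset(seqs$sequence))
  expect_equal(count_stops(substring(seqs$sequence, d$loci$frame_offset + 1)), c(0L, 0L))
})

test_that("concatenation respects locus order, lengths and boundaries", {
  d <- tiny_dataset()
  aln <- concatenate_loci(d)
  expect_s3_class(aln, "mlst_alignment")
  expect_equal(unique(nchar(aln$sequence)), sum(d$loci$fragment_length))
  b <- attr(aln, "boundaries")
  expect_equal(b$start, c(0L, 9L))
  expect_equal(b$end, c(9L, 21L))
  # rebuilding each locus from the boundaries recovers the originals
  for (i in seq_len(nrow(b))) {
    part <- substr(aln$sequence, b$start[i] + 1, b$end[i])
    orig <- locus_seqs(d, b$locus[i])[aln$id]
    expect_equal(part, unname(orig))
  }

  p <- assign_profiles(d)
  aln_st <- concatenate_loci(d, "per_st", p)
  expect_equal(nrow(aln_st), nrow(p$profiles))
  expect_error(concatenate_loci(d, "per_st"), "ProfileTable")

  one <- build_mlst_dataset(dplyr::filter(d$sequences, locus == "l1"))
  aln1 <- concatenate_loci(one)
  expect_equal(unname(sort(aln1$sequence)), unname(sort(locus_seqs(one, "l1"))))
})

test_that("metadata reader validates columns and parses flags", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "isolate_id\tsource\tregion\tis_reference",
    "a\tpickle\tSichuan\tTRUE", "b\tdairy\tXinjiang\tfalse"
  ), tf)
  md <- read_isolate_metadata(tf)
  expect_equal(md$is_reference, c(TRUE, FALSE))
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("isolate_id\tsource", "a\tpickle"), bad)
  expect_error(read_isolate_metadata(bad), "missing columns")
})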