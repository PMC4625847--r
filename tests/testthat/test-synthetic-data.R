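small_loci <- function() {
  locus_table(c("gA", "gB", "gC"), c(120L, 90L, 150L), frame_offset = 0L)
}

test_that("zero-rate simulations are perfectly clonal within founders", {
  sim <- simulate_population(sim_config(
    n_isolates = 10, loci = small_loci(), n_founders = 1,
    mutation_rate = 0, recombination_rate = 0, founder_divergence = 0,
    generations = 10, seed = 2
  ))
  p <- assign_profiles(sim$dataset)
  expect_equal(nrow(p$profiles), 1)
  aln <- concatenate_loci(sim$dataset)
  expect_equal(length(unique(aln$sequence)), 1)
  expect_equal(nrow(sim$truth$mutation_log), 0)
  expect_equal(nrow(sim$truth$recombination_log), 0)
})

test_that("simulations are bit-identical under the same seed", {
  cfg <- sim_config(
    n_isolates = 20, loci = small_loci(), n_founders = 3,
    mutation_rate = 1e-4, recombination_rate = 0.05, generations = 10, seed = 33
  )
  s1 <- simulate_population(cfg)
  s2 <- simulate_population(cfg)
  expect_identical(s1$dataset$sequences, s2$dataset$sequences)
  expect_identical(s1$truth$mutation_log, s2$truth$mutation_log)
  expect_identical(s1$truth$recombination_log, s2$truth$recombination_log)
  s3 <- simulate_population(sim_config(
    n_isolates = 20, loci = small_loci(), n_founders = 3,
    mutation_rate = 1e-4, recombination_rate = 0.05, generations = 10, seed = 34
  ))
  expect_false(identical(s1$dataset$sequences, s3$dataset$sequences))
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(n_isolates = 5, seed = NULL), "seed")
  expect_error(sim_config(n_isolates = 0, seed = 1), "at least one")
  expect_error(sim_config(n_isolates = 3, n_founders = 5, seed = 1), "n_founders")
  expect_error(sim_config(mutation_rate = 2, seed = 1), "rates")
  expect_error(sim_config(titv_ratio = 0, seed = 1), "titv")
})

test_that("mutate_sequence honours rate, titv kernel and coding guard", {
  s <- strrep("ATGAAACCC", 10)
  expect_identical(as.character(mutate_sequence(s, 0)), s)

  withr::with_seed(9, {
    # rate 1 with huge titv: every site transitions (A<->G, C<->T)
    out <- mutate_sequence("ACGT", 1, titv_ratio = 1e12)
    expect_equal(as.character(out), "GTAC")

    # empirical ti/tv over many mutated sites approximates the ratio
    long <- paste(sample(c("A", "C", "G", "T"), 2e4, replace = TRUE), collapse = "")
    mut <- mutate_sequence(long, 1, titv_ratio = 2)
    ev <- attr(mut, "events")
    is_ti <- mlstkit:::TRANSITION[ev$from] == ev$to
    phat <- mean(is_ti)
    se <- sqrt(phat * (1 - phat) / length(is_ti))
    expect_lt(abs(phat - 2 / 3), 3 * se)
  })

  # coding guard: in TAT (Tyr), the only mutations at position 3 are
  # TAC (Tyr) and the stops TAA/TAG, so with transversions forbidden from
  # being stops the site can only move to C
  withr::with_seed(4, {
    for (r in 1:20) {
      out <- mutate_sequence("TAT", 1, titv_ratio = 1, coding_guard = TRUE)
      expect_false(mlstkit:::is_stop_codon(as.character(out)))
    }
  })
})

test_that("recombination replaces whole loci and logs every event", {
  sim <- simulate_population(sim_config(
    n_isolates = 6, loci = small_loci(), n_founders = 2,
    mutation_rate = 0, recombination_rate = 0, founder_divergence = 0.05,
    generations = 1, seed = 12
  ))
  seqs <- sim$dataset$sequences
  withr::with_seed(3, res0 <- apply_recombination(seqs, 0))
  expect_equal(nrow(res0$events), 0)
  expect_equal(res0$sequences$sequence, arrange(seqs, locus, isolate_id)$sequence)

  two <- dplyr::filter(seqs, isolate_id %in% c("iso1", "iso2"))
  withr::with_seed(8, res1 <- apply_recombination(two, 1))
  expect_equal(nrow(res1$events), 2)
  # every transferred locus now matches some other isolate's allele
  for (k in seq_len(nrow(res1$events))) {
    ev <- res1$events[k, ]
    rec_seq <- res1$sequences$sequence[
      res1$sequences$isolate_id == ev$recipient &
        res1$sequences$locus == ev$locus
    ]
    donor_pool <- seqs$sequence[seqs$locus == ev$locus]
    expect_true(rec_seq %in% donor_pool)
  }
})

test_that("event logs replay to the emitted dataset exactly", {
  sim <- simulate_population(sim_config(
    n_isolates = 25, loci = small_loci(), n_founders = 3,
    mutation_rate = 2e-4, recombination_rate = 0.1, generations = 12, seed = 66
  ))
  replayed <- replay_truth(sim$truth)
  expect_identical(replayed$sequence, sim$dataset$sequences$sequence)
  expect_identical(replayed$isolate_id, sim$dataset$sequences$isolate_id)
})

test_that("without recombination the SLV graph respects the genealogy", {
  # founders far apart (profile distance 3 of 3 loci), so SLV pairs must
  # share a founder
  sim <- simulate_population(sim_config(
    n_isolates = 30, loci = small_loci(), n_founders = 3,
    founder_divergence = 0.05, mutation_rate = 5e-5,
    recombination_rate = 0, generations = 10, seed = 19
  ))
  p <- assign_profiles(sim$dataset)
  fo <- sim$truth$founder_assignment
  st_founder <- p$membership |>
    dplyr::left_join(fo, by = "isolate_id") |>
    dplyr::distinct(st, founder)
  expect_equal(nrow(st_founder), nrow(p$profiles)) # no ST spans founders
  m <- mlstkit:::profile_matrix(p)
  for (i in seq_len(nrow(m) - 1)) {
    for (j in (i + 1):nrow(m)) {
      if (sum(m[i, ] != m[j, ]) == 1) {
        expect_equal(
          st_founder$founder[st_founder$st == i],
          st_founder$founder[st_founder$st == j]
        )
      }
    }
  }
})

test_that("coding sequences stay stop-free with the guard on", {
  sim <- simulate_population(sim_config(
    n_isolates = 15, loci = small_loci(), n_founders = 2,
    mutation_rate = 5e-4, generations = 10, seed = 8
  ))
  expect_equal(sum(mlstkit:::count_stops(sim$dataset$sequences$sequence)), 0L)
})

test_that("simulated datasets write to the standard input layout and reload", {
  sim <- simulate_population(sim_config(
    n_isolates = 8, loci = small_loci(), n_founders = 2,
    mutation_rate = 1e-4, generations = 5, seed = 51
  ))
  dir <- withr::local_tempdir()
  write_simulated_dataset(sim, dir)
  expect_setequal(
    list.files(dir),
    c("gA.fasta", "gB.fasta", "gC.fasta", "metadata.tsv", "truth.json")
  )
  seqs <- dplyr::bind_rows(lapply(c("gA", "gB", "gC"), function(l) {
    read_locus_fasta(file.path(dir, paste0(l, ".fasta")), l)
  }))
  meta <- read_isolate_metadata(file.path(dir, "metadata.tsv"))
  d2 <- build_mlst_dataset(seqs, meta)
  expect_equal(d2$sequences, sim$dataset$sequences)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_equal(truth$config$seed, 51)
})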