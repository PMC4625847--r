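test_that("polymorphic sites require two distinct determined bases", {
  expect_equal(count_polymorphic_sites(c("AAAA", "AAAT")), list(n = 1L, sites = 3L))
  expect_equal(count_polymorphic_sites(c("AAAA", "AAAN"))$n, 0L)
  expect_equal(count_polymorphic_sites(c("ANAA", "ATAA", "ACAA"))$n, 1L)
  expect_error(count_polymorphic_sites("ACGT"), "single")
})

test_that("nucleotide diversity matches hand-enumerated pairs and a brute-force oracle", {
  expect_equal(nucleotide_diversity(c("AAAA", "AAAT")), 0.25)
  expect_equal(nucleotide_diversity(c("AAAA", "AAAT", "AAAT")), (1 + 1 + 0) / 3 / 4)
  withr::with_seed(101, {
    for (r in 1:40) {
      n <- sample(2:20, 1)
      seqs <- random_alignment(n, sample(10:40, 1), n_rate = 0.05)
      expect_equal(nucleotide_diversity(seqs), oracle_pi(seqs), tolerance = 1e-12)
    }
  })
  # pairs sharing no comparable sites are excluded with a warning
  expect_warning(
    pi3 <- nucleotide_diversity(c("NNAA", "AANN", "AAAA")),
    "no comparable sites"
  )
  expect_equal(pi3, 0)
})

test_that("concatenated pi is the length-weighted mean of per-locus pi on N-free data", {
  sim <- simulate_population(sim_config(
    n_isolates = 15, n_founders = 3,
    mutation_rate = 1e-4, generations = 10, seed = 5
  ))
  d <- sim$dataset
  per <- vapply(d$loci$locus, function(l) {
    nucleotide_diversity(locus_seqs(d, l))
  }, numeric(1))
  lens <- d$loci$fragment_length
  concat <- nucleotide_diversity(concatenate_loci(d))
  expect_equal(concat, sum(per * lens) / sum(lens), tolerance = 1e-12)
})

test_that("G+C content pools bases and rejects all-N input", {
  expect_equal(gc_content("GCGC"), 100)
  expect_equal(gc_content("ATGC"), 50)
  expect_equal(gc_content(c("AT", "GC")), 50)
  expect_equal(gc_content("ATNN"), 0)
  expect_error(gc_content("NNNN"), "all N")
})

test_that("SNP sites classify via observed codon pairs, allowing dual labels", {
  s <- classify_snp_sites(c("TTTAAA", "TTCAAA"))
  expect_equal(s$n_ssnp, 1L)
  expect_equal(s$n_nsnp, 0L)

  n <- classify_snp_sites(c("TTTAAA", "ATTAAA"))
  expect_equal(n$n_ssnp, 0L)
  expect_equal(n$n_nsnp, 1L)

  # CTA(Leu) / CTG(Leu) / ATG(Met): third-position site is synonymous via
  # CTA/CTG; first-position site nonsynonymous via CTG/ATG; with CTA vs ATA
  # (Ile) the first site is nonsynonymous only, but adding ATA(Ile)/ATG(Met)
  # makes the third site both synonymous (CTA/CTG) and nonsynonymous (ATA/ATG)
  both <- classify_snp_sites(c("CTA", "CTG", "ATG", "ATA"))
  lab3 <- both$labels[both$labels$site == 2, ]
  expect_true(lab3$synonymous && lab3$nonsynonymous)
  poly <- count_polymorphic_sites(c("CTA", "CTG", "ATG", "ATA"))
  expect_gte(both$n_ssnp + both$n_nsnp, poly$n)

  # incomplete terminal codon is skipped with a warning
  expect_warning(
    term <- classify_snp_sites(c("TTTA", "TTTG")),
    "terminal"
  )
  expect_equal(term$n_ssnp + term$n_nsnp, 0L)

  # a stop codon in the dominant frame is a frame error
  expect_error(
    classify_snp_sites(c("TAATTT", "TAATTC")),
    class = "mlstkit_frame_error"
  )
})

test_that("Nei-Gojobori handles canonical single-codon cases", {
  syn <- suppressWarnings(nei_gojobori(c("TTT", "TTC")))
  expect_equal(syn$dn, 0)
  expect_equal(syn$dnds, 0)

  ident <- nei_gojobori(c("TTTAAA", "TTTAAA"))
  expect_equal(ident$status, "degenerate")
  expect_equal(ident$dnds, 0)

  # nonsynonymous-only divergence: dS = 0 < dN, ratio undefined, flagged
  nonsyn <- nei_gojobori(c("TTTAAA", "ATTAAA"))
  expect_equal(nonsyn$ds, 0)
  expect_gt(nonsyn$dn, 0)
  expect_true(is.na(nonsyn$dnds))
  expect_equal(nonsyn$status, "undefined")
})

test_that("Nei-Gojobori proportions and correction match a hand computation", {
  # GGG (Gly) vs GGA (Gly) + shared AAA (Lys): GGN third position is
  # fourfold degenerate (1 synonymous site); AAA contributes 1/3
  # (only AAA->AAG is synonymous; the TAA change is a stop, excluded).
  # Sd = 1, S_bar = 1 + 1/3 per sequence -> p_S = 3/4 exactly, which
  # saturates the Jukes-Cantor correction; uncorrected mode returns it raw.
  raw <- nei_gojobori(c("GGGAAA", "GGAAAA"), correction = "none")
  aaa_s <- 1 / 3
  expect_equal(raw$ds, 1 / (1 + aaa_s), tolerance = 1e-12)
  expect_equal(raw$dn, 0)

  # ten Lys codons; one synonymous change (AAA->AAG) and one
  # nonsynonymous change (AAA->GAA, Lys->Glu): Sd = Nd = 1,
  # S_bar = 10/3 (every codon has synonymous fraction 1/3)
  s1 <- strrep("AAA", 10)
  s2 <- s1
  substr(s2, 3, 3) <- "G"
  substr(s2, 4, 4) <- "G"
  s_bar <- 10 / 3
  n_bar <- 30 - s_bar
  raw2 <- nei_gojobori(c(s1, s2), correction = "none")
  expect_equal(raw2$ds, 1 / s_bar, tolerance = 1e-12)
  expect_equal(raw2$dn, 1 / n_bar, tolerance = 1e-12)

  # Jukes-Cantor correction applied to the same proportions
  jc <- nei_gojobori(c(s1, s2))
  expect_equal(jc$ds, -0.75 * log(1 - 4 * (1 / s_bar) / 3), tolerance = 1e-12)
  expect_equal(jc$dn, -0.75 * log(1 - 4 * (1 / n_bar) / 3), tolerance = 1e-12)
  expect_equal(jc$dnds, jc$dn / jc$ds, tolerance = 1e-12)
})

test_that("synonymous-only pressure keeps dN at zero; nonsynonymous pressure raises dnds", {
  # mutate only fourfold-degenerate third positions: all changes synonymous
  base <- strrep("GGT", 20)
  withr::with_seed(55, {
    variants <- vapply(1:6, function(i) {
      s <- base
      idx <- sample(1:20, 3)
      for (k in idx) {
        pos <- 3 * k
        substr(s, pos, pos) <- sample(c("A", "C", "G", "T"), 1)
      }
      s
    }, character(1))
  })
  res <- nei_gojobori(variants)
  expect_equal(res$dn, 0)

  # increasing the fraction of first-position (nonsynonymous) changes
  # raises dnds monotonically
  make_set <- function(n_first) {
    s1 <- strrep("GGT", 30)
    s2 <- s1
    # synonymous changes at third positions
    for (k in seq_len(6 - n_first)) {
      pos <- 3 * k
      substr(s2, pos, pos) <- "A"
    }
    # nonsynonymous changes at first positions (GGT->TGT, Gly->Cys)
    for (k in seq_len(n_first)) {
      pos <- 3 * (10 + k) - 2
      substr(s2, pos, pos) <- "T"
    }
    c(s1, s2)
  }
  ratios <- vapply(0:4, function(nf) {
    r <- nei_gojobori(make_set(nf))
    r$dnds
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("the diversity report is internally consistent", {
  sim <- simulate_population(sim_config(
    n_isolates = 20, n_founders = 3,
    mutation_rate = 5e-5, generations = 10, seed = 3
  ))
  p <- assign_profiles(sim$dataset)
  rep <- diversity_report(sim$dataset, p)
  expect_s3_class(rep, "mlst_diversity")
  expect_equal(nrow(rep), nrow(sim$dataset$loci) + 1)
  per <- dplyr::filter(rep, locus != "concatenated")
  conc <- dplyr::filter(rep, locus == "concatenated")
  # allele counts come from the catalogs
  expect_equal(
    per$n_alleles,
    as.integer(table(factor(p$catalogs$locus, levels = sim$dataset$loci$locus)))
  )
  # per-locus polymorphic sites add up to the concatenated count (N-free data)
  expect_equal(sum(per$n_polymorphic_sites), conc$n_polymorphic_sites)
  expect_equal(sum(per$n_ssnp), conc$n_ssnp)
  expect_true(all(per$pi >= 0 & per$pi <= 1))
  expect_true(all(per$n_polymorphic_sites <= per$length_bp))
  expect_true(all(per$n_ssnp <= per$n_polymorphic_sites))
  expect_true(all(per$n_nsnp <= per$n_polymorphic_sites))

  tf <- withr::local_tempfile(fileext = ".tsv")
  write_diversity_report(rep, tf)
  tab <- read.delim(tf)
  expect_equal(names(tab)[1:4], c("locus", "length_bp", "n_alleles", "n_polymorphic_sites"))
  expect_equal(nrow(tab), nrow(rep))

  # ST-deduplicated mode uses one representative per ST
  rep_st <- diversity_report(sim$dataset, p, unit = "sts")
  expect_equal(nrow(rep_st), nrow(rep))
})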