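# Seeded simulator of clonal bacterial populations for MLST method
# validation: founder genotypes diverge from a common ancestor, descendants
# accumulate titv-weighted point mutations, and whole-locus recombination
# occasionally replaces one locus with another isolate's allele. Every event
# is logged so the emitted dataset can be replayed exactly from the truth
# record.

#' Simulation configuration
#'
#' Defaults mirror the shape of a natural *L. plantarum* MLST study
#' population: 186 isolates typed at the eight study loci (415-641 bp,
#' protein coding), ten planted founder lineages with sizes decaying
#' harmonically (the largest complex dominates), rare point mutation and
#' occasional whole-locus exchange.
#'
#' @param n_isolates Number of isolates.
#' @param loci Locus-definition tibble (see [locus_table()]); frame offsets
#'   default to 0.
#' @param n_founders Number of planted founder lineages (clonal complexes).
#' @param founder_divergence Expected per-site divergence of each founder
#'   from the common ancestral sequence.
#' @param mutation_rate Per-site per-generation substitution probability.
#' @param titv_ratio Transition/transversion ratio of the mutation kernel.
#' @param recombination_rate Per-isolate per-generation probability of
#'   replacing one uniformly chosen locus with the same locus from a
#'   uniformly chosen other isolate.
#' @param generations Number of generations of within-lineage evolution.
#' @param coding_guard Reject mutations that would create an in-frame stop
#'   codon (applies to founder divergence as well).
#' @param seed Integer seed; mandatory, echoed in all outputs.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_isolates = 186L, loci = lp_study_loci(),
                       n_founders = 10L, founder_divergence = 0.003,
                       mutation_rate = 4e-6, titv_ratio = 2,
                       recombination_rate = 0.002, generations = 25L,
                       coding_guard = TRUE, seed) {
  if (missing(seed) || is.null(seed)) {
    rlang::abort("sim_config() requires an explicit integer seed")
  }
  loci <- validate_locus_table(loci)
  loci$frame_offset[is.na(loci$frame_offset)] <- 0L
  cfg <- list(
    n_isolates = as.integer(n_isolates), loci = loci,
    n_founders = as.integer(n_founders),
    founder_divergence = founder_divergence,
    mutation_rate = mutation_rate, titv_ratio = titv_ratio,
    recombination_rate = recombination_rate,
    generations = as.integer(generations),
    coding_guard = isTRUE(coding_guard), seed = as.integer(seed)
  )
  if (cfg$n_isolates < 1 || nrow(loci) < 1) {
    rlang::abort("need at least one isolate and one locus")
  }
  if (cfg$n_founders < 1 || cfg$n_founders > cfg$n_isolates) {
    rlang::abort("n_founders must be in [1, n_isolates]")
  }
  rates <- c(cfg$founder_divergence, cfg$mutation_rate, cfg$recombination_rate)
  if (any(rates < 0 | rates > 1)) rlang::abort("rates must lie in [0, 1]")
  if (cfg$titv_ratio <= 0) rlang::abort("titv_ratio must be positive")
  if (cfg$generations < 0) rlang::abort("generations must be >= 0")
  structure(cfg, class = "sim_config")
}

SENSE_CODONS <- function() {
  cods <- all_codons()
  cods[translate_codon(cods) != "*"]
}

# random in-frame coding sequence without internal stop codons
random_coding_seq <- function(length_bp, frame_offset = 0L) {
  n_codon <- (length_bp - frame_offset) %/% 3L
  tail_len <- length_bp - frame_offset - 3L * n_codon
  paste0(
    paste(sample(DNA_BASES, frame_offset, replace = TRUE), collapse = ""),
    paste(sample(SENSE_CODONS(), n_codon, replace = TRUE), collapse = ""),
    paste(sample(DNA_BASES, tail_len, replace = TRUE), collapse = "")
  )
}

draw_substitution <- function(base, titv_ratio) {
  if (stats::runif(1) < titv_ratio / (titv_ratio + 1)) {
    TRANSITION[[base]]
  } else {
    sample(setdiff(DNA_BASES, c(base, TRANSITION[[base]])), 1L)
  }
}

# would replacing position pos (1-based) with `to` create an in-frame stop?
creates_stop <- function(seq, pos, to, frame_offset) {
  p <- pos - 1L - frame_offset
  if (p < 0L) {
    return(FALSE)
  }
  cod_i <- p %/% 3L
  start <- frame_offset + 3L * cod_i + 1L
  if (start + 2L > nchar(seq)) {
    return(FALSE)
  }
  cod <- strsplit(substr(seq, start, start + 2L), "")[[1]]
  cod[p %% 3L + 1L] <- to
  cod <- paste(cod, collapse = "")
  !grepl("N", cod, fixed = TRUE) && is_stop_codon(cod)
}

#' Mutate a sequence with a titv-weighted point-mutation kernel
#'
#' Each site mutates independently with probability `rate`; a substitution
#' is a transition with probability `titv_ratio / (titv_ratio + 1)`, with
#' the remaining mass split equally over the two transversions. With
#' `coding_guard = TRUE` substitutions that would create an in-frame stop
#' codon are rejected (not applied, not logged). Uses the global RNG.
#'
#' @param seq Nucleotide sequence.
#' @param rate Per-site substitution probability.
#' @param titv_ratio Transition/transversion ratio (> 0).
#' @param coding_guard Reject stop-creating substitutions?
#' @param frame_offset Frame used by the coding guard.
#' @return The mutated sequence, with attribute `"events"`: a tibble
#'   (`position` 1-based, `from`, `to`) of applied substitutions.
#' @export
mutate_sequence <- function(seq, rate, titv_ratio = 2, coding_guard = FALSE,
                            frame_offset = 0L) {
  L <- nchar(seq)
  k <- stats::rbinom(1L, L, rate)
  ev_pos <- integer(k)
  ev_from <- character(k)
  ev_to <- character(k)
  n_ev <- 0L
  if (k > 0) {
    pos <- sort(sample.int(L, k))
    for (p in pos) {
      from <- substr(seq, p, p)
      if (from == "N") next
      to <- draw_substitution(from, titv_ratio)
      if (coding_guard && creates_stop(seq, p, to, frame_offset)) next
      substr(seq, p, p) <- to
      n_ev <- n_ev + 1L
      ev_pos[n_ev] <- p
      ev_from[n_ev] <- from
      ev_to[n_ev] <- to
    }
  }
  attr(seq, "events") <- tibble(
    position = ev_pos[seq_len(n_ev)],
    from = ev_from[seq_len(n_ev)],
    to = ev_to[seq_len(n_ev)]
  )
  seq
}

#' Apply one round of whole-locus recombination
#'
#' Per isolate, with probability `rate`, one uniformly chosen locus'
#' sequence is replaced by that locus from a uniformly chosen other
#' isolate. Isolates are visited in row order of `metadata`/sequence
#' table, and events take effect immediately (a later recipient can
#' receive an allele imported earlier in the same round). Uses the global
#' RNG.
#'
#' @param sequences Long tibble (`isolate_id`, `locus`, `sequence`) with
#'   at least two isolates.
#' @param rate Per-isolate probability of one locus replacement.
#' @return A list with `sequences` (updated tibble) and `events` (tibble
#'   `recipient`, `donor`, `locus`).
#' @export
apply_recombination <- function(sequences, rate) {
  ids <- unique(sequences$isolate_id)
  if (length(ids) < 2) rlang::abort("recombination needs >= 2 isolates")
  loci <- unique(sequences$locus)
  seqs <- tidyr::pivot_wider(sequences,
    names_from = "locus", values_from = "sequence"
  )
  seqs <- seqs[match(ids, seqs$isolate_id), ]
  events <- list()
  hit <- stats::runif(length(ids)) < rate
  for (i in which(hit)) {
    locus <- loci[sample.int(length(loci), 1L)]
    donor <- sample.int(length(ids) - 1L, 1L)
    if (donor >= i) donor <- donor + 1L
    seqs[[locus]][i] <- seqs[[locus]][donor]
    events <- c(events, list(tibble(
      recipient = ids[i], donor = ids[donor], locus = locus
    )))
  }
  out <- tidyr::pivot_longer(seqs, -"isolate_id",
    names_to = "locus", values_to = "sequence"
  )
  list(
    sequences = arrange(out, .data$locus, .data$isolate_id),
    events = if (length(events)) bind_rows(events) else {
      tibble(recipient = character(), donor = character(), locus = character())
    }
  )
}

#' Simulate a clonal MLST population with known ground truth
#'
#' Founders are random in-frame coding sequences diverged from a common
#' ancestor; isolates are assigned to founders with harmonically decaying
#' lineage sizes (every founder gets at least one isolate) and then evolve
#' for `generations` rounds of point mutation followed by whole-locus
#' recombination. Metadata `source`/`region` labels are assigned per
#' founder, emulating niche structure. Fully deterministic given
#' `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A list with
#'   * `dataset` — an `mlst_dataset`;
#'   * `truth` — list with `founder_assignment` (tibble `isolate_id`,
#'     `founder`), `founder_sequences` (tibble `founder`, `locus`,
#'     `sequence`), `mutation_log` (tibble `generation`, `isolate_id`,
#'     `locus`, `position`, `from`, `to`), `recombination_log` (tibble
#'     `generation`, `recipient`, `donor`, `locus`), and `config`.
#' @examples
#' sim <- simulate_population(sim_config(n_isolates = 12, seed = 7))
#' sim$dataset
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  loci <- cfg$loci
  n <- cfg$n_isolates
  ids <- sprintf("iso%0*d", nchar(as.character(n)), seq_len(n))

  # founder lineage sizes: one isolate guaranteed each, the rest multinomial
  # with harmonic weights (largest lineage dominates, like a dominant CC)
  w <- 1 / seq_len(cfg$n_founders)
  founder <- c(
    seq_len(cfg$n_founders),
    if (n > cfg$n_founders) {
      sample.int(cfg$n_founders, n - cfg$n_founders, replace = TRUE, prob = w)
    }
  )[seq_len(n)]
  founder <- sort(founder)

  # ancestral and founder sequences per locus
  ancestral <- setNames(
    mapply(random_coding_seq, loci$fragment_length, loci$frame_offset),
    loci$locus
  )
  founder_seqs <- vector("list", cfg$n_founders)
  for (f in seq_len(cfg$n_founders)) {
    founder_seqs[[f]] <- setNames(vapply(loci$locus, function(l) {
      s <- mutate_sequence(
        ancestral[[l]], cfg$founder_divergence, cfg$titv_ratio,
        coding_guard = cfg$coding_guard,
        frame_offset = loci$frame_offset[loci$locus == l]
      )
      as.character(s)
    }, character(1)), loci$locus)
  }

  # population state: per locus, a character vector over isolates
  pop <- lapply(loci$locus, function(l) {
    vapply(founder, function(f) founder_seqs[[f]][[l]], character(1))
  })
  names(pop) <- loci$locus

  mut_log <- list()
  rec_log <- list()
  for (g in seq_len(cfg$generations)) {
    # mutation pass: per locus, draw the number of mutated cells across the
    # whole isolate-by-site grid (binomial), then place them uniformly --
    # exactly the per-site-independent model, without a per-isolate loop
    for (li in seq_along(loci$locus)) {
      l <- loci$locus[li]
      L <- loci$fragment_length[li]
      k_mut <- stats::rbinom(1L, n * L, cfg$mutation_rate)
      if (k_mut == 0) next
      cells <- sort(sample.int(n * L, k_mut))
      for (cell in cells) {
        i <- (cell - 1L) %/% L + 1L
        pos <- (cell - 1L) %% L + 1L
        s <- pop[[l]][i]
        from <- substr(s, pos, pos)
        if (from == "N") next
        to <- draw_substitution(from, cfg$titv_ratio)
        if (cfg$coding_guard &&
          creates_stop(s, pos, to, loci$frame_offset[li])) {
          next
        }
        substr(s, pos, pos) <- to
        pop[[l]][i] <- s
        mut_log <- c(mut_log, list(tibble(
          generation = g, isolate_id = ids[i], locus = l,
          position = pos, from = from, to = to
        )))
      }
    }
    # recombination pass
    if (cfg$recombination_rate > 0 && n >= 2) {
      hit <- stats::runif(n) < cfg$recombination_rate
      for (i in which(hit)) {
        li <- sample.int(nrow(loci), 1L)
        l <- loci$locus[li]
        donor <- sample.int(n - 1L, 1L)
        if (donor >= i) donor <- donor + 1L
        pop[[l]][i] <- pop[[l]][donor]
        rec_log <- c(rec_log, list(tibble(
          generation = g, recipient = ids[i], donor = ids[donor], locus = l
        )))
      }
    }
  }

  sequences <- bind_rows(lapply(loci$locus, function(l) {
    tibble(isolate_id = ids, locus = l, sequence = pop[[l]])
  }))
  sources <- c("pickle", "dairy", "sourdough", "sour_congee")
  regions <- c(
    "Sichuan", "Inner Mongolia", "Xinjiang", "Qinghai", "Tibet", "Dornogovi"
  )
  metadata <- tibble(
    isolate_id = ids,
    source = sources[(founder - 1L) %% length(sources) + 1L],
    region = regions[(founder - 1L) %% length(regions) + 1L],
    is_reference = FALSE
  )
  dataset <- build_mlst_dataset(sequences, metadata, loci = loci, mode = "strict")
  truth <- list(
    founder_assignment = tibble(isolate_id = ids, founder = founder),
    founder_sequences = bind_rows(lapply(seq_len(cfg$n_founders), function(f) {
      tibble(
        founder = f, locus = loci$locus,
        sequence = unname(unlist(founder_seqs[[f]]))
      )
    })),
    ancestral_sequences = tibble(
      locus = loci$locus, sequence = unname(ancestral)
    ),
    mutation_log = if (length(mut_log)) bind_rows(mut_log) else {
      tibble(
        generation = integer(), isolate_id = character(), locus = character(),
        position = integer(), from = character(), to = character()
      )
    },
    recombination_log = if (length(rec_log)) bind_rows(rec_log) else {
      tibble(
        generation = integer(), recipient = character(),
        donor = character(), locus = character()
      )
    },
    config = cfg
  )
  list(dataset = dataset, truth = truth)
}

#' Replay a simulation truth record
#'
#' Reconstructs the final sequences from the founder sequences and the
#' mutation/recombination event logs alone (no random draws). The result
#' is bit-identical to the simulated dataset, which is the correctness
#' contract of the logs.
#'
#' @param truth The `truth` component of [simulate_population()] output.
#' @return A long tibble (`isolate_id`, `locus`, `sequence`).
#' @export
replay_truth <- function(truth) {
  cfg <- truth$config
  ids <- truth$founder_assignment$isolate_id
  founder <- truth$founder_assignment$founder
  fs <- truth$founder_sequences
  pop <- lapply(cfg$loci$locus, function(l) {
    per_founder <- fs$sequence[fs$locus == l][order(fs$founder[fs$locus == l])]
    vapply(founder, function(f) per_founder[f], character(1))
  })
  names(pop) <- cfg$loci$locus
  for (g in seq_len(cfg$generations)) {
    mu <- truth$mutation_log[truth$mutation_log$generation == g, ]
    for (r in seq_len(nrow(mu))) {
      i <- match(mu$isolate_id[r], ids)
      s <- pop[[mu$locus[r]]][i]
      substr(s, mu$position[r], mu$position[r]) <- mu$to[r]
      pop[[mu$locus[r]]][i] <- s
    }
    re <- truth$recombination_log[truth$recombination_log$generation == g, ]
    for (r in seq_len(nrow(re))) {
      i <- match(re$recipient[r], ids)
      j <- match(re$donor[r], ids)
      pop[[re$locus[r]]][i] <- pop[[re$locus[r]]][j]
    }
  }
  bind_rows(lapply(cfg$loci$locus, function(l) {
    tibble(isolate_id = ids, locus = l, sequence = pop[[l]])
  })) |> arrange(.data$locus, .data$isolate_id)
}

#' Write a simulated dataset in the package's input layout
#'
#' Emits one FASTA per locus, the metadata TSV consumed by
#' [read_isolate_metadata()], and the truth record as JSON (config echoed,
#' seed included).
#'
#' @param sim Output of [simulate_population()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (l in sim$dataset$loci$locus) {
    rec <- sim$dataset$sequences[sim$dataset$sequences$locus == l, ]
    write_locus_fasta(rec, file.path(dir, paste0(l, ".fasta")))
  }
  utils::write.table(sim$dataset$metadata, file.path(dir, "metadata.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  truth <- sim$truth
  truth$config <- unclass(truth$config)
  truth$config$loci <- as.data.frame(truth$config$loci)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
    dataframe = "columns", auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
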