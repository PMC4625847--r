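# End-to-end orchestration: type -> eburst -> mst -> diversity -> linkage ->
# tree -> splits, from either on-disk FASTA input or a simulation block,
# with structured logging to stderr and all standard outputs on disk.

pipeline_log <- function(stage, level, msg) {
  message(sprintf("[%s] %s: %s", stage, level, msg))
}

run_stage <- function(stage, expr) {
  t0 <- proc.time()[["elapsed"]]
  pipeline_log(stage, "info", "started")
  res <- tryCatch(expr, error = function(e) {
    rlang::abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
      class = "mlstkit_stage_error", parent = e
    )
  })
  list(result = res, seconds = proc.time()[["elapsed"]] - t0)
}

#' Run the full MLST analysis pipeline
#'
#' Executes allele/ST typing, clonal-complex inference, minimum spanning
#' tree, diversity report, linkage disequilibrium, neighbour-joining tree
#' with bootstrap, and split decomposition, writing every standard output
#' plus a run manifest to `out_dir`. Input is either a directory of
#' per-locus FASTA files with a metadata TSV, or a simulation block.
#'
#' @param config A named list or path to a YAML file with fields:
#'   * `input`: list with `fasta` (named list/vector `locus = path` or a
#'     directory containing `<locus>.fasta` files) and optional `metadata`
#'     path — or instead
#'   * `simulate`: list of [sim_config()] arguments (seed required);
#'   * `out_dir`: output directory;
#'   * optional `unit` (`"isolates"`/`"unique_sts"`), `hj_bias`,
#'     `dnds_correction`, `permutations` (default 1000),
#'     `bootstrap_replicates` (default 1000), `eburst_threshold`
#'     (default loci - 1), `trim_mode`, `seed` (required whenever any
#'     stochastic stage runs).
#' @return Invisibly, a list with every stage result (`dataset`,
#'   `profiles`, `cc`, `mst`, `diversity`, `linkage`, `tree`, `splits`)
#'   and the manifest.
#' @export
run_mlst_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  has_input <- !is.null(config$input)
  has_sim <- !is.null(config$simulate)
  if (has_input == has_sim) {
    rlang::abort("config must contain exactly one of 'input' or 'simulate'")
  }
  if (is.null(config$out_dir)) rlang::abort("config$out_dir is required")
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% config$simulate$seed
  if (is.null(seed)) {
    rlang::abort("a seed is required (permutations and bootstrap are stochastic)")
  }
  perms <- config$permutations %||% 1000L
  boots <- config$bootstrap_replicates %||% 1000L
  unit <- config$unit %||% "isolates"
  hj_bias <- config$hj_bias %||% "unbiased"
  dnds_corr <- config$dnds_correction %||% "jukes_cantor"
  timings <- list()

  st <- run_stage("load", {
    if (has_sim) {
      sim_args <- config$simulate
      sim_args$loci <- if (!is.null(sim_args$loci)) {
        validate_locus_table(as_tibble(sim_args$loci))
      } else {
        lp_study_loci()
      }
      sim <- do.call(sim_config, sim_args)
      simulate_population(sim)$dataset
    } else {
      fasta <- config$input$fasta
      if (length(fasta) == 1 && dir.exists(fasta[[1]])) {
        files <- list.files(fasta[[1]], pattern = "\\.fasta$", full.names = TRUE)
        fasta <- setNames(as.list(files), sub("\\.fasta$", "", basename(files)))
      }
      seqs <- bind_rows(lapply(names(fasta), function(l) {
        read_locus_fasta(fasta[[l]], l)
      }))
      meta <- if (!is.null(config$input$metadata)) {
        read_isolate_metadata(config$input$metadata)
      }
      build_mlst_dataset(seqs, meta, mode = config$trim_mode %||% "trim_to_shortest")
    }
  })
  dataset <- st$result
  timings$load <- st$seconds
  utils::write.table(summary(dataset), file.path(out_dir, "dataset_summary.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )

  st <- run_stage("type", assign_profiles(dataset))
  profiles <- st$result
  timings$type <- st$seconds
  export_profiles(profiles, file.path(out_dir, "profiles"))

  st <- run_stage("eburst", {
    find_clonal_complexes(profiles, group_threshold = config$eburst_threshold %||% NULL)
  })
  cc <- st$result
  timings$eburst <- st$seconds
  write_cc_table(cc, file.path(out_dir, "clonal_complexes.tsv"))

  st <- run_stage("mst", build_mst(profiles, metadata = dataset$metadata))
  mst <- st$result
  timings$mst <- st$seconds
  write_mst_graphml(mst, file.path(out_dir, "mst.graphml"))
  write_mst_dot(mst, file.path(out_dir, "mst.dot"))

  st <- run_stage("diversity", {
    diversity_report(dataset, profiles,
      unit = if (unit == "unique_sts") "sts" else "isolates",
      dnds_correction = dnds_corr
    )
  })
  diversity <- st$result
  timings$diversity <- st$seconds
  write_diversity_report(diversity, file.path(out_dir, "diversity.tsv"))

  st <- run_stage("linkage", {
    tryCatch(
      index_of_association(profiles,
        unit = unit, hj_bias = hj_bias,
        n_perm = perms, seed = seed
      ),
      mlstkit_degenerate_stat = function(e) {
        pipeline_log("linkage", "warn", conditionMessage(e))
        NULL
      }
    )
  })
  linkage <- st$result
  timings$linkage <- st$seconds
  jsonlite::write_json(
    if (is.null(linkage)) {
      list(note = "undefined: all loci monomorphic")
    } else {
      glance(linkage)
    },
    file.path(out_dir, "linkage.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA
  )

  st_aln <- concatenate_loci(dataset, taxa = "per_st", profiles = profiles)
  write_alignment_fasta(st_aln, file.path(out_dir, "concatenated_sts.fasta"))

  st <- run_stage("tree", {
    if (nrow(st_aln) < 2) {
      pipeline_log("tree", "warn", "single ST: writing a one-leaf tree")
      ape::read.tree(text = sprintf("(%s);", st_aln$id[1]))
    } else {
      bootstrap_support(st_aln, n_reps = boots, seed = seed)
    }
  })
  tree <- st$result
  timings$tree <- st$seconds
  ape::write.tree(tree, file.path(out_dir, "tree.nwk"))

  st <- run_stage("splits", {
    dm <- k2p_matrix(st_aln)
    write_phylip(dm, file.path(out_dir, "k2p_sts.phylip"))
    if (nrow(st_aln) < 2) {
      pipeline_log("splits", "warn", "single ST: empty split system")
      structure(
        list(
          taxa = st_aln$id,
          splits = tibble(
            id = integer(), side_a = list(), size_a = integer(),
            alpha = numeric(), trivial = logical()
          ),
          fit = 100
        ),
        class = "mlst_splits"
      )
    } else {
      split_decomposition(dm)
    }
  })
  splits <- st$result
  timings$splits <- st$seconds
  write_nexus_splits(splits, file.path(out_dir, "splits.nex"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("mlstkit")),
    r_version = R.version.string,
    seed = seed,
    config = config,
    stage_seconds = timings
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  pipeline_log("done", "info", sprintf("all outputs in %s", out_dir))
  invisible(list(
    dataset = dataset, profiles = profiles, cc = cc, mst = mst,
    diversity = diversity, linkage = linkage, tree = tree, splits = splits,
    manifest = manifest
  ))
}
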