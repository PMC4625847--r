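#' Catalogue the alleles of one locus
#'
#' Every distinct nucleotide sequence at a locus defines an allele. Alleles
#' are numbered densely 1..K in order of first observation over the input
#' rows, so numbering is deterministic for a given record order.
#'
#' @param sequences Tibble with a `sequence` column (equal-length fragments
#'   of one locus); typically one row per isolate.
#' @param locus Optional locus label recorded in the output.
#' @return A tibble of class `mlst_allele_catalog` with columns `locus`,
#'   `allele`, `sequence`, one row per distinct sequence.
#' @examples
#' catalog_alleles(tibble::tibble(sequence = c("AAAA", "AAAA", "AAAT")))
#' @export
catalog_alleles <- function(sequences, locus = NA_character_) {
  seqs <- toupper(sequences$sequence)
  if (length(seqs) == 0) rlang::abort("no sequences to catalogue")
  if (length(unique(nchar(seqs))) != 1) {
    rlang::abort("allele cataloguing requires equal-length sequences",
      class = "mlstkit_length_error"
    )
  }
  uniq <- unique(seqs)
  out <- tibble(locus = locus, allele = seq_along(uniq), sequence = uniq)
  class(out) <- c("mlst_allele_catalog", class(out))
  out
}

# map sequences to allele numbers given a catalog
allele_numbers <- function(seqs, catalog) {
  idx <- match(toupper(seqs), catalog$sequence)
  if (anyNA(idx)) rlang::abort("sequence not present in allele catalog")
  catalog$allele[idx]
}

#' Assign allelic profiles and sequence types
#'
#' Numbers alleles per locus and isolates' allelic profiles, then assigns
#' sequence types (STs): isolates sharing the same combination of alleles
#' (one per locus) share an ST. Isolates are processed in lexicographic
#' order of their IDs, and allele and ST numbers follow first observation in
#' that order, making the numbering deterministic; comparisons with other
#' numbering schemes are meaningful up to relabeling only.
#'
#' @param dataset An `mlst_dataset` (complete matrix).
#' @return An object of class `mlst_profiles`: list with
#'   * `catalogs` — tibble (`locus`, `allele`, `sequence`);
#'   * `profiles` — tibble with `st`, one allele column per locus, and
#'     `n_isolates`;
#'   * `membership` — tibble (`isolate_id`, `st`);
#'   * `loci` — locus order used for profiles.
#' @examples
#' d <- simulate_population(sim_config(n_isolates = 8, seed = 1))$dataset
#' p <- assign_profiles(d)
#' p$profiles
#' @export
assign_profiles <- function(dataset) {
  loci <- dataset$loci$locus
  ids <- sort(unique(dataset$sequences$isolate_id))
  catalogs <- vector("list", length(loci))
  prof_cols <- vector("list", length(loci))
  for (i in seq_along(loci)) {
    seqs <- locus_seqs(dataset, loci[i]) # sorted by isolate_id
    cat_i <- catalog_alleles(tibble(sequence = unname(seqs)), locus = loci[i])
    catalogs[[i]] <- cat_i
    prof_cols[[i]] <- allele_numbers(unname(seqs[ids]), cat_i)
  }
  prof_mat <- do.call(cbind, prof_cols)
  colnames(prof_mat) <- loci
  key <- apply(prof_mat, 1L, paste, collapse = "_")
  st <- match(key, unique(key)) # first-observation order over sorted isolates
  membership <- tibble(isolate_id = ids, st = st)
  first_rows <- match(unique(key), key)
  profiles <- as_tibble(prof_mat[first_rows, , drop = FALSE]) |>
    mutate(st = seq_along(first_rows), .before = 1L) |>
    left_join(count(membership, .data$st, name = "n_isolates"), by = "st")
  catalogs <- bind_rows(catalogs)
  class(catalogs) <- c("tbl_df", "tbl", "data.frame")
  structure(
    list(
      catalogs = catalogs, profiles = profiles,
      membership = membership, loci = loci
    ),
    class = "mlst_profiles"
  )
}

#' @export
print.mlst_profiles <- function(x, ...) {
  cat(sprintf(
    "<mlst_profiles> %d isolates -> %d STs over %d loci\n",
    nrow(x$membership), nrow(x$profiles), length(x$loci)
  ))
  alle <- count(x$catalogs, .data$locus)
  cat(sprintf(
    "  alleles per locus: %s\n",
    paste(sprintf("%s=%d", alle$locus, alle$n), collapse = " ")
  ))
  invisible(x)
}

#' Tidy a profile table
#'
#' @param x An `mlst_profiles` object.
#' @param ... Unused.
#' @return The ST-by-locus profile tibble (`st`, allele columns,
#'   `n_isolates`).
#' @method tidy mlst_profiles
#' @export
tidy.mlst_profiles <- function(x, ...) x$profiles

#' @rdname tidy.mlst_profiles
#' @return For `glance()`: a one-row tibble with `n_isolates`, `n_sts`,
#'   `n_loci`, `max_st_size`.
#' @method glance mlst_profiles
#' @export
glance.mlst_profiles <- function(x, ...) {
  tibble(
    n_isolates = nrow(x$membership), n_sts = nrow(x$profiles),
    n_loci = length(x$loci), max_st_size = max(x$profiles$n_isolates)
  )
}

# matrix of allelic profiles (rows = STs) from an mlst_profiles object
profile_matrix <- function(profiles) {
  m <- as.matrix(profiles$profiles[profiles$loci])
  rownames(m) <- profiles$profiles$st
  m
}

#' Export a profile table to disk
#'
#' Writes a PubMLST-style tab-separated profile file
#' (`ST<TAB>locus1..locusL<TAB>count`), a per-locus allele FASTA with IDs
#' `locus_alleleNumber`, and the isolate-to-ST membership table.
#' [import_profiles()] on the same directory reproduces the object exactly.
#'
#' @param profiles An `mlst_profiles` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_profiles <- function(profiles, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prof <- profiles$profiles |>
    rename(ST = "st", count = "n_isolates")
  utils::write.table(prof, file.path(dir, "profiles.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(profiles$membership, file.path(dir, "members.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  for (l in profiles$loci) {
    cat_l <- profiles$catalogs[profiles$catalogs$locus == l, ]
    write_locus_fasta(
      tibble(
        isolate_id = paste0(l, "_", cat_l$allele),
        sequence = cat_l$sequence
      ),
      file.path(dir, paste0("alleles_", l, ".fasta"))
    )
  }
  invisible(dir)
}

#' Import a profile table written by [export_profiles()]
#'
#' @param dir Directory holding `profiles.tsv`, `members.tsv` and
#'   `alleles_<locus>.fasta` files.
#' @return An `mlst_profiles` object.
#' @export
import_profiles <- function(dir) {
  prof <- as_tibble(utils::read.table(file.path(dir, "profiles.tsv"),
    header = TRUE, sep = "\t", check.names = FALSE
  ))
  loci <- setdiff(names(prof), c("ST", "count"))
  membership <- as_tibble(utils::read.table(file.path(dir, "members.tsv"),
    header = TRUE, sep = "\t", colClasses = c("character", "integer")
  ))
  catalogs <- bind_rows(lapply(loci, function(l) {
    fa <- read_locus_fasta(file.path(dir, paste0("alleles_", l, ".fasta")), l)
    tibble(
      locus = l,
      allele = as.integer(sub(paste0("^", l, "_"), "", fa$isolate_id)),
      sequence = fa$sequence
    ) |> arrange(.data$allele)
  }))
  profiles <- prof |> rename(st = "ST", n_isolates = "count") |>
    select("st", dplyr::all_of(loci), "n_isolates")
  structure(
    list(
      catalogs = catalogs, profiles = profiles,
      membership = membership, loci = loci
    ),
    class = "mlst_profiles"
  )
}
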