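#' Read one locus' sequence fragments from a FASTA file
#'
#' Reads a per-locus FASTA file into a long tibble of sequence records. The
#' record ID (first whitespace-delimited token of the header) is taken as the
#' isolate ID; sequences are uppercased and must contain only A, C, G, T or N.
#'
#' @param path Path to a FASTA file holding one fragment per isolate.
#' @param locus Locus label to attach to every record.
#' @return A tibble with columns `isolate_id`, `locus`, `sequence`.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">iso1", "acgt", ">iso2 extra words", "ACGT"), tf)
#' read_locus_fasta(tf, "demo")
#' @export
read_locus_fasta <- function(path, locus) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("FASTA file not found: %s", path))
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) {
      rlang::abort(sprintf("malformed FASTA '%s': %s", path, conditionMessage(e)),
        class = "mlstkit_parse_error"
      )
    }
  )
  if (length(set) == 0) {
    rlang::warn(sprintf("empty FASTA file: %s", path))
    return(tibble(
      isolate_id = character(), locus = character(), sequence = character()
    ))
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    rlang::abort(
      sprintf(
        "duplicate isolate_id in '%s': %s", path,
        paste(unique(dup), collapse = ", ")
      ),
      class = "mlstkit_duplicate_error"
    )
  }
  seqs <- check_dna(as.character(set), ids)
  tibble(isolate_id = ids, locus = locus, sequence = unname(seqs))
}

#' Write sequence records of one locus to FASTA
#'
#' @param sequences Tibble with columns `isolate_id`, `sequence` (rows of one
#'   locus).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_locus_fasta <- function(sequences, path) {
  set <- Biostrings::BStringSet(setNames(sequences$sequence, sequences$isolate_id))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read an isolate metadata table
#'
#' Expects a tab-separated file with header
#' `isolate_id<TAB>source<TAB>region<TAB>is_reference`.
#'
#' @param path Path to the metadata TSV.
#' @return A tibble with those four columns (`is_reference` as logical).
#' @export
read_isolate_metadata <- function(path) {
  df <- utils::read.table(path,
    header = TRUE, sep = "\t", colClasses = "character",
    stringsAsFactors = FALSE, quote = ""
  )
  need <- c("isolate_id", "source", "region", "is_reference")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    rlang::abort(sprintf("metadata missing columns: %s", paste(miss, collapse = ", ")))
  }
  out <- as_tibble(df[need])
  out$is_reference <- toupper(out$is_reference) %in% c("TRUE", "T", "1", "YES")
  if (anyDuplicated(out$isolate_id)) {
    rlang::abort("duplicate isolate_id in metadata", class = "mlstkit_duplicate_error")
  }
  out
}

#' Validate and length-harmonise sequence fragments
#'
#' In `strict` mode every sequence must already have its locus' declared
#' `fragment_length`; offenders are reported by isolate. In
#' `trim_to_shortest` mode all fragments of a locus are truncated at the
#' right end to the shortest length present and the locus table is updated.
#'
#' @param sequences Long tibble (`isolate_id`, `locus`, `sequence`).
#' @param loci Locus-definition tibble (see [locus_table()]).
#' @param mode `"strict"` or `"trim_to_shortest"`.
#' @return The harmonised sequence tibble; the updated locus table is
#'   attached as attribute `"loci"`.
#' @export
validate_and_trim <- function(sequences, loci, mode = c("strict", "trim_to_shortest")) {
  mode <- match.arg(mode)
  loci <- validate_locus_table(loci)
  sequences <- mutate(sequences, sequence = check_dna(.data$sequence, .data$isolate_id))
  extra <- setdiff(unique(sequences$locus), loci$locus)
  if (length(extra) > 0) {
    rlang::abort(sprintf("sequences present for undeclared loci: %s", paste(extra, collapse = ", ")))
  }
  out <- vector("list", nrow(loci))
  for (i in seq_len(nrow(loci))) {
    def <- loci[i, ]
    rec <- filter(sequences, .data$locus == def$locus)
    if (nrow(rec) == 0) {
      out[[i]] <- rec
      next
    }
    lens <- nchar(rec$sequence)
    if (mode == "strict") {
      bad <- lens != def$fragment_length
      if (any(bad)) {
        rlang::abort(
          sprintf(
            "locus %s: length != %d for isolate(s) %s",
            def$locus, def$fragment_length,
            paste(rec$isolate_id[bad], collapse = ", ")
          ),
          class = "mlstkit_length_error"
        )
      }
    } else {
      target <- min(lens)
      rec$sequence <- substr(rec$sequence, 1L, target)
      loci$fragment_length[i] <- target
    }
    if (loci$fragment_length[i] < 9L && def$coding) {
      rlang::abort(
        sprintf("locus %s: fewer than 3 codons after trimming", def$locus),
        class = "mlstkit_degenerate_locus_error"
      )
    }
    out[[i]] <- rec
  }
  res <- bind_rows(out)
  attr(res, "loci") <- loci
  res
}

#' Assemble an analysis-ready MLST dataset
#'
#' Combines per-locus sequence records and isolate metadata into a complete
#' data matrix: every retained isolate has exactly one fragment at every
#' locus. Isolates missing any locus are dropped with a warning and listed in
#' the `rejected` attribute; metadata rows without sequences are ignored.
#' Missing frame offsets of coding loci are auto-detected as the reading
#' frame free of internal stop codons.
#'
#' @param sequences Long tibble (`isolate_id`, `locus`, `sequence`), e.g.
#'   rows bound from [read_locus_fasta()] calls.
#' @param metadata Optional isolate metadata tibble
#'   (`isolate_id`, `source`, `region`, `is_reference`).
#' @param loci Optional locus-definition tibble; derived from the data when
#'   `NULL` (observed length, coding, auto frame).
#' @param mode Length-harmonisation mode passed to [validate_and_trim()].
#' @return An object of class `mlst_dataset`: a list of tibbles `loci`,
#'   `sequences`, `metadata`, with attribute `rejected` (isolate IDs dropped
#'   for incomplete locus coverage).
#' @examples
#' seqs <- tibble::tibble(
#'   isolate_id = rep(c("a", "b"), 2),
#'   locus = rep(c("l1", "l2"), each = 2),
#'   sequence = c("ATGAAA", "ATGAAG", "ATGCCCGGG", "ATGCCCGGT")
#' )
#' d <- build_mlst_dataset(seqs)
#' summary(d)
#' @export
build_mlst_dataset <- function(sequences, metadata = NULL, loci = NULL,
                               mode = c("strict", "trim_to_shortest")) {
  mode <- match.arg(mode)
  if (nrow(sequences) == 0) rlang::abort("no sequence records", class = "mlstkit_empty_dataset")
  if (anyDuplicated(sequences[c("isolate_id", "locus")])) {
    rlang::abort("duplicate (isolate_id, locus) records", class = "mlstkit_duplicate_error")
  }
  sequences <- arrange(sequences, .data$locus, .data$isolate_id)
  if (is.null(loci)) {
    loci <- sequences |>
      group_by(locus = .data$locus) |>
      summarise(fragment_length = min(nchar(.data$sequence)), .groups = "drop") |>
      mutate(frame_offset = NA_integer_, coding = TRUE)
    if (mode == "strict") {
      # derived lengths must be consistent in strict mode
      chk <- sequences |>
        group_by(.data$locus) |>
        summarise(n_len = dplyr::n_distinct(nchar(.data$sequence)), .groups = "drop")
      if (any(chk$n_len > 1)) {
        rlang::abort(
          sprintf(
            "unequal fragment lengths at locus %s (use mode = 'trim_to_shortest')",
            paste(chk$locus[chk$n_len > 1], collapse = ", ")
          ),
          class = "mlstkit_length_error"
        )
      }
    }
  }
  sequences <- validate_and_trim(sequences, loci, mode)
  loci <- attr(sequences, "loci")
  loci <- filter(loci, .data$locus %in% unique(sequences$locus))
  attr(sequences, "loci") <- NULL

  # enforce complete matrix
  cov <- sequences |>
    count(.data$isolate_id, name = "n_loci")
  complete <- cov$isolate_id[cov$n_loci == nrow(loci)]
  rejected <- setdiff(unique(sequences$isolate_id), complete)
  if (length(rejected) > 0) {
    rlang::warn(sprintf(
      "dropping %d isolate(s) with incomplete locus coverage: %s",
      length(rejected), paste(head(rejected, 10), collapse = ", ")
    ))
  }
  if (length(complete) == 0) {
    rlang::abort("no isolate has complete locus coverage", class = "mlstkit_empty_dataset")
  }
  sequences <- filter(sequences, .data$isolate_id %in% complete)

  if (is.null(metadata)) {
    metadata <- tibble(
      isolate_id = sort(complete), source = NA_character_,
      region = NA_character_, is_reference = FALSE
    )
  } else {
    orphan <- setdiff(metadata$isolate_id, complete)
    if (length(orphan) > 0) {
      rlang::warn(sprintf("%d metadata row(s) without sequences ignored", length(orphan)))
    }
    metadata <- filter(metadata, .data$isolate_id %in% complete)
    missing_meta <- setdiff(complete, metadata$isolate_id)
    if (length(missing_meta) > 0) {
      metadata <- bind_rows(metadata, tibble(
        isolate_id = missing_meta, source = NA_character_,
        region = NA_character_, is_reference = FALSE
      ))
    }
    metadata <- arrange(metadata, .data$isolate_id)
  }

  # auto-detect missing frames for coding loci
  for (i in seq_len(nrow(loci))) {
    if (loci$coding[i] && is.na(loci$frame_offset[i])) {
      s <- sequences$sequence[sequences$locus == loci$locus[i]]
      loci$frame_offset[i] <- detect_frame_offset(s)
    }
  }

  structure(
    list(loci = loci, sequences = as_tibble(sequences), metadata = metadata),
    rejected = rejected, class = "mlst_dataset"
  )
}

#' @export
print.mlst_dataset <- function(x, ...) {
  cat(sprintf(
    "<mlst_dataset> %d isolates x %d loci (%s)\n",
    dplyr::n_distinct(x$sequences$isolate_id), nrow(x$loci),
    paste(x$loci$locus, collapse = ", ")
  ))
  cat(sprintf(
    "  concatenated length: %d bp; %d reference isolate(s)\n",
    sum(x$loci$fragment_length), sum(x$metadata$is_reference)
  ))
  invisible(x)
}

#' Summarise an MLST dataset
#'
#' @param object An `mlst_dataset`.
#' @param ... Unused.
#' @return A tibble with one row per locus (isolate count, fragment length,
#'   frame offset) plus a `concatenated` row whose length is the sum of the
#'   per-locus fragment lengths.
#' @export
summary.mlst_dataset <- function(object, ...) {
  per <- object$sequences |>
    group_by(locus = .data$locus) |>
    summarise(n_isolates = dplyr::n(), .groups = "drop") |>
    left_join(object$loci, by = "locus") |>
    select("locus", "n_isolates", "fragment_length", "frame_offset", "coding")
  bind_rows(per, tibble(
    locus = "concatenated",
    n_isolates = dplyr::n_distinct(object$sequences$isolate_id),
    fragment_length = sum(object$loci$fragment_length),
    frame_offset = NA_integer_, coding = NA
  ))
}

# named character vector of one locus' sequences, isolates sorted by ID
locus_seqs <- function(dataset, locus) {
  rec <- dataset$sequences[dataset$sequences$locus == locus, ]
  rec <- rec[order(rec$isolate_id), ]
  setNames(rec$sequence, rec$isolate_id)
}

#' Concatenate locus fragments into a single alignment
#'
#' Joins the fragments of every locus, in the dataset's declared locus
#' order, into one equal-length row per taxon. Taxa are either isolates or
#' sequence types (one row per ST built from that ST's allele sequences;
#' requires `profiles`).
#'
#' @param dataset An `mlst_dataset`.
#' @param taxa `"per_isolate"` or `"per_st"`.
#' @param profiles An `mlst_profiles` object (required for `"per_st"`).
#' @return A tibble of class `mlst_alignment` with columns `id`, `sequence`,
#'   carrying attribute `boundaries`: a tibble (`locus`, `start`, `end`) of
#'   0-based half-open per-locus offsets.
#' @export
concatenate_loci <- function(dataset, taxa = c("per_isolate", "per_st"),
                             profiles = NULL) {
  taxa <- match.arg(taxa)
  loci <- dataset$loci
  ends <- cumsum(loci$fragment_length)
  boundaries <- tibble(
    locus = loci$locus,
    start = c(0L, head(ends, -1L)), end = ends
  )
  if (taxa == "per_isolate") {
    parts <- lapply(loci$locus, function(l) locus_seqs(dataset, l))
    ids <- names(parts[[1]])
    rows <- do.call(paste0, lapply(parts, function(p) unname(p[ids])))
  } else {
    if (is.null(profiles)) {
      rlang::abort("taxa = 'per_st' requires a ProfileTable (`profiles`)")
    }
    ids <- paste0("ST", profiles$profiles$st)
    rows <- do.call(paste0, lapply(loci$locus, function(l) {
      cat_l <- profiles$catalogs[profiles$catalogs$locus == l, ]
      cat_l$sequence[match(profiles$profiles[[l]], cat_l$allele)]
    }))
  }
  out <- tibble(id = ids, sequence = rows)
  attr(out, "boundaries") <- boundaries
  class(out) <- c("mlst_alignment", class(out))
  out
}

#' Write a concatenated alignment to FASTA
#'
#' @param alignment An `mlst_alignment` (or any tibble with `id`,
#'   `sequence`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(alignment, path) {
  set <- Biostrings::BStringSet(setNames(alignment$sequence, alignment$id))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}
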