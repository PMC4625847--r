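#' Define MLST loci
#'
#' Builds (and validates) the locus-definition table used throughout the
#' package: one row per housekeeping-gene fragment with its expected trimmed
#' length, reading-frame offset and coding flag.
#'
#' @param locus Character vector of short locus labels (e.g. `"clpX"`).
#' @param fragment_length Integer vector of expected trimmed fragment lengths
#'   in bp.
#' @param frame_offset Integer vector in `{0, 1, 2}`: 0-based index of the
#'   first complete codon position within the fragment. May be `NA` for
#'   coding loci, in which case [detect_frame_offset()] fills it in when a
#'   dataset is built.
#' @param coding Logical vector: is the fragment protein-coding?
#'
#' @return A tibble with columns `locus`, `fragment_length`, `frame_offset`,
#'   `coding`.
#' @examples
#' locus_table(c("clpX", "recA"), c(443, 546))
#' @export
locus_table <- function(locus, fragment_length,
                        frame_offset = NA_integer_, coding = TRUE) {
  tbl <- tibble(
    locus = as.character(locus),
    fragment_length = as.integer(fragment_length),
    frame_offset = as.integer(frame_offset),
    coding = as.logical(coding)
  )
  validate_locus_table(tbl)
}

validate_locus_table <- function(tbl) {
  stopifnot(all(c("locus", "fragment_length", "frame_offset", "coding") %in% names(tbl)))
  if (anyDuplicated(tbl$locus)) rlang::abort("duplicate locus labels")
  if (any(tbl$fragment_length <= 0L)) rlang::abort("fragment_length must be positive")
  off <- tbl$frame_offset[!is.na(tbl$frame_offset)]
  if (any(!off %in% 0:2)) rlang::abort("frame_offset must be 0, 1 or 2")
  bad <- tbl$coding & !is.na(tbl$frame_offset) &
    (tbl$fragment_length - tbl$frame_offset) < 3L
  if (any(bad)) {
    rlang::abort(sprintf(
      "coding locus '%s' leaves no complete codon after frame offset",
      tbl$locus[which(bad)[1]]
    ))
  }
  as_tibble(tbl)
}

#' Housekeeping loci of the L. plantarum MLST scheme
#'
#' The eight protein-coding loci used for typing *Lactobacillus plantarum*
#' (clpX, groEL, murC, murE, pheS, pyrG, recA, uvrC) with their trimmed
#' fragment lengths. Fragment lengths range from 415 to 641 bp; note that
#' they sum to 4270 bp while the concatenated alignment of the original
#' study is described as 4251 bp — both numbers are reported by
#' [summary.mlst_dataset()] and neither is forced onto the other.
#'
#' @return A locus-definition tibble (see [locus_table()]).
#' @examples
#' lp_study_loci()
#' @export
lp_study_loci <- function() {
  locus_table(
    locus = c("clpX", "groEL", "murC", "murE", "pheS", "pyrG", "recA", "uvrC"),
    fragment_length = c(443L, 641L, 462L, 607L, 536L, 415L, 546L, 620L),
    coding = TRUE
  )
}

#' Detect the reading frame of a coding fragment
#'
#' Chooses the frame offset (0, 1 or 2) that produces zero internal stop
#' codons across all distinct sequences of a locus; ties are broken toward
#' the smallest offset. If no frame is stop-free the offset with the fewest
#' stops is returned with a warning.
#'
#' @param seqs Character vector of equal-length nucleotide sequences.
#' @return Integer frame offset in `{0, 1, 2}`.
#' @examples
#' detect_frame_offset(c("ATGAAACCC", "ATGAAACCG"))
#' @export
detect_frame_offset <- function(seqs) {
  seqs <- unique(toupper(seqs))
  stops <- vapply(0:2, function(off) sum(count_stops(seqs, off)), numeric(1))
  best <- which.min(stops) - 1L # which.min takes first on ties -> offset 0 wins
  if (stops[best + 1L] > 0) {
    rlang::warn(sprintf(
      "no stop-free reading frame found; using offset %d (%d internal stops)",
      best, stops[best + 1L]
    ))
  }
  best
}
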