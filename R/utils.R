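# Shared internal helpers: sequence <-> matrix conversion, alphabet checks,
# codon utilities. Sequences are uppercase strings over {A,C,G,T,N}; 'N' marks
# an undetermined base and is excluded pairwise downstream.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")
DNA_BASES <- c("A", "C", "G", "T")

# transition partner for each base (A<->G, C<->T)
TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

check_dna <- function(seqs, ids = names(seqs)) {
  seqs <- toupper(seqs)
  bad <- !grepl("^[ACGTN]+$", seqs)
  if (any(bad)) {
    i <- which(bad)[1]
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    pos <- which(!chars %in% DNA_ALPHABET)[1]
    rlang::abort(sprintf(
      "illegal character '%s' at position %d in sequence for '%s'",
      chars[pos], pos, if (is.null(ids)) i else ids[i]
    ), class = "mlstkit_alphabet_error")
  }
  if (any(!nzchar(seqs))) {
    rlang::abort("empty sequence encountered", class = "mlstkit_alphabet_error")
  }
  seqs
}

# character matrix (rows = sequences, cols = sites) from equal-length strings
aln_matrix <- function(seqs) {
  lens <- nchar(seqs)
  if (length(seqs) == 0) rlang::abort("no sequences")
  if (length(unique(lens)) != 1) {
    rlang::abort("sequences must be of equal length", class = "mlstkit_length_error")
  }
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
    nrow = length(seqs), byrow = TRUE
  )
  rownames(m) <- names(seqs)
  m
}

# list of 0/1 indicator matrices (n x L), one per base, plus non-N indicator
base_indicators <- function(m) {
  out <- lapply(DNA_BASES, function(b) (m == b) * 1L)
  names(out) <- DNA_BASES
  out$valid <- (m != "N") * 1L
  out
}

# pairwise mismatch and comparable-site counts for equal-length sequences,
# with sites containing N excluded pairwise; returns list of n x n matrices
pairwise_mismatch <- function(seqs) {
  m <- aln_matrix(seqs)
  ind <- base_indicators(m)
  matches <- Reduce(`+`, lapply(DNA_BASES, function(b) tcrossprod(ind[[b]])))
  comparable <- tcrossprod(ind$valid)
  list(mismatch = comparable - matches, comparable = comparable)
}

split_codons <- function(seq, frame_offset = 0L) {
  s <- substring(seq, frame_offset + 1L)
  n_codon <- nchar(s) %/% 3L
  if (n_codon < 1L) return(character(0))
  substring(s, 3L * seq_len(n_codon) - 2L, 3L * seq_len(n_codon))
}

GENETIC_CODE_TBL <- NULL # filled at load time

translate_codon <- function(codon) {
  aa <- unname(Biostrings::GENETIC_CODE[codon])
  aa[is.na(aa)] <- "X" # codons containing N
  aa
}

is_stop_codon <- function(codon) {
  !is.na(Biostrings::GENETIC_CODE[codon]) &
    unname(Biostrings::GENETIC_CODE[codon]) == "*"
}

# count internal stop codons in each sequence for a given frame
count_stops <- function(seqs, frame_offset = 0L) {
  vapply(seqs, function(s) {
    cods <- split_codons(s, frame_offset)
    cods <- cods[!grepl("N", cods, fixed = TRUE)]
    sum(is_stop_codon(cods))
  }, integer(1), USE.NAMES = FALSE)
}

# accept an alignment as a character vector of sequences or a tibble with a
# `sequence` column (ids from `isolate_id` or `id` when present)
as_seqs <- function(x) {
  if (is.data.frame(x)) {
    ids <- if ("isolate_id" %in% names(x)) {
      x$isolate_id
    } else if ("id" %in% names(x)) {
      x$id
    } else {
      NULL
    }
    return(setNames(toupper(x$sequence), ids))
  }
  setNames(toupper(as.character(x)), names(x))
}

# collapse to unique sequences with multiplicities; returns list(seq, w)
unique_weighted <- function(seqs) {
  tab <- table(factor(seqs, levels = unique(seqs)))
  list(seq = names(tab), w = as.integer(tab))
}

# weights for unordered pairs among unique sequences (diagonal = within-class
# pairs); returns matrix of pair counts
pair_weights <- function(w) {
  m <- tcrossprod(w)
  diag(m) <- w * (w - 1) / 2
  m[lower.tri(m)] <- 0
  m
}
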