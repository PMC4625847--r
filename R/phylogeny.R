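# Kimura two-parameter distances, neighbour joining with deterministic
# tie-breaks, and column-resampling bootstrap support.

#' Kimura two-parameter distance
#'
#' With `P` and `Q` the proportions of transition and transversion
#' differences over the pair's comparable (mutually non-N) sites,
#' `d = -(1/2) log(1 - 2P - Q) - (1/4) log(1 - 2Q)`.
#'
#' @param s1,s2 Equal-length nucleotide sequences.
#' @return Numeric distance; 0 iff the sequences are identical at
#'   comparable sites.
#' @examples
#' k2p_distance(strrep("A", 90), paste0(strrep("A", 80), strrep("G", 10))) |>
#'   round(6) # 10% transitions
#' @export
k2p_distance <- function(s1, s2) {
  if (nchar(s1) != nchar(s2)) {
    rlang::abort("sequences differ in length", class = "mlstkit_length_error")
  }
  a <- strsplit(toupper(s1), "")[[1]]
  b <- strsplit(toupper(s2), "")[[1]]
  ok <- a != "N" & b != "N"
  if (!any(ok)) rlang::abort("no mutually determined sites")
  a <- a[ok]
  b <- b[ok]
  diff <- a != b
  ts <- diff & TRANSITION[a] == b
  p <- sum(ts) / length(a)
  q <- (sum(diff) - sum(ts)) / length(a)
  arg1 <- 1 - 2 * p - q
  arg2 <- 1 - 2 * q
  if (arg1 <= 0 || arg2 <= 0) {
    rlang::abort("saturated pair: K2P logarithm argument <= 0",
      class = "mlstkit_saturation_error"
    )
  }
  -0.5 * log(arg1) - 0.25 * log(arg2)
}

#' Kimura two-parameter distance matrix
#'
#' Pairwise [k2p_distance()] over an alignment, with N-containing positions
#' excluded pairwise.
#'
#' @param alignment Equal-length sequences: character vector (named by
#'   taxon) or a tibble with `id`/`isolate_id` and `sequence` columns.
#' @return A symmetric numeric matrix with zero diagonal and taxa as
#'   dimnames.
#' @export
k2p_matrix <- function(alignment) {
  seqs <- as_seqs(alignment)
  if (is.null(names(seqs))) names(seqs) <- paste0("t", seq_along(seqs))
  m <- aln_matrix(seqs)
  ind <- base_indicators(m)
  comparable <- tcrossprod(ind$valid)
  matches <- Reduce(`+`, lapply(DNA_BASES, function(b) tcrossprod(ind[[b]])))
  transitions <- tcrossprod(ind$A, ind$G) + tcrossprod(ind$G, ind$A) +
    tcrossprod(ind$C, ind$T) + tcrossprod(ind$T, ind$C)
  p <- transitions / comparable
  q <- (comparable - matches - transitions) / comparable
  arg1 <- 1 - 2 * p - q
  arg2 <- 1 - 2 * q
  bad <- (arg1 <= 0 | arg2 <= 0) & upper.tri(arg1)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)
    rlang::abort(
      sprintf(
        "saturated pair(s): %s",
        paste(sprintf("%s-%s", rownames(m)[idx[, 1]], rownames(m)[idx[, 2]]),
          collapse = ", "
        )
      ),
      class = "mlstkit_saturation_error"
    )
  }
  d <- -0.5 * log(arg1) - 0.25 * log(arg2)
  diag(d) <- 0
  dimnames(d) <- list(names(seqs), names(seqs))
  d
}

#' Neighbour joining
#'
#' Saitou-Nei agglomeration with the standard Q criterion. Pair selection
#' ties are broken toward the smallest pair of current node indices (taxa
#' in input order, then internal nodes in creation order). Negative branch
#' lengths are clamped to zero with the deficit moved to the sibling
#' branch.
#'
#' @param dm Symmetric distance matrix with taxa as dimnames (or a `dist`).
#' @return An unrooted tree of class `phylo` (from the \pkg{ape} package).
#' @examples
#' dm <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
#' ape::write.tree(neighbour_joining(dm))
#' @export
neighbour_joining <- function(dm) {
  d <- as.matrix(dm)
  n <- nrow(d)
  if (n < 2) rlang::abort("neighbour joining needs at least 2 taxa")
  labs <- rownames(d)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  fmt <- function(x) sprintf("%.10g", max(x, 0))
  if (n == 2) {
    nwk <- sprintf("(%s:%s,%s:%s);", labs[1], fmt(d[1, 2] / 2), labs[2], fmt(d[1, 2] / 2))
    return(ape::read.tree(text = nwk))
  }
  sub <- labs # newick fragment per active node
  active <- seq_len(n)
  while (length(active) > 3) {
    k <- length(active)
    dd <- d[active, active]
    r <- rowSums(dd)
    q <- (k - 2) * dd - outer(r, r, `+`)
    diag(q) <- Inf
    best <- which(q == min(q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    i <- best[1]
    j <- best[2]
    bi <- dd[i, j] / 2 + (r[i] - r[j]) / (2 * (k - 2))
    bj <- dd[i, j] - bi
    if (bi < 0) {
      bj <- bj + bi
      bi <- 0
    } else if (bj < 0) {
      bi <- bi + bj
      bj <- 0
    }
    new_sub <- sprintf(
      "(%s:%s,%s:%s)", sub[active[i]], fmt(bi), sub[active[j]], fmt(bj)
    )
    du <- (d[active[i], active] + d[active[j], active] - dd[i, j]) / 2
    ai <- active[i]
    d[ai, active] <- du
    d[active, ai] <- du
    d[ai, ai] <- 0
    sub[ai] <- new_sub
    active <- active[-j]
  }
  a <- active
  b1 <- (d[a[1], a[2]] + d[a[1], a[3]] - d[a[2], a[3]]) / 2
  b2 <- (d[a[1], a[2]] + d[a[2], a[3]] - d[a[1], a[3]]) / 2
  b3 <- (d[a[1], a[3]] + d[a[2], a[3]] - d[a[1], a[2]]) / 2
  nwk <- sprintf(
    "(%s:%s,%s:%s,%s:%s);",
    sub[a[1]], fmt(b1), sub[a[2]], fmt(b2), sub[a[3]], fmt(b3)
  )
  ape::read.tree(text = nwk)
}

#' Neighbour-joining tree with bootstrap support
#'
#' Resamples alignment columns with replacement, rebuilds the K2P + NJ tree
#' for each replicate, and reports for every internal branch of the
#' full-data tree the percentage of replicates containing the same
#' bipartition (stored as `node.label`). Taxa are sorted canonically
#' (alphabetically) before any random draw, so support values do not
#' depend on input row order.
#'
#' @param alignment Equal-length sequences (character vector named by
#'   taxon, or tibble with `id` and `sequence`).
#' @param n_reps Number of bootstrap replicates (default 1000).
#' @param seed Integer seed for column resampling.
#' @return A `phylo` tree with `node.label` giving support in `[0, 100]`.
#' @export
bootstrap_support <- function(alignment, n_reps = 1000L, seed) {
  if (n_reps < 1) rlang::abort("n_reps must be >= 1")
  seqs <- as_seqs(alignment)
  if (is.null(names(seqs))) names(seqs) <- paste0("t", seq_along(seqs))
  seqs <- seqs[order(names(seqs))]
  m <- aln_matrix(seqs)
  base_tree <- neighbour_joining(k2p_matrix(seqs))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  trees <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    boot <- setNames(apply(m[, cols, drop = FALSE], 1L, paste, collapse = ""), names(seqs))
    trees[[r]] <- neighbour_joining(k2p_matrix(boot))
  }
  counts <- ape::prop.clades(base_tree, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  base_tree$node.label <- as.character(round(100 * counts / n_reps, 1))
  base_tree
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param dm Symmetric distance matrix with taxa as dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(dm, path) {
  d <- as.matrix(dm)
  lines <- c(
    sprintf("%5d", nrow(d)),
    vapply(seq_len(nrow(d)), function(i) {
      paste0(
        formatC(rownames(d)[i], width = -10),
        paste(sprintf("%.6f", d[i, ]), collapse = " ")
      )
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}
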