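# Split decomposition (Bandelt-Dress d-splits): isolation indices of
# bipartitions and the incremental taxon-insertion algorithm, with an
# exhaustive enumeration mode as oracle for small taxon sets. Incompatible
# splits with positive isolation index are the network signature of
# recombination.

# all unordered pairs (i <= j) from an index set, as a 2-column matrix
pairs_with_rep <- function(idx) {
  g <- expand.grid(i = idx, j = idx)
  as.matrix(g[g$i <= g$j, , drop = FALSE])
}

#' Isolation index of a bipartition
#'
#' For a split of the taxa into sides `A` and `B`,
#' `alpha(A, B) = (1/2) min over i,j in A and k,l in B` of
#' `max(d(i,k) + d(j,l), d(i,l) + d(j,k), d(i,j) + d(k,l)) - d(i,j) - d(k,l)`
#' (pairs with `i = j` or `k = l` included, which covers singleton sides).
#' Splits with positive `alpha` are d-splits; for a tree-additive metric
#' the d-splits are exactly the tree's edges and `alpha` recovers their
#' branch lengths.
#'
#' @param dm Symmetric distance matrix with taxa as dimnames.
#' @param side_a Character vector of taxon labels (or integer indices)
#'   forming one side of the split; the other side is the complement.
#' @return Numeric isolation index (may be `<= 0` for non-d-splits).
#' @export
isolation_index <- function(dm, side_a) {
  d <- as.matrix(dm)
  n <- nrow(d)
  taxa <- rownames(d)
  if (is.null(taxa)) {
    taxa <- paste0("t", seq_len(n))
    dimnames(d) <- list(taxa, taxa)
  }
  ia <- if (is.character(side_a)) match(side_a, taxa) else as.integer(side_a)
  if (anyNA(ia)) rlang::abort("unknown taxa in side_a")
  ia <- unique(ia)
  ib <- setdiff(seq_len(n), ia)
  if (length(ia) == 0 || length(ib) == 0) {
    rlang::abort("split must have two non-empty sides")
  }
  pa <- pairs_with_rep(ia)
  pb <- pairs_with_rep(ib)
  d_ij <- d[pa] # d(i,j), zero when i = j
  d_kl <- d[pb]
  t1 <- d[pa[, 1], pb[, 1], drop = FALSE] + d[pa[, 2], pb[, 2], drop = FALSE]
  t2 <- d[pa[, 1], pb[, 2], drop = FALSE] + d[pa[, 2], pb[, 1], drop = FALSE]
  t3 <- outer(d_ij, d_kl, `+`)
  beta <- pmax(t1, t2, t3) - t3
  0.5 * min(beta)
}

canonical_split <- function(side_a, taxa) {
  # store the side not containing the first taxon
  if (taxa[1] %in% side_a) setdiff(taxa, side_a) else side_a
}

#' Split decomposition of a distance matrix
#'
#' Finds all splits with positive isolation index (d-splits). The default
#' incremental algorithm inserts taxa one at a time, extending each
#' currently held split both ways and adding the new trivial split,
#' keeping candidates with `alpha > 0` -- the classic split-decomposition
#' construction, valid because d-splits form a weakly compatible system.
#' `method = "exhaustive"` enumerates every bipartition (taxa count
#' capped at 12) and serves as an independent oracle.
#'
#' @param dm Symmetric distance matrix with taxa as dimnames.
#' @param method `"incremental"` or `"exhaustive"`.
#' @param alpha_min Keep splits with `alpha` strictly greater than this
#'   (default 0; small tolerance added internally for float noise).
#' @return An object of class `mlst_splits`: list with `taxa`, `splits`
#'   (tibble: `id`, `side_a` list-column of taxon labels, `size_a`,
#'   `alpha`, `trivial`) and `fit` (percentage of the total pairwise
#'   distance represented by the split metric; 100 for additive metrics).
#' @export
split_decomposition <- function(dm, method = c("incremental", "exhaustive"),
                                alpha_min = 0) {
  method <- match.arg(method)
  d <- as.matrix(dm)
  n <- nrow(d)
  taxa <- rownames(d)
  if (is.null(taxa)) {
    taxa <- paste0("t", seq_len(n))
    dimnames(d) <- list(taxa, taxa)
  }
  if (n < 2) rlang::abort("split decomposition needs >= 2 taxa")
  tol <- 1e-10
  sides <- list()
  if (method == "exhaustive") {
    if (n > 12) rlang::abort("exhaustive mode is capped at 12 taxa")
    for (code in seq_len(2^(n - 1) - 1)) {
      side <- which(as.logical(bitwAnd(code, 2^(seq_len(n) - 1))))
      a <- isolation_index(d, side)
      if (a > alpha_min + tol) sides <- c(sides, list(side))
    }
  } else {
    sides <- list(1L) # split {t1} | {t2} on the first two taxa
    for (t in 3:max(3, n)) {
      if (t > n) break
      cand <- list()
      for (s in sides) {
        cand <- c(cand, list(s, c(s, t)))
      }
      cand <- c(cand, list(t))
      keep <- list()
      for (s in cand) {
        sub <- d[1:t, 1:t, drop = FALSE]
        a <- isolation_index(sub, s)
        if (a > alpha_min + tol) keep <- c(keep, list(s))
      }
      sides <- keep
    }
    if (n == 2) sides <- list(1L)
  }
  alphas <- vapply(sides, function(s) isolation_index(d, s), numeric(1))
  ok <- alphas > alpha_min + tol
  sides <- sides[ok]
  alphas <- alphas[ok]
  side_lab <- lapply(sides, function(s) canonical_split(taxa[s], taxa))
  o <- order(-alphas, vapply(side_lab, length, integer(1)))
  side_lab <- side_lab[o]
  alphas <- alphas[o]
  splits <- tibble(
    id = seq_along(alphas),
    side_a = side_lab,
    size_a = vapply(side_lab, length, integer(1)),
    alpha = alphas,
    trivial = vapply(side_lab, length, integer(1)) == 1L |
      vapply(side_lab, length, integer(1)) == n - 1L
  )
  # fit: share of the pairwise distance explained by the split metric
  approx <- matrix(0, n, n, dimnames = dimnames(d))
  for (k in seq_len(nrow(splits))) {
    in_a <- taxa %in% splits$side_a[[k]]
    sep <- outer(in_a, in_a, `!=`)
    approx <- approx + splits$alpha[k] * sep
  }
  tot <- sum(d[upper.tri(d)])
  fit <- if (tot > 0) 100 * sum(approx[upper.tri(approx)]) / tot else 100
  structure(
    list(taxa = taxa, splits = splits, fit = fit),
    class = "mlst_splits"
  )
}

#' @export
print.mlst_splits <- function(x, ...) {
  cat(sprintf(
    "<mlst_splits> %d taxa, %d d-splits (%d non-trivial), fit %.1f%%\n",
    length(x$taxa), nrow(x$splits), sum(!x$splits$trivial), x$fit
  ))
  invisible(x)
}

#' Tidy a split system
#'
#' @param x An `mlst_splits` object.
#' @param ... Unused.
#' @return `tidy()`: the splits tibble with `side_a` rendered as a
#'   comma-separated string. `glance()`: one-row summary with split counts
#'   and fit.
#' @method tidy mlst_splits
#' @export
tidy.mlst_splits <- function(x, ...) {
  mutate(x$splits, side_a = vapply(.data$side_a, paste, character(1), collapse = ","))
}

#' @rdname tidy.mlst_splits
#' @method glance mlst_splits
#' @export
glance.mlst_splits <- function(x, ...) {
  tibble(
    n_taxa = length(x$taxa), n_splits = nrow(x$splits),
    n_nontrivial = sum(!x$splits$trivial), fit = x$fit
  )
}

# do two splits cross (all four intersections non-empty)?
splits_cross <- function(a1, a2, taxa) {
  b1 <- setdiff(taxa, a1)
  b2 <- setdiff(taxa, a2)
  length(intersect(a1, a2)) > 0 && length(intersect(a1, b2)) > 0 &&
    length(intersect(b1, a2)) > 0 && length(intersect(b1, b2)) > 0
}

#' Write a split system as a NEXUS splits block
#'
#' Produces a minimal NEXUS file with a `TAXA` block and a SplitsTree-style
#' `SPLITS` block (split weights = isolation indices).
#'
#' @param splits An `mlst_splits` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_nexus_splits <- function(splits, path) {
  taxa <- splits$taxa
  lines <- c(
    "#NEXUS",
    "BEGIN TAXA;",
    sprintf("  DIMENSIONS NTAX=%d;", length(taxa)),
    "  TAXLABELS",
    sprintf("    '%s'", taxa),
    "  ;",
    "END;",
    "BEGIN SPLITS;",
    sprintf(
      "  DIMENSIONS NTAX=%d NSPLITS=%d;", length(taxa),
      nrow(splits$splits)
    ),
    "  FORMAT LABELS=NO WEIGHTS=YES;",
    "  MATRIX"
  )
  for (k in seq_len(nrow(splits$splits))) {
    idx <- match(splits$splits$side_a[[k]], taxa)
    lines <- c(lines, sprintf(
      "    [%d] %.8g %s,",
      k, splits$splits$alpha[k], paste(idx, collapse = " ")
    ))
  }
  lines <- c(lines, "  ;", "END;")
  writeLines(lines, path)
  invisible(path)
}
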