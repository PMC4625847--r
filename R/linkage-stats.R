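# Multilocus linkage disequilibrium: index of association (I_A), its
# standardized form (I_A^S), and a permutation test that shuffles alleles
# independently within each locus.

#' Pairwise allelic mismatch distribution
#'
#' Allelic distances for all unordered pairs of profiles; the variance of
#' this distribution is the V_D entering the index of association.
#'
#' @param profiles A matrix/data frame of allele numbers (rows = units,
#'   columns = loci), or an `mlst_profiles` object (ST profiles are used).
#' @return Integer vector of length `n(n-1)/2`.
#' @examples
#' mismatch_distribution(rbind(c(1, 1), c(1, 1), c(2, 2), c(2, 2)))
#' @export
mismatch_distribution <- function(profiles) {
  m <- as_profile_matrix(profiles)
  if (nrow(m) < 2) rlang::abort("need at least 2 profiles")
  d <- matrix(0L, nrow(m), nrow(m))
  for (j in seq_len(ncol(m))) d <- d + outer(m[, j], m[, j], `!=`)
  as.integer(d[upper.tri(d)])
}

as_profile_matrix <- function(profiles, unit = "isolates") {
  if (inherits(profiles, "mlst_profiles")) {
    m <- profile_matrix(profiles)
    if (unit == "isolates") {
      m <- m[match(profiles$membership$st, profiles$profiles$st), , drop = FALSE]
      rownames(m) <- profiles$membership$isolate_id
    }
    return(m)
  }
  m <- as.matrix(profiles)
  storage.mode(m) <- "integer"
  m
}

ia_core <- function(m, hj_bias = c("unbiased", "biased")) {
  hj_bias <- match.arg(hj_bias)
  n <- nrow(m)
  l <- ncol(m)
  dist <- {
    d <- matrix(0L, n, n)
    for (j in seq_len(l)) d <- d + outer(m[, j], m[, j], `!=`)
    as.numeric(d[upper.tri(d)])
  }
  n_pairs <- length(dist)
  v_d <- mean(dist^2) - mean(dist)^2 # population variance over pairs
  h <- vapply(seq_len(l), function(j) {
    p <- table(m[, j]) / n
    h0 <- 1 - sum(p^2)
    if (hj_bias == "unbiased") n / (n - 1) * h0 else h0
  }, numeric(1))
  v_e <- sum(h * (1 - h))
  list(v_d = v_d, v_e = v_e, n = n, l = l, n_pairs = n_pairs)
}

#' Index of association and standardized index of association
#'
#' Measures multilocus linkage disequilibrium. With `V_D` the variance of
#' pairwise allelic mismatch counts and `V_e` its expectation under
#' inter-locus independence (`V_e = sum_j h_j (1 - h_j)` with `h_j` the
#' per-locus mismatch probability), `I_A = V_D / V_e - 1` and
#' `I_A^S = I_A / (l - 1)`. Both are zero in expectation under linkage
#' equilibrium (free recombination) and positive under clonality. `h_j`
#' uses the unbiased `n/(n-1)` factor by default. An optional permutation
#' test shuffles the allele column of each locus independently; the p-value
#' is `(1 + #{permuted V_D >= observed V_D}) / (1 + n_perm)`.
#'
#' @param profiles An `mlst_profiles` object or a matrix/data frame of
#'   allele numbers (rows = units, columns = loci).
#' @param unit `"isolates"` (each isolate contributes its profile; default)
#'   or `"unique_sts"` (each ST once). Ignored for plain matrices.
#' @param hj_bias `"unbiased"` (`n/(n-1)` factor, default) or `"biased"`.
#' @param n_perm Number of permutations for the significance test
#'   (0 skips the test).
#' @param seed Integer seed for the permutation null; required when
#'   `n_perm > 0`.
#' @return An object of class `mlst_linkage`: list with `n_units`,
#'   `l_loci`, `v_d`, `v_e`, `i_a`, `i_a_s`, `p_value`, `n_permutations`,
#'   `seed`, `permuted_v_d` (numeric vector, for plotting), `hj_bias`,
#'   `unit`.
#' @examples
#' fit <- index_of_association(rbind(c(1, 1), c(1, 1), c(2, 2), c(2, 2)))
#' fit$i_a # 1.0
#' @export
index_of_association <- function(profiles, unit = c("isolates", "unique_sts"),
                                 hj_bias = c("unbiased", "biased"),
                                 n_perm = 0L, seed = NULL) {
  unit <- match.arg(unit)
  hj_bias <- match.arg(hj_bias)
  m <- as_profile_matrix(profiles, if (unit == "isolates") "isolates" else "sts")
  if (nrow(m) < 3) rlang::abort("index of association needs >= 3 profiles")
  if (ncol(m) < 2) rlang::abort("I_A^S is undefined for a single locus")
  obs <- ia_core(m, hj_bias)
  if (obs$v_e == 0) {
    rlang::abort("all loci are monomorphic: V_e = 0, I_A undefined",
      class = "mlstkit_degenerate_stat"
    )
  }
  i_a <- obs$v_d / obs$v_e - 1
  out <- list(
    n_units = obs$n, l_loci = obs$l, v_d = obs$v_d, v_e = obs$v_e,
    i_a = i_a, i_a_s = i_a / (obs$l - 1),
    p_value = NA_real_, n_permutations = as.integer(n_perm),
    seed = seed, permuted_v_d = numeric(0),
    hj_bias = hj_bias, unit = unit
  )
  if (n_perm > 0) {
    if (is.null(seed)) rlang::abort("a seed is required for the permutation test")
    perm <- permutation_test(m, n_perm = n_perm, seed = seed, hj_bias = hj_bias)
    out$p_value <- perm$p_value
    out$permuted_v_d <- perm$permuted_v_d
  }
  structure(out, class = "mlst_linkage")
}

#' Permutation test for the index of association
#'
#' Generates the linkage-equilibrium null by independently permuting the
#' allele column at each locus and recomputing `V_D`.
#'
#' @param profiles Matrix/data frame of allele numbers or `mlst_profiles`.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed (reproducible null).
#' @param hj_bias See [index_of_association()].
#' @return List with `p_value`, `permuted_v_d`, `observed_v_d`.
#' @export
permutation_test <- function(profiles, n_perm = 1000L, seed, hj_bias = "unbiased") {
  if (n_perm < 1) rlang::abort("n_perm must be >= 1")
  m <- as_profile_matrix(profiles)
  obs <- ia_core(m, hj_bias)$v_d
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  perm_vd <- vapply(seq_len(n_perm), function(r) {
    mp <- apply(m, 2L, sample)
    ia_core(mp, hj_bias)$v_d
  }, numeric(1))
  list(
    p_value = (1 + sum(perm_vd >= obs)) / (1 + n_perm),
    permuted_v_d = perm_vd, observed_v_d = obs
  )
}

# save/restore global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.mlst_linkage <- function(x, ...) {
  cat(sprintf(
    "<mlst_linkage> %d %s x %d loci\n  V_D = %.4g, V_e = %.4g, I_A = %.4g, I_A^S = %.4g\n",
    x$n_units, x$unit, x$l_loci, x$v_d, x$v_e, x$i_a, x$i_a_s
  ))
  if (!is.na(x$p_value)) {
    cat(sprintf(
      "  permutation P = %.4g (%d permutations, seed %s)\n",
      x$p_value, x$n_permutations, format(x$seed)
    ))
  }
  invisible(x)
}

#' Tidy linkage-disequilibrium results
#'
#' @param x An `mlst_linkage` object.
#' @param ... Unused.
#' @return `tidy()`: a two-row tibble (one per statistic, `I_A` and
#'   `I_A^S`) with the shared permutation p-value. `glance()`: a one-row
#'   tibble with every scalar field.
#' @method tidy mlst_linkage
#' @export
tidy.mlst_linkage <- function(x, ...) {
  tibble(
    statistic = c("I_A", "I_A_S"),
    estimate = c(x$i_a, x$i_a_s),
    p_value = rep(x$p_value, 2)
  )
}

#' @rdname tidy.mlst_linkage
#' @method glance mlst_linkage
#' @export
glance.mlst_linkage <- function(x, ...) {
  tibble(
    n_units = x$n_units, l_loci = x$l_loci, v_d = x$v_d, v_e = x$v_e,
    i_a = x$i_a, i_a_s = x$i_a_s, p_value = x$p_value,
    n_permutations = x$n_permutations, unit = x$unit, hj_bias = x$hj_bias
  )
}
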