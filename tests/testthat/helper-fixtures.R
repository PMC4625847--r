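# Fixtures and independent oracles used across the suite. Everything is
# generated in code; oracles are deliberately naive (loops, enumeration)
# and never share code with the package internals they check.

# small complete two-locus dataset built by hand
tiny_dataset <- function() {
  seqs <- tibble::tibble(
    isolate_id = rep(c("isoA", "isoB", "isoC"), 2),
    locus = rep(c("l1", "l2"), each = 3),
    sequence = c(
      "ATGAAAGGG", "ATGAAAGGG", "ATGAAAGGT",
      "ATGCCCTTTAAA", "ATGCCGTTTAAA", "ATGCCCTTTAAA"
    )
  )
  build_mlst_dataset(seqs)
}

# random allelic profile matrix (rows = units)
random_profile_matrix <- function(n, l, n_alleles = 3L) {
  matrix(sample.int(n_alleles, n * l, replace = TRUE), nrow = n)
}

# random alignment of equal-length sequences, optional N contamination
random_alignment <- function(n, len, n_rate = 0) {
  vapply(seq_len(n), function(i) {
    chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    if (n_rate > 0) {
      idx <- which(stats::runif(len) < n_rate)
      chars[idx] <- "N"
    }
    paste(chars, collapse = "")
  }, character(1))
}

# oracle: pi by explicit double loop over pairs and sites
oracle_pi <- function(seqs) {
  m <- strsplit(seqs, "")
  n <- length(seqs)
  vals <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- m[[i]]
      b <- m[[j]]
      ok <- a != "N" & b != "N"
      if (!any(ok)) next
      vals <- c(vals, sum(a[ok] != b[ok]) / sum(ok))
    }
  }
  mean(vals)
}

# oracle: V_D as plain variance (divide by number of pairs) of pairwise
# allelic mismatch counts
oracle_vd <- function(m) {
  n <- nrow(m)
  d <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- c(d, sum(m[i, ] != m[j, ]))
    }
  }
  mean(d^2) - mean(d)^2
}

# oracle: clonal-complex partition by breadth-first search on the SLV-style
# graph (edge iff 0 < distance <= max_dist)
oracle_cc_partition <- function(m, max_dist = 1L) {
  n <- nrow(m)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      dij <- sum(m[i, ] != m[j, ])
      adj[i, j] <- i != j && dij <= max_dist
    }
  }
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# oracle: minimum spanning tree weight by exhaustive enumeration of all
# (n-1)-edge subsets (tiny n only)
oracle_mst_weight <- function(d) {
  n <- nrow(d)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  best <- Inf
  for (sel in utils::combn(nrow(pairs), n - 1, simplify = FALSE)) {
    e <- pairs[sel, , drop = FALSE]
    parent <- seq_len(n)
    find <- function(i) {
      while (parent[i] != i) i <- parent[i]
      i
    }
    acyclic <- TRUE
    for (k in seq_len(nrow(e))) {
      ri <- find(e[k, 1])
      rj <- find(e[k, 2])
      if (ri == rj) {
        acyclic <- FALSE
        break
      }
      parent[ri] <- rj
    }
    if (acyclic && length(unique(vapply(seq_len(n), find, integer(1)))) == 1) {
      best <- min(best, sum(d[e]))
    }
  }
  best
}

# oracle: isolation index by explicit quadruple loop
oracle_alpha <- function(d, side_a) {
  n <- nrow(d)
  b <- setdiff(seq_len(n), side_a)
  best <- Inf
  for (i in side_a) {
    for (j in side_a) {
      for (k in b) {
        for (l in b) {
          v <- max(
            d[i, k] + d[j, l], d[i, l] + d[j, k],
            d[i, j] + d[k, l]
          ) - d[i, j] - d[k, l]
          best <- min(best, v)
        }
      }
    }
  }
  best / 2
}

# oracle: all d-splits by exhaustive bipartition enumeration with oracle_alpha
oracle_dsplits <- function(d) {
  n <- nrow(d)
  out <- list()
  for (code in seq_len(2^(n - 1) - 1)) {
    side <- which(as.logical(bitwAnd(code, 2^(seq_len(n) - 1))))
    a <- oracle_alpha(d, side)
    if (a > 1e-10) out <- c(out, list(list(side = side, alpha = a)))
  }
  out
}

# random unrooted binary tree with positive branch lengths, as ape::phylo,
# plus its additive distance matrix
random_additive_tree <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE, br = function(k) stats::runif(k, 0.1, 1))
  tr$tip.label <- paste0("t", seq_len(n_taxa))
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

# canonical partition signature: blocks as sorted strings, order-free
partition_signature <- function(labels, block) {
  blocks <- split(labels, block)
  unname(sort(vapply(blocks, function(b) paste(sort(b), collapse = ","), character(1))))
}

# helper: wrap a profile matrix as a minimal mlst_profiles object
profiles_from_matrix <- function(m, sizes = rep(1L, nrow(m))) {
  loci <- paste0("L", seq_len(ncol(m)))
  colnames(m) <- loci
  prof <- tibble::as_tibble(m)
  prof$st <- seq_len(nrow(m))
  prof$n_isolates <- as.integer(sizes)
  membership <- tibble::tibble(
    isolate_id = unlist(lapply(seq_len(nrow(m)), function(i) {
      sprintf("i%d_%d", i, seq_len(sizes[i]))
    })),
    st = rep(seq_len(nrow(m)), sizes)
  )
  structure(
    list(
      catalogs = tibble::tibble(), membership = membership,
      profiles = dplyr::select(prof, "st", dplyr::all_of(loci), "n_isolates"),
      loci = loci
    ),
    class = "mlst_profiles"
  )
}
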