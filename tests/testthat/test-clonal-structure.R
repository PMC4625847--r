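test_that("allelic distance counts differing loci and matches a positional oracle", {
  expect_equal(allelic_distance(c(1, 1, 1), c(1, 1, 1)), 0)
  expect_equal(allelic_distance(c(1, 1, 1), c(1, 1, 2)), 1)
  expect_error(allelic_distance(1:3, 1:4), class = "mlstkit_length_error")
  withr::with_seed(42, {
    for (r in 1:50) {
      a <- sample.int(5, 8, replace = TRUE)
      b <- sample.int(5, 8, replace = TRUE)
      oracle <- sum(vapply(1:8, function(i) a[i] != b[i], logical(1)))
      expect_equal(allelic_distance(a, b), oracle)
    }
  })
})

test_that("clonal complexes are the SLV components; singletons stay out", {
  m <- rbind(c(1, 1, 1), c(1, 1, 2), c(1, 2, 2), c(3, 3, 3))
  p <- profiles_from_matrix(m)
  cc <- find_clonal_complexes(p, group_threshold = 2)
  expect_equal(nrow(cc$complexes), 1)
  expect_equal(sort(cc$assignments$st[!is.na(cc$assignments$complex)]), 1:3)
  expect_equal(cc$singletons, 4L)

  # all pairwise distance L: no complexes at all
  m2 <- rbind(c(1, 1, 1), c(2, 2, 2), c(3, 3, 3))
  cc2 <- find_clonal_complexes(profiles_from_matrix(m2), group_threshold = 2)
  expect_equal(nrow(cc2$complexes), 0)
  expect_equal(cc2$singletons, 1:3)

  expect_error(find_clonal_complexes(p, group_threshold = 0))
})

test_that("CC partition equals an independent BFS oracle on random instances", {
  withr::with_seed(99, {
    for (r in 1:40) {
      n <- sample(3:7, 1)
      l <- sample(3:8, 1)
      m <- random_profile_matrix(n, l, n_alleles = 3L)
      m <- m[!duplicated(m), , drop = FALSE]
      if (nrow(m) < 2) next
      p <- profiles_from_matrix(m)
      cc <- find_clonal_complexes(p, group_threshold = ncol(m) - 1L)
      got <- ifelse(is.na(cc$assignments$complex),
        paste0("S", cc$assignments$st), cc$assignments$complex
      )
      want <- oracle_cc_partition(m, max_dist = 1L)
      expect_equal(
        partition_signature(seq_len(nrow(m)), got),
        partition_signature(seq_len(nrow(m)), want)
      )
    }
  })
})

test_that("raising the grouping threshold only refines complexes", {
  withr::with_seed(7, m <- random_profile_matrix(12, 5, n_alleles = 2L))
  m <- m[!duplicated(m), , drop = FALSE]
  p <- profiles_from_matrix(m)
  prev <- NULL
  for (thr in 1:5) {
    cc <- find_clonal_complexes(p, group_threshold = thr)
    block <- ifelse(is.na(cc$assignments$complex),
      paste0("S", cc$assignments$st), cc$assignments$complex
    )
    if (!is.null(prev)) {
      # every block at the stricter threshold sits inside one looser block
      for (b in unique(block)) {
        expect_length(unique(prev[block == b]), 1)
      }
    }
    prev <- block
  }
})

test_that("founder prediction maximises SLV count with the documented tie-breaks", {
  # chain ST1 - ST2 - ST3: ST2 has 2 SLVs
  m <- rbind(c(1, 1, 1), c(1, 1, 2), c(1, 2, 2))
  f <- predict_founder(profiles_from_matrix(m), 1:3)
  expect_equal(f$founder_st, 2L)
  expect_equal(f$slv, 2)
  expect_equal(f$tie_break, "slv")

  # symmetric pair: isolate count decides
  m2 <- rbind(c(1, 1, 1), c(1, 1, 2))
  f2 <- predict_founder(profiles_from_matrix(m2, sizes = c(1L, 5L)), 1:2)
  expect_equal(f2$founder_st, 2L)
  expect_equal(f2$tie_break, "isolates")

  # fully symmetric: lower ST number
  f3 <- predict_founder(profiles_from_matrix(m2), 1:2)
  expect_equal(f3$founder_st, 1L)
  expect_equal(f3$tie_break, "st_number")
})

test_that("MST weight matches igraph and exhaustive enumeration oracles", {
  withr::with_seed(31, {
    for (r in 1:30) {
      n <- sample(4:7, 1)
      m <- random_profile_matrix(n, 6, n_alleles = 4L)
      m <- m[!duplicated(m), , drop = FALSE]
      if (nrow(m) < 3) next
      p <- profiles_from_matrix(m)
      mst <- build_mst(p)
      d <- matrix(0L, nrow(m), nrow(m))
      for (j in seq_len(ncol(m))) d <- d + outer(m[, j], m[, j], `!=`)
      g <- igraph::graph_from_adjacency_matrix(d, weighted = TRUE, mode = "undirected")
      ig_w <- sum(igraph::E(igraph::mst(g))$weight)
      expect_equal(mst$total_weight, ig_w)
      if (nrow(m) <= 5) {
        expect_equal(mst$total_weight, oracle_mst_weight(d))
      }
      # tree shape: |E| = |V| - 1, connected
      expect_equal(nrow(mst$edges), nrow(m) - 1)
      gg <- igraph::graph_from_data_frame(mst$edges[1:2], directed = FALSE)
      expect_true(igraph::is_connected(gg))
    }
  })
})

test_that("MST beats 1000 random spanning trees and handles known ties", {
  # 3 STs with pairwise distances 1, 1, 2: the two distance-1 edges win
  m <- rbind(c(1, 1), c(1, 2), c(2, 2))
  mst <- build_mst(profiles_from_matrix(m))
  expect_equal(mst$total_weight, 2)
  expect_equal(sort(mst$edges$distance), c(1L, 1L))

  # two STs: the single edge
  m2 <- rbind(c(1, 1), c(1, 2))
  mst2 <- build_mst(profiles_from_matrix(m2))
  expect_equal(nrow(mst2$edges), 1)

  withr::with_seed(13, {
    m3 <- random_profile_matrix(8, 6, n_alleles = 3L)
    m3 <- m3[!duplicated(m3), , drop = FALSE]
    p3 <- profiles_from_matrix(m3)
    mst3 <- build_mst(p3)
    n <- nrow(m3)
    d <- matrix(0L, n, n)
    for (j in seq_len(ncol(m3))) d <- d + outer(m3[, j], m3[, j], `!=`)
    for (r in 1:1000) {
      # random spanning tree by random-order Kruskal
      pairs <- which(upper.tri(d), arr.ind = TRUE)
      ord <- sample(nrow(pairs))
      parent <- seq_len(n)
      find <- function(i) {
        while (parent[i] != i) i <- parent[i]
        i
      }
      w <- 0L
      for (k in ord) {
        ri <- find(pairs[k, 1])
        rj <- find(pairs[k, 2])
        if (ri != rj) {
          parent[ri] <- rj
          w <- w + d[pairs[k, 1], pairs[k, 2]]
        }
      }
      expect_gte(w, mst3$total_weight)
    }
  })
})

test_that("degenerate single-ST table yields a one-node tree with a warning", {
  p <- profiles_from_matrix(rbind(c(1, 1, 1)))
  expect_warning(mst <- build_mst(p), "degenerate")
  expect_equal(nrow(mst$edges), 0)
  expect_equal(nrow(mst$nodes), 1)
})

test_that("MST and CC tables export to GraphML, DOT and TSV", {
  m <- rbind(c(1, 1, 1), c(1, 1, 2), c(1, 2, 2), c(3, 3, 3))
  p <- profiles_from_matrix(m)
  mst <- build_mst(p)
  cc <- find_clonal_complexes(p, group_threshold = 2)
  d <- withr::local_tempdir()
  write_mst_graphml(mst, file.path(d, "m.graphml"))
  g <- igraph::read_graph(file.path(d, "m.graphml"), format = "graphml")
  expect_equal(igraph::vcount(g), 4)
  expect_equal(igraph::ecount(g), 3)
  write_mst_dot(mst, file.path(d, "m.dot"))
  expect_match(readLines(file.path(d, "m.dot"))[1], "graph mst")
  write_cc_table(cc, file.path(d, "cc.tsv"))
  tab <- read.delim(file.path(d, "cc.tsv"))
  expect_equal(names(tab), c("ST", "complex", "founder_flag"))
  expect_equal(sum(tab$founder_flag), 1)
})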