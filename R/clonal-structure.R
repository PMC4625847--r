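# Clonal structure from allelic profiles: single-locus-variant (SLV) graph
# grouping in the eBURST sense, founder prediction, and a deterministic
# Kruskal minimum spanning tree over the complete allelic-distance graph.

#' Allelic distance between two profiles
#'
#' Number of loci at which two allelic profiles carry different allele
#' numbers.
#'
#' @param a,b Integer vectors of allele numbers, one entry per locus, in the
#'   same locus order.
#' @return Integer count in `[0, L]`.
#' @examples
#' allelic_distance(c(1, 1, 1), c(1, 1, 2))
#' @export
allelic_distance <- function(a, b) {
  if (length(a) != length(b)) {
    rlang::abort("profiles differ in length", class = "mlstkit_length_error")
  }
  sum(a != b)
}

# S x S matrix of allelic distances between ST profiles
profile_distance_matrix <- function(profiles) {
  m <- profile_matrix(profiles)
  s <- nrow(m)
  d <- matrix(0L, s, s, dimnames = list(rownames(m), rownames(m)))
  for (j in seq_len(ncol(m))) {
    d <- d + outer(m[, j], m[, j], `!=`)
  }
  d
}

# union-find with path compression (internal; also used by Kruskal)
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

connected_components <- function(n, edges) {
  parent <- uf_new(n)
  if (nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      ri <- uf_find(parent, edges$i[k])
      rj <- uf_find(parent, edges$j[k])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  match(roots, unique(roots))
}

#' Predict the founder sequence type of a clonal complex
#'
#' The founder is the member ST with the most single-locus variants (SLVs)
#' in the profile table. Ties are broken by the larger double-locus-variant
#' (DLV) count, then the larger isolate count, then the smaller ST number;
#' the tie-break chain actually used is reported.
#'
#' @param profiles An `mlst_profiles` object.
#' @param members Integer vector of member ST numbers (at least 2).
#' @return A list with `founder_st`, `slv`, and `tie_break` (one of
#'   `"slv"`, `"dlv"`, `"isolates"`, `"st_number"`).
#' @export
predict_founder <- function(profiles, members) {
  if (length(members) < 2) rlang::abort("a clonal complex needs >= 2 member STs")
  d <- profile_distance_matrix(profiles)
  slv <- rowSums(d == 1L)[as.character(members)]
  dlv <- rowSums(d == 2L)[as.character(members)]
  size <- profiles$profiles$n_isolates[match(members, profiles$profiles$st)]
  cand <- seq_along(members)
  steps <- list(slv = slv, dlv = dlv, isolates = size, st_number = -members)
  used <- "slv"
  for (nm in names(steps)) {
    keep <- cand[steps[[nm]][cand] == max(steps[[nm]][cand])]
    if (length(keep) < length(cand)) used <- nm
    cand <- keep
    if (length(cand) == 1L) break
  }
  list(founder_st = members[cand[1]], slv = unname(slv[cand[1]]), tie_break = used)
}

#' Group sequence types into clonal complexes
#'
#' Builds the eBURST-style graph linking STs that share at least
#' `group_threshold` of the `L` loci (allelic distance at most
#' `L - group_threshold`; the default `L - 1` links single-locus variants).
#' Clonal complexes (CCs) are the connected components with two or more
#' member STs, labelled CC1, CC2, ... by descending isolate count (ties:
#' more STs, then smaller minimum ST number); remaining STs are singletons.
#' Each CC is annotated with its predicted founder (see
#' [predict_founder()]).
#'
#' @param profiles An `mlst_profiles` object.
#' @param group_threshold Minimum number of shared alleles for a link;
#'   between 1 and the number of loci. Default `L - 1`.
#' @return An object of class `mlst_cc`: list with
#'   * `assignments` — tibble (`st`, `complex` or `NA` for singletons,
#'     `n_isolates`, `slv`, `dlv`, `is_founder`);
#'   * `complexes` — tibble (`complex`, `n_sts`, `n_isolates`,
#'     `founder_st`, `founder_slv`, `tie_break`);
#'   * `singletons` — integer vector of singleton ST numbers;
#'   * `group_threshold`.
#' @examples
#' d <- simulate_population(sim_config(n_isolates = 30, seed = 4))$dataset
#' find_clonal_complexes(assign_profiles(d))
#' @export
find_clonal_complexes <- function(profiles, group_threshold = NULL) {
  L <- length(profiles$loci)
  if (is.null(group_threshold)) group_threshold <- L - 1L
  if (group_threshold < 1L || group_threshold > L) {
    rlang::abort(sprintf("group_threshold must be in [1, %d]", L))
  }
  sts <- profiles$profiles$st
  d <- profile_distance_matrix(profiles)
  slv <- rowSums(d == 1L)
  dlv <- rowSums(d == 2L)
  link <- which(d > 0L & d <= (L - group_threshold) & upper.tri(d), arr.ind = TRUE)
  comp <- connected_components(length(sts), tibble(i = link[, 1], j = link[, 2]))

  sizes <- profiles$profiles$n_isolates
  comp_tbl <- tibble(st = sts, comp = comp, n_isolates = sizes) |>
    group_by(.data$comp) |>
    summarise(
      n_sts = dplyr::n(), n_isolates = sum(.data$n_isolates),
      min_st = min(.data$st), .groups = "drop"
    )
  cc_rows <- comp_tbl |>
    filter(.data$n_sts >= 2L) |>
    arrange(dplyr::desc(.data$n_isolates), dplyr::desc(.data$n_sts), .data$min_st)
  cc_label <- setNames(
    if (nrow(cc_rows)) paste0("CC", seq_len(nrow(cc_rows))) else character(0),
    cc_rows$comp
  )

  complexes <- vector("list", nrow(cc_rows))
  founder_of <- integer(0)
  for (k in seq_len(nrow(cc_rows))) {
    members <- sts[comp == cc_rows$comp[k]]
    f <- predict_founder(profiles, members)
    founder_of[cc_label[as.character(cc_rows$comp[k])]] <- f$founder_st
    complexes[[k]] <- tibble(
      complex = cc_label[as.character(cc_rows$comp[k])],
      n_sts = cc_rows$n_sts[k], n_isolates = cc_rows$n_isolates[k],
      founder_st = f$founder_st, founder_slv = f$slv, tie_break = f$tie_break
    )
  }
  complexes <- bind_rows(complexes)

  assignments <- tibble(
    st = sts,
    complex = unname(cc_label[as.character(comp)]),
    n_isolates = sizes, slv = as.integer(slv), dlv = as.integer(dlv)
  ) |>
    mutate(is_founder = .data$st %in% founder_of &
      !is.na(.data$complex) &
      .data$st == unname(founder_of[.data$complex]))
  singletons <- sts[is.na(assignments$complex)]
  structure(
    list(
      assignments = assignments, complexes = complexes,
      singletons = singletons, group_threshold = group_threshold
    ),
    class = "mlst_cc"
  )
}

#' @export
print.mlst_cc <- function(x, ...) {
  cat(sprintf(
    "<mlst_cc> %d clonal complexes, %d singletons (threshold: share >= %d alleles)\n",
    nrow(x$complexes), length(x$singletons), x$group_threshold
  ))
  if (nrow(x$complexes)) print(head(x$complexes, 10))
  invisible(x)
}

#' Tidy clonal-complex assignments
#'
#' @param x An `mlst_cc` object.
#' @param ... Unused.
#' @return `tidy()`: the per-ST assignment tibble. `glance()`: one-row
#'   summary (CC count, singleton count, largest CC size, threshold).
#' @method tidy mlst_cc
#' @export
tidy.mlst_cc <- function(x, ...) x$assignments

#' @rdname tidy.mlst_cc
#' @method glance mlst_cc
#' @export
glance.mlst_cc <- function(x, ...) {
  tibble(
    n_complexes = nrow(x$complexes),
    n_singletons = length(x$singletons),
    largest_cc_isolates = if (nrow(x$complexes)) max(x$complexes$n_isolates) else NA_integer_,
    largest_cc_sts = if (nrow(x$complexes)) max(x$complexes$n_sts) else NA_integer_,
    group_threshold = x$group_threshold
  )
}

#' Write clonal-complex assignments as a tab-separated table
#'
#' Columns: `ST`, `complex` (empty for singletons), `founder_flag`.
#'
#' @param cc An `mlst_cc` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cc_table <- function(cc, path) {
  out <- cc$assignments |>
    mutate(
      complex = ifelse(is.na(.data$complex), "", .data$complex),
      founder_flag = as.integer(.data$is_founder)
    ) |>
    select(ST = "st", "complex", "founder_flag")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Minimum spanning tree over allelic profiles
#'
#' Computes a minimum spanning tree of the complete graph on sequence types
#' weighted by allelic distance, using a Kruskal scan that is fully
#' deterministic: candidate edges of equal weight are ordered by larger
#' summed SLV counts of their endpoints, then larger summed isolate counts,
#' then the lexicographically smaller ST-number pair. Edges are annotated
#' with a display class by distance (1 bold, 2 thin, 3 dotted, larger
#' suppressed) after the fashion of MLST spanning-tree figures.
#'
#' @param profiles An `mlst_profiles` object with at least one ST.
#' @param metadata Optional isolate metadata; when given, each node carries
#'   the most frequent `source` among its member isolates.
#' @return An object of class `mlst_mst`: list with `nodes`
#'   (`st`, `n_isolates`, `source`), `edges`
#'   (`from`, `to`, `distance`, `link_class`) and `total_weight`.
#' @export
build_mst <- function(profiles, metadata = NULL) {
  sts <- profiles$profiles$st
  nodes <- tibble(
    st = sts, n_isolates = profiles$profiles$n_isolates,
    source = NA_character_
  )
  if (!is.null(metadata)) {
    dom <- profiles$membership |>
      left_join(metadata, by = "isolate_id") |>
      group_by(.data$st, .data$source) |>
      summarise(n = dplyr::n(), .groups = "drop_last") |>
      arrange(dplyr::desc(.data$n), .data$source, .by_group = TRUE) |>
      dplyr::slice(1L) |>
      ungroup()
    nodes$source <- dom$source[match(nodes$st, dom$st)]
  }
  if (length(sts) < 2L) {
    rlang::warn("fewer than 2 STs: degenerate spanning tree with no edges")
    return(structure(
      list(
        nodes = nodes,
        edges = tibble(
          from = integer(), to = integer(),
          distance = integer(), link_class = character()
        ),
        total_weight = 0
      ),
      class = "mlst_mst"
    ))
  }
  d <- profile_distance_matrix(profiles)
  slv <- rowSums(d == 1L)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  ed <- tibble(
    i = pairs[, 1], j = pairs[, 2],
    weight = d[pairs],
    key_slv = -(slv[pairs[, 1]] + slv[pairs[, 2]]),
    key_size = -(nodes$n_isolates[pairs[, 1]] + nodes$n_isolates[pairs[, 2]]),
    st_lo = pmin(sts[pairs[, 1]], sts[pairs[, 2]]),
    st_hi = pmax(sts[pairs[, 1]], sts[pairs[, 2]])
  ) |>
    arrange(.data$weight, .data$key_slv, .data$key_size, .data$st_lo, .data$st_hi)

  parent <- uf_new(length(sts))
  keep <- logical(nrow(ed))
  n_used <- 0L
  for (k in seq_len(nrow(ed))) {
    ri <- uf_find(parent, ed$i[k])
    rj <- uf_find(parent, ed$j[k])
    if (ri != rj) {
      parent[max(ri, rj)] <- min(ri, rj)
      keep[k] <- TRUE
      n_used <- n_used + 1L
      if (n_used == length(sts) - 1L) break
    }
  }
  edges <- ed[keep, ] |>
    mutate(
      from = .data$st_lo, to = .data$st_hi, distance = as.integer(.data$weight),
      link_class = dplyr::case_when(
        .data$distance == 1L ~ "bold",
        .data$distance == 2L ~ "thin",
        .data$distance == 3L ~ "dotted",
        TRUE ~ "suppressed"
      )
    ) |>
    select("from", "to", "distance", "link_class") |>
    arrange(.data$from, .data$to)
  structure(
    list(nodes = nodes, edges = edges, total_weight = sum(edges$distance)),
    class = "mlst_mst"
  )
}

#' @export
print.mlst_mst <- function(x, ...) {
  cat(sprintf(
    "<mlst_mst> %d STs, %d edges, total allelic-distance weight %d\n",
    nrow(x$nodes), nrow(x$edges), x$total_weight
  ))
  invisible(x)
}

#' @rdname tidy.mlst_cc
#' @method tidy mlst_mst
#' @export
tidy.mlst_mst <- function(x, ...) x$edges

#' @rdname tidy.mlst_cc
#' @method glance mlst_mst
#' @export
glance.mlst_mst <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
    total_weight = x$total_weight,
    max_edge_distance = if (nrow(x$edges)) max(x$edges$distance) else NA_integer_
  )
}

# igraph representation used for export and plotting
mst_igraph <- function(mst) {
  g <- igraph::graph_from_data_frame(
    mutate(mst$edges, from = paste0("ST", .data$from), to = paste0("ST", .data$to)),
    directed = FALSE,
    vertices = tibble(
      name = paste0("ST", mst$nodes$st),
      n_isolates = mst$nodes$n_isolates,
      source = ifelse(is.na(mst$nodes$source), "", mst$nodes$source)
    )
  )
  g
}

#' Export a spanning tree as GraphML or DOT
#'
#' @param mst An `mlst_mst` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mst_graphml <- function(mst, path) {
  igraph::write_graph(mst_igraph(mst), path, format = "graphml")
  invisible(path)
}

#' @rdname write_mst_graphml
#' @export
write_mst_dot <- function(mst, path) {
  lines <- c(
    "graph mst {",
    sprintf(
      '  "ST%d" [n_isolates=%d, source="%s"];',
      mst$nodes$st, mst$nodes$n_isolates,
      ifelse(is.na(mst$nodes$source), "", mst$nodes$source)
    ),
    if (nrow(mst$edges)) {
      sprintf(
        '  "ST%d" -- "ST%d" [label=%d, style="%s"];',
        mst$edges$from, mst$edges$to, mst$edges$distance, mst$edges$link_class
      )
    },
    "}"
  )
  writeLines(lines, path)
  invisible(path)
}
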