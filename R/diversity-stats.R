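# Per-locus and concatenated diversity statistics: polymorphic sites,
# nucleotide diversity (pi), G+C content, synonymous/nonsynonymous site
# classification and Nei-Gojobori (1986) dN/dS with Jukes-Cantor correction.
# Sites containing 'N' are excluded pairwise, never listwise.

#' Count polymorphic sites
#'
#' A site is polymorphic iff at least two distinct non-N characters occur
#' there; variation visible only through N is not polymorphism.
#'
#' @param alignment Equal-length sequences: a character vector or a tibble
#'   with a `sequence` column.
#' @return A list with `n` (count) and `sites` (0-based site indices).
#' @examples
#' count_polymorphic_sites(c("AAAA", "AAAT"))
#' @export
count_polymorphic_sites <- function(alignment) {
  seqs <- as_seqs(alignment)
  if (length(seqs) < 2) {
    rlang::abort("polymorphism is undefined for a single sequence")
  }
  m <- aln_matrix(unique(seqs))
  poly <- apply(m, 2L, function(col) {
    length(unique(col[col != "N"])) >= 2L
  })
  list(n = sum(poly), sites = which(poly) - 1L)
}

#' Nucleotide diversity per site
#'
#' Mean over all unordered sequence pairs of the proportion of differing
#' sites among the pair's mutually non-N sites; no small-sample correction
#' factor is applied. Pairs with no comparable sites are excluded with a
#' warning.
#'
#' @inheritParams count_polymorphic_sites
#' @return Numeric `pi` in `[0, 1]`.
#' @examples
#' nucleotide_diversity(c("AAAA", "AAAT", "AAAT")) # 2/3 differing pairs / 4 sites
#' @export
nucleotide_diversity <- function(alignment) {
  seqs <- as_seqs(alignment)
  if (length(seqs) < 2) rlang::abort("pi is undefined for a single sequence")
  uw <- unique_weighted(seqs)
  pm <- pairwise_mismatch(setNames(uw$seq, NULL))
  w <- pair_weights(uw$w)
  use <- upper.tri(w, diag = TRUE) & w > 0
  mism <- pm$mismatch[use]
  comp <- pm$comparable[use]
  wt <- w[use]
  bad <- comp == 0
  if (any(bad)) {
    rlang::warn(sprintf("%d pair(s) with no comparable sites excluded", sum(wt[bad])))
    if (all(bad)) rlang::abort("no sequence pair has comparable sites")
  }
  sum(wt[!bad] * mism[!bad] / comp[!bad]) / sum(wt[!bad])
}

#' G+C content
#'
#' Percentage of G and C among all non-N bases, pooled over all sequences.
#'
#' @inheritParams count_polymorphic_sites
#' @return Percentage in `[0, 100]`.
#' @examples
#' gc_content("ATGC")
#' @export
gc_content <- function(alignment) {
  seqs <- as_seqs(alignment)
  chars <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
  gc <- sum(chars %in% c("G", "C"))
  acgt <- sum(chars %in% DNA_BASES)
  if (acgt == 0) rlang::abort("no determined bases (all N)")
  100 * gc / acgt
}

# ---- codon tables for NG86 and site classification (built lazily) ----

.ng86 <- new.env(parent = emptyenv())

all_codons <- function() {
  b <- DNA_BASES
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

ng86_tables <- function() {
  if (!is.null(.ng86$syn_sites)) {
    return(as.list(.ng86))
  }
  codons <- all_codons()
  aa <- translate_codon(codons)
  n_cod <- length(codons)
  # potential synonymous sites per codon: at each position the fraction of
  # sense (non-stop) single-base changes that are synonymous
  syn_sites <- numeric(n_cod)
  names(syn_sites) <- codons
  for (ci in seq_len(n_cod)) {
    if (aa[ci] == "*") {
      syn_sites[ci] <- NA_real_
      next
    }
    chars <- strsplit(codons[ci], "")[[1]]
    s <- 0
    for (pos in 1:3) {
      alts <- setdiff(DNA_BASES, chars[pos])
      alt_cod <- vapply(alts, function(b) {
        x <- chars
        x[pos] <- b
        paste(x, collapse = "")
      }, character(1))
      alt_aa <- translate_codon(alt_cod)
      sense <- alt_aa != "*"
      if (any(sense)) s <- s + sum(alt_aa[sense] == aa[ci]) / sum(sense)
    }
    syn_sites[ci] <- s
  }
  # pairwise observed synonymous/nonsynonymous differences with equal-weight
  # averaging over minimal mutational pathways, pathways through stop codons
  # excluded
  sd_mat <- matrix(0, n_cod, n_cod, dimnames = list(codons, codons))
  nd_mat <- sd_mat
  path_counts <- function(c1, c2) {
    pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    k <- length(pos)
    if (k == 0) {
      return(c(0, 0))
    }
    orders <- if (k == 1) list(pos) else {
      perms <- if (k == 2) list(pos, rev(pos)) else {
        idx <- list(
          c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
          c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)
        )
        lapply(idx, function(i) pos[i])
      }
      perms
    }
    acc <- matrix(NA_real_, length(orders), 2)
    for (oi in seq_along(orders)) {
      cur <- strsplit(c1, "")[[1]]
      tgt <- strsplit(c2, "")[[1]]
      sy <- 0
      ns <- 0
      ok <- TRUE
      for (p in orders[[oi]]) {
        nxt <- cur
        nxt[p] <- tgt[p]
        a1 <- translate_codon(paste(cur, collapse = ""))
        a2 <- translate_codon(paste(nxt, collapse = ""))
        if (a2 == "*" || a1 == "*") {
          ok <- FALSE
          break
        }
        if (a1 == a2) sy <- sy + 1 else ns <- ns + 1
        cur <- nxt
      }
      if (ok) acc[oi, ] <- c(sy, ns)
    }
    valid <- !is.na(acc[, 1])
    if (!any(valid)) {
      # all pathways pass a stop codon: count every step nonsynonymous
      return(c(0, k))
    }
    colMeans(acc[valid, , drop = FALSE])
  }
  sense <- which(aa != "*")
  for (i in sense) {
    for (j in sense) {
      if (j <= i) next
      pn <- path_counts(codons[i], codons[j])
      sd_mat[i, j] <- pn[1]
      sd_mat[j, i] <- pn[1]
      nd_mat[i, j] <- pn[2]
      nd_mat[j, i] <- pn[2]
    }
  }
  .ng86$codons <- codons
  .ng86$aa <- aa
  .ng86$syn_sites <- syn_sites
  .ng86$sd <- sd_mat
  .ng86$nd <- nd_mat
  as.list(.ng86)
}

# integer codon indices (1..64, NA for codons containing N) per sequence
codon_indices <- function(seq, frame_offset) {
  cods <- split_codons(seq, frame_offset)
  match(cods, all_codons())
}

#' Classify polymorphic sites as synonymous or nonsynonymous
#'
#' For each polymorphic site of a coding alignment, all observed complete
#' codons covering the site are compared: the site is synonymous (sSNP) if
#' some pair of observed codons differing only at that site encodes the
#' same amino acid, and nonsynonymous (nSNP) if some such pair encodes
#' different amino acids. A site may carry both labels. Sites falling in
#' incomplete terminal codons are skipped with a warning.
#'
#' @inheritParams count_polymorphic_sites
#' @param frame_offset 0-based offset of the first complete codon.
#' @return A list with `n_ssnp`, `n_nsnp` and `labels` — a tibble
#'   (`site` 0-based, `synonymous`, `nonsynonymous`).
#' @examples
#' classify_snp_sites(c("TTTAAA", "TTCAAA")) # Phe/Phe: synonymous
#' @export
classify_snp_sites <- function(alignment, frame_offset = 0L) {
  seqs <- unique(as_seqs(alignment))
  if (length(seqs) == 1) {
    # monomorphic alignment: nothing to classify
    return(list(
      n_ssnp = 0L, n_nsnp = 0L,
      labels = tibble(
        site = integer(), synonymous = logical(), nonsynonymous = logical()
      )
    ))
  }
  poly <- count_polymorphic_sites(seqs)
  m <- aln_matrix(seqs)
  L <- ncol(m)
  n_codon <- (L - frame_offset) %/% 3L
  # majority-frame sanity check: the most frequent complete codon at any
  # position must not be a stop
  cod_idx_all <- lapply(seqs, codon_indices, frame_offset = frame_offset)
  cod_mat <- do.call(rbind, cod_idx_all)
  if (n_codon > 0) {
    maj <- apply(cod_mat, 2L, function(col) {
      col <- col[!is.na(col)]
      if (length(col) == 0) {
        return(NA_integer_)
      }
      as.integer(names(sort(table(col), decreasing = TRUE))[1])
    })
    tabs <- ng86_tables()
    if (any(!is.na(maj) & tabs$aa[maj] == "*")) {
      rlang::abort("internal stop codon in the majority reading frame",
        class = "mlstkit_frame_error"
      )
    }
  }
  labels <- tibble(
    site = poly$sites, synonymous = FALSE, nonsynonymous = FALSE,
    skipped = FALSE
  )
  for (r in seq_len(nrow(labels))) {
    s <- labels$site[r] # 0-based
    p <- s - frame_offset
    cod_i <- p %/% 3L # 0-based codon index
    if (p < 0L || cod_i >= n_codon) {
      labels$skipped[r] <- TRUE
      next
    }
    start <- frame_offset + 3L * cod_i + 1L
    obs <- unique(apply(m[, start:(start + 2L), drop = FALSE], 1L, paste, collapse = ""))
    obs <- obs[!grepl("N", obs, fixed = TRUE)]
    if (length(obs) < 2) next
    within <- (p %% 3L) + 1L
    for (a in seq_along(obs)) {
      for (b in seq_along(obs)) {
        if (b <= a) next
        diff_pos <- which(strsplit(obs[a], "")[[1]] != strsplit(obs[b], "")[[1]])
        if (length(diff_pos) == 1 && diff_pos == within) {
          if (translate_codon(obs[a]) == translate_codon(obs[b])) {
            labels$synonymous[r] <- TRUE
          } else {
            labels$nonsynonymous[r] <- TRUE
          }
        }
      }
    }
  }
  if (any(labels$skipped)) {
    rlang::warn(sprintf(
      "%d polymorphic site(s) in incomplete terminal codons skipped",
      sum(labels$skipped)
    ))
  }
  list(
    n_ssnp = sum(labels$synonymous),
    n_nsnp = sum(labels$nonsynonymous),
    labels = select(labels, "site", "synonymous", "nonsynonymous")
  )
}

#' Nei-Gojobori dN/dS
#'
#' Implements the Nei and Gojobori (1986) method: potential synonymous (S)
#' and nonsynonymous (N) sites per sequence from codon mutational
#' opportunity; pairwise observed synonymous/nonsynonymous differences with
#' equal-weight averaging over minimal mutational pathways for codons
#' differing at 2-3 positions (pathways through stop codons excluded);
#' proportions converted to distances by the Jukes-Cantor correction
#' `d = -(3/4) log(1 - 4p/3)` (or left uncorrected with
#' `correction = "none"`). `dN` and `dS` are means over all sequence pairs.
#'
#' @inheritParams classify_snp_sites
#' @param correction `"jukes_cantor"` (default) or `"none"`.
#' @return A list with `dn`, `ds`, `dnds` and `status`: `"ok"`,
#'   `"degenerate"` (no substitutions at all) or `"undefined"`
#'   (`dS = 0 < dN`; `dnds` is `NA`, never a number). Convention:
#'   `dN = 0` gives `dnds = 0`.
#' @examples
#' nei_gojobori(c("TTT", "TTC"))$dnds # synonymous only -> 0
#' @export
nei_gojobori <- function(alignment, frame_offset = 0L,
                         correction = c("jukes_cantor", "none")) {
  correction <- match.arg(correction)
  seqs <- as_seqs(alignment)
  if (length(seqs) < 2) rlang::abort("dN/dS needs at least 2 sequences")
  tabs <- ng86_tables()
  uw <- unique_weighted(seqs)
  ncods <- lapply(uw$seq, codon_indices, frame_offset = frame_offset)
  if (any(vapply(ncods, function(ix) any(tabs$aa[ix[!is.na(ix)]] == "*"), logical(1)))) {
    rlang::abort("stop codon encountered in coding sequence",
      class = "mlstkit_frame_error"
    )
  }
  k <- length(uw$seq)
  w <- pair_weights(uw$w)
  jc <- function(p) {
    if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
  }
  # saturated proportions (p >= 3/4, correction undefined) drop the pair
  # from that statistic's mean only, so e.g. dN stays estimable when a
  # short fragment saturates p_S
  dn_sum <- 0
  ds_sum <- 0
  wn_sum <- 0
  ws_sum <- 0
  dropped <- 0
  for (i in seq_len(k)) {
    for (j in i:k) {
      if (w[i, j] == 0) next
      if (i == j) {
        # identical sequences: zero distance
        wn_sum <- wn_sum + w[i, j]
        ws_sum <- ws_sum + w[i, j]
        next
      }
      ok <- !is.na(ncods[[i]]) & !is.na(ncods[[j]])
      ci <- ncods[[i]][ok]
      cj <- ncods[[j]][ok]
      sd <- sum(tabs$sd[cbind(ci, cj)])
      nd <- sum(tabs$nd[cbind(ci, cj)])
      s_bar <- (sum(tabs$syn_sites[ci]) + sum(tabs$syn_sites[cj])) / 2
      n_bar <- 3 * length(ci) - s_bar
      ps <- if (s_bar > 0) sd / s_bar else 0
      pn <- if (n_bar > 0) nd / n_bar else 0
      if (correction == "jukes_cantor") {
        ds_p <- jc(ps)
        dn_p <- jc(pn)
        if (is.na(ds_p) || is.na(dn_p)) dropped <- dropped + w[i, j]
      } else {
        ds_p <- ps
        dn_p <- pn
      }
      if (!is.na(dn_p)) {
        dn_sum <- dn_sum + w[i, j] * dn_p
        wn_sum <- wn_sum + w[i, j]
      }
      if (!is.na(ds_p)) {
        ds_sum <- ds_sum + w[i, j] * ds_p
        ws_sum <- ws_sum + w[i, j]
      }
    }
  }
  if (dropped > 0) {
    rlang::warn(sprintf(
      "%d pair(s) with substitution proportion >= 3/4: correction undefined, excluded from the affected mean",
      dropped
    ))
  }
  if (wn_sum == 0) rlang::abort("no usable sequence pairs for dN/dS")
  dn <- dn_sum / wn_sum
  ds <- if (ws_sum > 0) ds_sum / ws_sum else 0
  if (k == 1) {
    # all sequences identical
    list(dn = 0, ds = 0, dnds = 0, status = "degenerate")
  } else if (dn == 0) {
    list(dn = 0, ds = ds, dnds = 0, status = "ok")
  } else if (ds == 0) {
    list(dn = dn, ds = 0, dnds = NA_real_, status = "undefined")
  } else {
    list(dn = dn, ds = ds, dnds = dn / ds, status = "ok")
  }
}

#' Per-locus diversity report
#'
#' One row per locus plus a `concatenated` row, in the shape of the classic
#' MLST descriptive table: fragment length, allele count, polymorphic
#' sites, sSNP and nSNP counts, nucleotide diversity, G+C% and dN/dS.
#' Statistics are computed over all isolate sequences by default (not
#' deduplicated alleles); `unit = "sts"` restricts to one representative
#' isolate per sequence type.
#'
#' @param dataset An `mlst_dataset`.
#' @param profiles An `mlst_profiles` for the same dataset (for allele
#'   counts; computed on the fly if `NULL`).
#' @param unit `"isolates"` (default) or `"sts"`.
#' @param dnds_correction Passed to [nei_gojobori()].
#' @return A tibble of class `mlst_diversity` with columns `locus`,
#'   `length_bp`, `n_alleles`, `n_polymorphic_sites`, `n_ssnp`, `n_nsnp`,
#'   `pi`, `gc_percent`, `dnds`, `dnds_status`.
#' @export
diversity_report <- function(dataset, profiles = NULL,
                             unit = c("isolates", "sts"),
                             dnds_correction = c("jukes_cantor", "none")) {
  unit <- match.arg(unit)
  dnds_correction <- match.arg(dnds_correction)
  if (is.null(profiles)) profiles <- assign_profiles(dataset)
  keep_ids <- if (unit == "sts") {
    profiles$membership |>
      group_by(.data$st) |>
      summarise(isolate_id = min(.data$isolate_id), .groups = "drop") |>
      pull(.data$isolate_id)
  } else {
    unique(dataset$sequences$isolate_id)
  }
  rows <- vector("list", nrow(dataset$loci) + 1L)
  for (i in seq_len(nrow(dataset$loci))) {
    def <- dataset$loci[i, ]
    seqs <- locus_seqs(dataset, def$locus)
    seqs <- seqs[names(seqs) %in% keep_ids]
    snp <- if (def$coding) {
      classify_snp_sites(seqs, def$frame_offset)
    } else {
      list(n_ssnp = NA_integer_, n_nsnp = NA_integer_)
    }
    ng <- if (def$coding) {
      nei_gojobori(seqs, def$frame_offset, correction = dnds_correction)
    } else {
      list(dnds = NA_real_, status = "noncoding")
    }
    rows[[i]] <- tibble(
      locus = def$locus,
      length_bp = def$fragment_length,
      n_alleles = sum(profiles$catalogs$locus == def$locus),
      n_polymorphic_sites = count_polymorphic_sites(seqs)$n,
      n_ssnp = snp$n_ssnp, n_nsnp = snp$n_nsnp,
      pi = nucleotide_diversity(seqs),
      gc_percent = gc_content(seqs),
      dnds = ng$dnds, dnds_status = ng$status
    )
  }
  concat <- concatenate_loci(dataset)
  concat <- concat[concat$id %in% keep_ids, ]
  per <- bind_rows(rows[seq_len(nrow(dataset$loci))])
  rows[[length(rows)]] <- tibble(
    locus = "concatenated",
    length_bp = sum(dataset$loci$fragment_length),
    n_alleles = length(unique(concat$sequence)),
    n_polymorphic_sites = count_polymorphic_sites(concat)$n,
    n_ssnp = sum(per$n_ssnp), n_nsnp = sum(per$n_nsnp),
    pi = nucleotide_diversity(concat),
    gc_percent = gc_content(concat),
    dnds = NA_real_, dnds_status = "see_per_locus"
  )
  out <- bind_rows(rows)
  class(out) <- c("mlst_diversity", class(out))
  out
}

#' Write a diversity report as tab-separated text
#'
#' Columns in fixed order: locus, length, alleles, polymorphic sites,
#' sSNP, nSNP, pi, gc_percent, dnds.
#'
#' @param report Output of [diversity_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_diversity_report <- function(report, path) {
  out <- report[c(
    "locus", "length_bp", "n_alleles", "n_polymorphic_sites",
    "n_ssnp", "n_nsnp", "pi", "gc_percent", "dnds"
  )]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
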