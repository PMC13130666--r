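## ---------------------------------------------------------------------------
## NK/T separation and T-subset assignment: stringent marker rules + kNN
## rescue of unresolved cells.
## ---------------------------------------------------------------------------

T_SUBSET_MARKERS <- c("CD8A", "CD8B", "CD4", "FOXP3", "IL2RA")

#' Parameters for T/NK separation and T-subset assignment
#'
#' @param knn_k neighbors consulted when rescuing unresolved cells.
#' @param knn_majority minimum neighbors sharing a label for reassignment.
#' @param de_top_genes genes taken from each side of the per-patient
#'   TCR+/TCR- comparison.
#' @param de_min_comparisons comparisons a gene must recur in to enter the
#'   NK or T signature.
#' @param min_5prime_cells 5'-sequenced cells a patient needs to contribute
#'   a comparison.
#' @param n_pcs principal components for the kNN embedding.
#' @return object of class `t_subset_params`.
#' @export
t_subset_params <- function(knn_k = 10L, knn_majority = 8L,
                            de_top_genes = 50L, de_min_comparisons = 5L,
                            min_5prime_cells = 10L, n_pcs = 20L) {
  stop_if_not(knn_majority <= knn_k, "knn_majority must be <= knn_k")
  structure(list(knn_k = as.integer(knn_k), knn_majority = as.integer(knn_majority),
                 de_top_genes = as.integer(de_top_genes),
                 de_min_comparisons = as.integer(de_min_comparisons),
                 min_5prime_cells = as.integer(min_5prime_cells),
                 n_pcs = as.integer(n_pcs)),
            class = "t_subset_params")
}

#' Separate T from NK cells using TCR-derived signatures
#'
#' For every patient with at least `min_5prime_cells` 5'-sequenced candidate
#' cells (where TCR evidence is reliable), genes are compared between TCR+
#' and TCR- cells; the top `de_top_genes` over-expressed genes on each side
#' are collected, and genes recurring in at least `de_min_comparisons`
#' patient comparisons form the T and NK signatures. All candidate cells
#' are then scored for both signatures and assigned to the higher one. When
#' no patient is eligible the TCR flag alone decides (logged).
#'
#' @param norm a centered `normalized_matrix` restricted to the T/NK
#'   candidate cells (its `cell_meta` must carry `patient`, `platform`,
#'   `tcr`).
#' @param params a [t_subset_params()].
#' @param score_params a [signature_score_params()].
#' @return data.frame per cell: `cell_id`, `class` ("T"/"NK"), `t_score`,
#'   `nk_score`; the signatures are in `attr(, "signatures")`.
#' @export
split_t_nk <- function(norm, params = t_subset_params(),
                       score_params = signature_score_params()) {
  cm <- norm$cell_meta
  stop_if_not(!is.null(cm$tcr), "per-cell TCR flags required")
  t_genes <- character(); nk_genes <- character()
  n_comparisons <- 0L
  for (pat in unique(cm$patient)) {
    i5 <- which(cm$patient == pat & cm$platform == "5prime")
    if (length(i5) < params$min_5prime_cells) next
    pos <- i5[cm$tcr[i5]]; neg <- i5[!cm$tcr[i5]]
    if (length(pos) < 2 || length(neg) < 2) next
    de <- row_t_test(norm$values[, pos, drop = FALSE],
                     norm$values[, neg, drop = FALSE])
    ord <- order(de$t, decreasing = TRUE)
    genes <- rownames(norm$values)
    t_genes <- c(t_genes, genes[utils::head(ord, params$de_top_genes)])
    nk_genes <- c(nk_genes, genes[utils::tail(ord, params$de_top_genes)])
    n_comparisons <- n_comparisons + 1L
  }
  t_sig <- names(which(table(t_genes) >= params$de_min_comparisons))
  nk_sig <- names(which(table(nk_genes) >= params$de_min_comparisons))
  if (n_comparisons == 0 || length(t_sig) == 0 || length(nk_sig) == 0) {
    message("no eligible patients/recurrent genes; falling back to the TCR flag")
    out <- data.frame(cell_id = cm$cell_id,
                      class = ifelse(cm$tcr, "T", "NK"),
                      t_score = NA_real_, nk_score = NA_real_,
                      stringsAsFactors = FALSE)
    attr(out, "signatures") <- NULL
    return(out)
  }
  ts <- score_signature(norm, t_sig, params = score_params)
  ns <- score_signature(norm, nk_sig, params = score_params)
  out <- data.frame(cell_id = cm$cell_id,
                    class = ifelse(ts >= ns, "T", "NK"),
                    t_score = ts, nk_score = ns, stringsAsFactors = FALSE)
  attr(out, "signatures") <- list(T = t_sig, NK = nk_sig,
                                  n_comparisons = n_comparisons)
  out
}

#' Stringent T-subset assignment from marker UMI counts
#'
#' CD8: at least one CD8A or CD8B UMI and zero CD4/FOXP3/IL2RA. T helper:
#' at least one CD4 UMI and zero CD8A/CD8B/FOXP3/IL2RA. Treg: at least one
#' FOXP3 UMI and one IL2RA UMI and zero CD8A/CD8B (CD4 is permitted). Any
#' other pattern is unresolved. The three rules are mutually exclusive by
#' construction.
#'
#' @param counts UMI matrix (genes x cells) containing rows CD8A, CD8B,
#'   CD4, FOXP3, IL2RA (error when any is absent).
#' @return character vector per cell: "CD8", "Th", "Treg" or "unresolved".
#' @export
stringent_t_rules <- function(counts) {
  missing <- setdiff(T_SUBSET_MARKERS, rownames(counts))
  stop_if_not(length(missing) == 0, "marker gene(s) absent from matrix: %s",
              paste(missing, collapse = ", "))
  m <- as.matrix(counts[T_SUBSET_MARKERS, , drop = FALSE])
  cd8a <- m["CD8A", ]; cd8b <- m["CD8B", ]; cd4 <- m["CD4", ]
  foxp3 <- m["FOXP3", ]; il2ra <- m["IL2RA", ]
  lab <- rep("unresolved", ncol(m))
  lab[(cd8a >= 1 | cd8b >= 1) & cd4 == 0 & foxp3 == 0 & il2ra == 0] <- "CD8"
  lab[cd4 >= 1 & cd8a == 0 & cd8b == 0 & foxp3 == 0 & il2ra == 0] <- "Th"
  lab[foxp3 >= 1 & il2ra >= 1 & cd8a == 0 & cd8b == 0] <- "Treg"
  lab
}

#' Rescue unresolved T cells by k-nearest-neighbor vote
#'
#' Unresolved cells carrying markers of conflicting subsets (any CD8A/CD8B
#' UMI together with any CD4, FOXP3 or IL2RA UMI) are removed from rescue.
#' Each remaining unresolved cell adopts the label held by at least
#' `knn_majority` of its `knn_k` nearest stringently labeled neighbors in
#' PCA space; otherwise it stays unresolved. Stringently assigned labels
#' are never changed.
#'
#' @param values genes x cells centered expression matrix of all T cells.
#' @param stringent per-cell labels from [stringent_t_rules()].
#' @param counts optional UMI matrix for the marker-conflict removal.
#' @param params a [t_subset_params()].
#' @return data.frame per cell: `stringent`, `final`, `n_majority`,
#'   `conflict`.
#' @export
knn_rescue <- function(values, stringent, counts = NULL,
                       params = t_subset_params()) {
  labeled <- which(stringent != "unresolved")
  stop_if_not(length(labeled) >= params$knn_k,
              "need at least knn_k stringently labeled cells")
  conflict <- rep(FALSE, ncol(values))
  if (!is.null(counts)) {
    m <- as.matrix(counts[T_SUBSET_MARKERS, , drop = FALSE])
    conflict <- (m["CD8A", ] + m["CD8B", ] >= 1) &
      (m["CD4", ] >= 1 | m["FOXP3", ] >= 1 | m["IL2RA", ] >= 1)
    conflict <- conflict & stringent == "unresolved"
  }
  emb <- pca_embed(values, params$n_pcs)
  final <- stringent
  n_major <- rep(NA_integer_, ncol(values))
  todo <- which(stringent == "unresolved" & !conflict)
  if (length(todo)) {
    d <- as.matrix(stats::dist(emb))[todo, labeled, drop = FALSE]
    for (i in seq_along(todo)) {
      nn <- labeled[order(d[i, ])[seq_len(params$knn_k)]]
      tab <- table(stringent[nn])
      n_major[todo[i]] <- max(tab)
      if (max(tab) >= params$knn_majority)
        final[todo[i]] <- names(which.max(tab))
    }
  }
  data.frame(stringent = stringent, final = final, n_majority = n_major,
             conflict = conflict, stringsAsFactors = FALSE)
}
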