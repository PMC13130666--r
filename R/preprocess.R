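## ---------------------------------------------------------------------------
## QC, normalization, platform batch correction, cluster-based cell typing and
## differential expression: the shared substrate of all downstream stages.
## ---------------------------------------------------------------------------

#' Annotated UMI count matrix
#'
#' The hub object of the single-cell pipeline: a genes x cells UMI matrix
#' together with per-cell and per-gene annotations. Detected-gene counts and
#' mitochondrial fractions are computed from the matrix on construction.
#'
#' @param counts genes x cells matrix of nonnegative integer UMI counts
#'   (dense or `Matrix` sparse); rownames are gene symbols, colnames cell ids.
#' @param cell_meta data.frame with one row per cell; expected columns
#'   include `cell_id`, `patient`, `timepoint` ("pre"/"post"), `platform`
#'   ("3prime"/"5prime") and logical `tcr`.
#' @param gene_meta data.frame with one row per gene: `symbol`,
#'   `chromosome`, `arm`, `order` (within-chromosome position, strictly
#'   increasing) and logical `mito`.
#' @return object of class `annotated_counts` with elements `counts`,
#'   `cell_meta` (augmented with `n_genes_detected`, `mito_fraction`) and
#'   `gene_meta`.
#' @export
annotated_counts <- function(counts, cell_meta, gene_meta) {
  stop_if_not(nrow(counts) == nrow(gene_meta),
              "counts rows (%d) != gene_meta rows (%d)", nrow(counts), nrow(gene_meta))
  stop_if_not(ncol(counts) == nrow(cell_meta),
              "counts cols (%d) != cell_meta rows (%d)", ncol(counts), nrow(cell_meta))
  stop_if_not(min(counts) >= 0, "counts must be nonnegative")
  for (chr in unique(gene_meta$chromosome)) {
    o <- gene_meta$order[gene_meta$chromosome == chr]
    stop_if_not(all(diff(o) > 0),
                "gene order must be strictly increasing within %s", chr)
  }
  cm <- cell_meta
  cm$n_genes_detected <- Matrix::colSums(counts > 0)
  tot <- Matrix::colSums(counts)
  mito <- which(gene_meta$mito %||% rep(FALSE, nrow(gene_meta)))
  cm$mito_fraction <- if (length(mito))
    Matrix::colSums(counts[mito, , drop = FALSE]) / pmax(tot, 1) else 0
  structure(list(counts = counts, cell_meta = cm, gene_meta = gene_meta),
            class = "annotated_counts")
}

#' @export
print.annotated_counts <- function(x, ...) {
  cat(sprintf("annotated_counts: %d genes x %d cells (%d patients)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cell_meta$patient))))
  invisible(x)
}

#' @export
dim.annotated_counts <- function(x) dim(x$counts)

## subset an annotated_counts by cell index/logical, and optionally genes
subset_cells <- function(ac, cells, genes = NULL) {
  genes <- genes %||% seq_len(nrow(ac$counts))
  structure(list(counts = ac$counts[genes, cells, drop = FALSE],
                 cell_meta = ac$cell_meta[cells, , drop = FALSE],
                 gene_meta = ac$gene_meta[genes, , drop = FALSE]),
            class = "annotated_counts")
}

#' Quality-control thresholds
#'
#' Defaults follow the standard thresholds for droplet data from mixed solid
#' tumors: non-lymphoid cells need at least 1,000 detected genes, lymphoid
#' cells (whose transcriptomes are less complex) at least 500, and any cell
#' with more than 20% mitochondrial UMIs is removed. Genes are retained when
#' their dataset-wide mean expression is at least 4 log2(CPM) or they reach
#' 5 UMIs in at least 20 cells.
#'
#' @param min_genes_nonlymphoid,min_genes_lymphoid detected-gene minima.
#' @param max_mito maximum mitochondrial UMI fraction.
#' @param gene_keep_mean_log2cpm mean-expression gene criterion (log2 CPM).
#' @param gene_keep_min_umi,gene_keep_min_cells UMI-prevalence gene criterion.
#' @return object of class `qc_params`.
#' @export
qc_params <- function(min_genes_nonlymphoid = 1000L, min_genes_lymphoid = 500L,
                      max_mito = 0.20, gene_keep_mean_log2cpm = 4,
                      gene_keep_min_umi = 5L, gene_keep_min_cells = 20L) {
  p <- list(min_genes_nonlymphoid = min_genes_nonlymphoid,
            min_genes_lymphoid = min_genes_lymphoid,
            max_mito = max_mito,
            gene_keep_mean_log2cpm = gene_keep_mean_log2cpm,
            gene_keep_min_umi = gene_keep_min_umi,
            gene_keep_min_cells = gene_keep_min_cells)
  stop_if_not(all(unlist(p) > 0), "QC thresholds must be positive")
  structure(p, class = "qc_params")
}

#' Filter cells on detected genes and mitochondrial load
#'
#' Lymphoid cells are kept with at least `min_genes_lymphoid` detected genes,
#' non-lymphoid cells with at least `min_genes_nonlymphoid`; in addition every
#' retained cell must have a mitochondrial UMI fraction of at most
#' `max_mito`. Removal reasons are recorded per cell in the returned
#' attribute `qc_log`.
#'
#' @param data an [annotated_counts()] object.
#' @param initial_lineage per-cell character vector, `"lymphoid"` or
#'   `"non_lymphoid"` (see [initial_lineage()]).
#' @param params a [qc_params()].
#' @return filtered `annotated_counts`; `attr(, "qc_log")` is a data.frame of
#'   all input cells with their removal reason (`NA` when kept).
#' @export
qc_filter_cells <- function(data, initial_lineage, params = qc_params()) {
  stop_if_not(length(initial_lineage) == ncol(data$counts),
              "initial_lineage must label every cell")
  miss <- is.na(initial_lineage)
  if (any(miss))
    stop_if_not(FALSE, "missing lineage label for cell(s): %s",
                paste(utils::head(data$cell_meta$cell_id[miss], 5), collapse = ", "))
  lymph <- initial_lineage == "lymphoid"
  ng <- data$cell_meta$n_genes_detected
  min_genes <- ifelse(lymph, params$min_genes_lymphoid, params$min_genes_nonlymphoid)
  reason <- rep(NA_character_, ncol(data$counts))
  reason[ng < min_genes] <- "low_gene_count"
  high_mito <- data$cell_meta$mito_fraction > params$max_mito
  reason[high_mito & is.na(reason)] <- "high_mito"
  reason[high_mito & reason == "low_gene_count"] <- "low_gene_count;high_mito"
  keep <- is.na(reason)
  out <- subset_cells(data, keep)
  attr(out, "qc_log") <- data.frame(cell_id = data$cell_meta$cell_id,
                                    lineage = initial_lineage,
                                    n_genes_detected = ng,
                                    mito_fraction = data$cell_meta$mito_fraction,
                                    removed_reason = reason,
                                    stringsAsFactors = FALSE)
  out
}

#' Filter genes on expression level or prevalence
#'
#' A gene is retained if its mean expression across the dataset is at least
#' `gene_keep_mean_log2cpm` log2(CPM), or it has at least `gene_keep_min_umi`
#' UMIs in at least `gene_keep_min_cells` cells. Gene order is preserved.
#'
#' @inheritParams qc_filter_cells
#' @return filtered `annotated_counts`.
#' @export
filter_genes <- function(data, params = qc_params()) {
  stop_if_not(ncol(data$counts) > 0 && nrow(data$counts) > 0,
              "empty count matrix")
  tot <- Matrix::colSums(data$counts)
  cpm_mean <- Matrix::rowMeans(log2(Matrix::t(Matrix::t(data$counts) / tot) * 1e6 + 1))
  prevalent <- Matrix::rowSums(data$counts >= params$gene_keep_min_umi) >=
    params$gene_keep_min_cells
  keep <- cpm_mean >= params$gene_keep_mean_log2cpm | prevalent
  subset_cells(data, seq_len(ncol(data$counts)), genes = which(keep))
}

## log2(CPM/10 + 1) on a plain numeric matrix
log2cpm <- function(counts) {
  tot <- colSums(counts)
  log2(sweep(counts, 2, tot, "/") * 1e5 + 1)
}

#' Normalize UMI counts to log2(CPM/10 + 1), optionally centered
#'
#' `value[g,c] = log2(1e6 * count[g,c] / total_umi[c] / 10 + 1)`; with
#' `center = TRUE` each gene's mean across cells is subtracted afterwards.
#'
#' @param data an [annotated_counts()] object.
#' @param center subtract per-gene means after the transform?
#' @return object of class `normalized_matrix`: list with dense `values`
#'   (genes x cells), logical `centered`, and the originating `gene_meta`
#'   and `cell_meta`.
#' @export
normalize_log2cpm <- function(data, center = TRUE) {
  tot <- Matrix::colSums(data$counts)
  if (any(tot == 0))
    stop_if_not(FALSE, "cells with zero total UMIs: %s",
                paste(utils::head(data$cell_meta$cell_id[tot == 0], 5), collapse = ", "))
  v <- as.matrix(Matrix::t(Matrix::t(data$counts) / tot) * 1e5)
  v <- log2(v + 1)
  if (center) v <- v - rowMeans(v)
  structure(list(values = v, centered = center,
                 gene_meta = data$gene_meta, cell_meta = data$cell_meta),
            class = "normalized_matrix")
}

#' Construct a normalized expression matrix object
#'
#' Mostly used internally by [normalize_log2cpm()]; exposed so that slices
#' or externally normalized matrices can enter the pipeline.
#'
#' @param values genes x cells numeric matrix with rownames.
#' @param gene_meta,cell_meta annotation data.frames (one row per
#'   gene/cell).
#' @param centered are the values per-gene centered?
#' @return object of class `normalized_matrix`.
#' @export
normalized_matrix <- function(values, gene_meta = NULL, cell_meta = NULL,
                              centered = FALSE) {
  gene_meta <- gene_meta %||% data.frame(symbol = rownames(values))
  cell_meta <- cell_meta %||% data.frame(cell_id = colnames(values) %||%
                                           paste0("c", seq_len(ncol(values))))
  stop_if_not(nrow(gene_meta) == nrow(values) && nrow(cell_meta) == ncol(values),
              "annotation dimensions must match the matrix")
  structure(list(values = values, centered = centered,
                 gene_meta = gene_meta, cell_meta = cell_meta),
            class = "normalized_matrix")
}

#' Center 3'-sequenced cells onto 5'-sequenced cells per patient and cluster
#'
#' For every (cluster, patient) stratum containing both platforms, each
#' gene's 3' values are shifted so their stratum mean equals the mean of the
#' stratum's 5' cells. 5' cells, and 3' cells without a cross-platform
#' partner in their stratum, are left untouched.
#'
#' @param norm a `normalized_matrix`.
#' @param cluster_labels per-cell cluster (or cell-type) labels defining the
#'   strata, together with `norm$cell_meta$patient` and `$platform`.
#' @return corrected `normalized_matrix`.
#' @export
batch_correct_platform <- function(norm, cluster_labels) {
  cm <- norm$cell_meta
  stop_if_not(length(cluster_labels) == ncol(norm$values),
              "cluster_labels must label every cell")
  v <- norm$values
  strata <- split(seq_len(ncol(v)), paste(cm$patient, cluster_labels, sep = "\r"))
  for (idx in strata) {
    p3 <- idx[cm$platform[idx] == "3prime"]
    p5 <- idx[cm$platform[idx] == "5prime"]
    if (length(p3) == 0 || length(p5) == 0) next
    shift <- rowMeans(v[, p5, drop = FALSE]) - rowMeans(v[, p3, drop = FALSE])
    v[, p3] <- v[, p3, drop = FALSE] + shift
  }
  norm$values <- v
  norm
}

#' Initial lineage call from canonical markers
#'
#' Scores every cell for each marker set on uncentered log2(CPM/10+1) values
#' (mean marker expression) and assigns the top-scoring type; types in
#' `lymphoid_types` map to the `"lymphoid"` lineage used by the QC filter.
#'
#' @param data an [annotated_counts()] object.
#' @param marker_sets named list of marker gene sets.
#' @param lymphoid_types names of lymphoid sets.
#' @return list with `type` (per-cell best marker set) and `lineage`
#'   ("lymphoid"/"non_lymphoid").
#' @export
initial_lineage <- function(data, marker_sets = default_marker_spec(),
                            lymphoid_types = LYMPHOID_TYPES) {
  norm <- normalize_log2cpm(data, center = FALSE)
  sc <- sapply(marker_sets, function(g) {
    g <- intersect(g, rownames(norm$values))
    if (!length(g)) return(rep(-Inf, ncol(norm$values)))
    colMeans(norm$values[g, , drop = FALSE])
  })
  type <- colnames(sc)[max.col(sc, ties.method = "first")]
  list(type = type,
       lineage = ifelse(type %in% lymphoid_types, "lymphoid", "non_lymphoid"))
}

#' Graph-based clustering of cells
#'
#' PCA embedding of the (gene-centered) expression matrix followed by Louvain
#' community detection on a k-nearest-neighbor graph. The clustering backend
#' is deliberately generic; `k` follows the dataset's scale and is truncated
#' to `n - 1` when fewer cells are available.
#'
#' @param values genes x cells numeric matrix.
#' @param k number of nearest neighbors for the graph.
#' @param n_pcs number of principal components.
#' @param seed RNG seed for the community detection.
#' @return integer vector of cluster labels.
#' @export
cluster_cells <- function(values, k = 200L, n_pcs = 30L, seed = 1L) {
  n <- ncol(values)
  k <- min(k, n - 1L)
  emb <- pca_embed(values, n_pcs)
  g <- knn_graph(emb, k)
  with_seed(seed, igraph::membership(igraph::cluster_louvain(g)))
}

pca_embed <- function(values, n_pcs) {
  x <- t(values - rowMeans(values))
  n_pcs <- min(n_pcs, dim(x) - 1L)
  pr <- stats::prcomp(x, rank. = n_pcs, center = FALSE)
  pr$x
}

knn_graph <- function(emb, k) {
  n <- nrow(emb)
  d <- as.matrix(stats::dist(emb))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
  edges <- cbind(rep(seq_len(n), each = k), as.vector(t(nn)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::simplify(g)
}

#' Assign cell types from clusters, markers and signature scores
#'
#' Clusters are labeled by matching their top differentially expressed genes
#' (vs all other cells) against the marker sets; each cell is additionally
#' scored for every marker set with the bin-matched signature score. A cell
#' is flagged unresolved when (a) it is TCR-positive but sits in a non-T/NK
#' cluster, (b) its top-scoring type is discordant with its cluster's type,
#' or (c) its top score is below `1.15 x` the second score and the
#' second-scoring type is discordant. Cells scoring as fibroblasts inside
#' epithelial clusters are retained (possible EMT).
#'
#' @param norm a centered `normalized_matrix`.
#' @param marker_sets named list of marker gene sets.
#' @param type_class named character vector mapping each type to
#'   "epithelial", "stromal" or "immune"; defaults cover the simulator's
#'   types.
#' @param cluster_k,n_pcs clustering parameters (see [cluster_cells()]).
#' @param de_top_genes number of top cluster-vs-rest genes matched against
#'   marker sets.
#' @param score_params a [signature_score_params()].
#' @param seed RNG seed.
#' @return data.frame per cell: `cluster`, `cluster_type`, `top_type`,
#'   `second_type`, their scores, `type` (final; NA when unresolved),
#'   `unresolved`, `unresolved_reason`.
#' @export
assign_cell_types <- function(norm, marker_sets = default_marker_spec(),
                              type_class = default_type_class(),
                              cluster_k = 200L, n_pcs = 30L,
                              de_top_genes = 50L,
                              score_params = signature_score_params(),
                              seed = 1L) {
  stop_if_not(length(marker_sets) > 0 && all(lengths(marker_sets) > 0),
              "empty marker set")
  v <- norm$values
  cl <- cluster_cells(v, k = cluster_k, n_pcs = n_pcs, seed = seed)

  ## label clusters by overlap of their top DE genes with the marker sets
  cluster_type <- vapply(sort(unique(cl)), function(ci) {
    de <- row_t_test(v[, cl == ci, drop = FALSE], v[, cl != ci, drop = FALSE])
    top <- rownames(v)[order(de$t, decreasing = TRUE)[seq_len(min(de_top_genes, nrow(v)))]]
    ov <- vapply(marker_sets, function(g) length(intersect(g, top)) / length(g), 0)
    names(which.max(ov))
  }, "")
  names(cluster_type) <- sort(unique(cl))

  scores <- sapply(marker_sets, function(g)
    score_signature(norm, g, params = score_params))
  ord <- t(apply(scores, 1, order, decreasing = TRUE))
  top_type <- colnames(scores)[ord[, 1]]
  second_type <- colnames(scores)[ord[, 2]]
  top_score <- scores[cbind(seq_len(nrow(scores)), ord[, 1])]
  second_score <- scores[cbind(seq_len(nrow(scores)), ord[, 2])]

  ctype <- cluster_type[as.character(cl)]
  tcr <- norm$cell_meta$tcr %||% rep(FALSE, ncol(v))
  tnk_cluster <- type_class[ctype] == "immune" & ctype %in% c("T_CD8", "T_helper", "T_reg", "NK")

  disc_top <- mapply(is_discordant, top_type, ctype,
                     MoreArgs = list(type_class = type_class))
  disc_second <- mapply(is_discordant, second_type, ctype,
                        MoreArgs = list(type_class = type_class))

  reason <- rep(NA_character_, ncol(v))
  reason[tcr & !tnk_cluster] <- "tcr_in_non_tnk_cluster"
  reason[is.na(reason) & disc_top] <- "top_score_discordant"
  low_margin <- top_score < 1.15 * second_score & disc_second
  reason[is.na(reason) & low_margin] <- "ambiguous_second_discordant"

  unresolved <- !is.na(reason)
  type <- ifelse(unresolved, NA_character_, ctype)
  data.frame(cell_id = norm$cell_meta$cell_id, cluster = as.integer(cl),
             cluster_type = unname(ctype), top_type = top_type,
             second_type = second_type, top_score = top_score,
             second_score = second_score, type = type,
             unresolved = unresolved, unresolved_reason = reason,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Default mapping of simulator cell types to lineage classes
#' @return named character vector.
#' @export
default_type_class <- function() {
  c(epithelial_normal = "epithelial", malignant = "epithelial",
    fibroblast = "stromal", myofibroblast = "stromal",
    endothelial = "stromal",
    macrophage = "immune", T_CD8 = "immune", T_helper = "immune",
    T_reg = "immune", NK = "immune", B = "immune")
}

## discordance rules: within stromal clusters any non-stromal call is
## discordant (and vice versa for epithelial, except fibroblast calls, kept
## as possible EMT); within immune clusters only the cluster's own type is
## concordant, except T and NK which co-cluster.
is_discordant <- function(cell_type, cluster_type, type_class) {
  ccl <- type_class[[cluster_type]]
  tcl <- type_class[[cell_type]]
  if (ccl == "stromal") return(tcl != "stromal")
  if (ccl == "epithelial") {
    if (cell_type == "fibroblast") return(FALSE)
    return(tcl != "epithelial")
  }
  tnk <- c("T_CD8", "T_helper", "T_reg", "NK")
  if (cluster_type %in% tnk && cell_type %in% tnk) return(FALSE)
  cell_type != cluster_type
}

#' Per-gene differential expression between two groups
#'
#' Two-sided t-tests (Welch by default) on normalized log2 values, with
#' Benjamini-Hochberg q-values. The log2 fold-change is the difference of
#' group means in log2 space. Genes with zero variance in both groups get
#' p = 1 and are flagged.
#'
#' @param norm a `normalized_matrix` (or plain genes x cells matrix).
#' @param group per-cell factor/character with exactly two levels; the first
#'   level (or `levels[1]`) is the reference "A" group.
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @return data.frame per gene: `gene`, `mean_a`, `mean_b`, `log2fc`
#'   (A minus B), `t`, `p`, `q`, `zero_variance`.
#' @export
differential_expression <- function(norm, group, var_equal = FALSE) {
  v <- if (inherits(norm, "normalized_matrix")) norm$values else norm
  group <- as.factor(group)
  stop_if_not(nlevels(group) == 2, "group must have exactly two levels")
  a <- v[, group == levels(group)[1], drop = FALSE]
  b <- v[, group == levels(group)[2], drop = FALSE]
  stop_if_not(ncol(a) >= 2 && ncol(b) >= 2, "need >= 2 cells per group")
  tt <- row_t_test(a, b, var_equal = var_equal)
  data.frame(gene = rownames(v), mean_a = tt$mean_a, mean_b = tt$mean_b,
             log2fc = tt$mean_a - tt$mean_b, t = tt$t, p = tt$p,
             q = stats::p.adjust(tt$p, "BH"), zero_variance = tt$zero_var,
             stringsAsFactors = FALSE, row.names = NULL)
}
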