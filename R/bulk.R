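## ---------------------------------------------------------------------------
## Bulk deconvolution, confounder-residual adjustment, purity-normalized
## malignant profiles and ROC evaluation of the malignant IFN/MHC-II score.
## ---------------------------------------------------------------------------

#' Parameters for reference-matrix construction
#'
#' @param min_cells_per_type cell types with fewer cells are dropped from
#'   the reference.
#' @param max_cells_per_sample_type,min_cells_per_sample_type per-(sample,
#'   type) sampling bounds.
#' @param bulk_gene_min_samples reference genes must be detected in at
#'   least this many bulk samples.
#' @param seed RNG seed for the cell subsampling.
#' @return object of class `reference_matrix_params`.
#' @export
reference_matrix_params <- function(min_cells_per_type = 1000L,
                                    max_cells_per_sample_type = 50L,
                                    min_cells_per_sample_type = 10L,
                                    bulk_gene_min_samples = 5L,
                                    seed = 1L) {
  stop_if_not(min_cells_per_sample_type <= max_cells_per_sample_type,
              "min sampling bound must be <= max")
  structure(list(min_cells_per_type = as.integer(min_cells_per_type),
                 max_cells_per_sample_type = as.integer(max_cells_per_sample_type),
                 min_cells_per_sample_type = as.integer(min_cells_per_sample_type),
                 bulk_gene_min_samples = as.integer(bulk_gene_min_samples),
                 seed = as.integer(seed)),
            class = "reference_matrix_params")
}

#' Build a single-cell reference matrix and cell-type centroids
#'
#' Cell types with fewer than `min_cells_per_type` cells are dropped and
#' dendritic subtypes (pDC/cDC) are merged into one DC category. For every
#' (sample, type) with at least `min_cells_per_sample_type` cells, up to
#' `max_cells_per_sample_type` cells are sampled. Genes must be nonzero in
#' the sampled reference and detected in at least `bulk_gene_min_samples`
#' bulk samples. Centroids are per-type mean CPM profiles of the sampled
#' cells.
#'
#' @param data an [annotated_counts()] object of typed single cells.
#' @param cell_type per-cell type labels (NA cells are ignored).
#' @param bulk_counts genes x samples bulk count matrix (or a
#'   `bulk_cohort`).
#' @param params a [reference_matrix_params()].
#' @return list with `centroids` (genes x types, CPM scale), `cells`
#'   (sampled cell ids), `cell_type` (their labels), `genes`.
#' @export
build_reference <- function(data, cell_type, bulk_counts,
                            params = reference_matrix_params()) {
  if (inherits(bulk_counts, "bulk_cohort")) bulk_counts <- bulk_counts$counts
  ty <- cell_type
  ty[ty %in% c("pDC", "cDC")] <- "DC"
  keep_ty <- names(which(table(ty) >= params$min_cells_per_type))
  stop_if_not(length(keep_ty) > 0, "no cell type passes min_cells_per_type")
  sampled <- with_seed(derive_seed(params$seed, 7L), {
    idx <- integer()
    for (tt in keep_ty) for (smp in unique(data$cell_meta$sample)) {
      i <- which(ty == tt & data$cell_meta$sample == smp & !is.na(ty))
      if (length(i) < params$min_cells_per_sample_type) next
      idx <- c(idx, if (length(i) > params$max_cells_per_sample_type)
        sample(i, params$max_cells_per_sample_type) else i)
    }
    idx
  })
  stop_if_not(length(sampled) > 0, "no (sample, type) stratum passes the bounds")
  ref <- data$counts[, sampled, drop = FALSE]
  ref_ty <- ty[sampled]
  nonzero_ref <- Matrix::rowSums(ref) > 0
  in_bulk <- rownames(ref) %in%
    rownames(bulk_counts)[rowSums(bulk_counts > 0) >= params$bulk_gene_min_samples]
  genes <- rownames(ref)[nonzero_ref & in_bulk]
  stop_if_not(length(genes) > 0, "no genes overlap between reference and bulk")
  ref <- ref[genes, , drop = FALSE]
  cpm <- as.matrix(Matrix::t(Matrix::t(ref) / Matrix::colSums(ref)) * 1e6)
  centroids <- sapply(sort(unique(ref_ty)), function(tt)
    rowMeans(cpm[, ref_ty == tt, drop = FALSE]))
  list(centroids = centroids, cells = data$cell_meta$cell_id[sampled],
       cell_type = ref_ty, genes = genes)
}

#' Estimate cell-type fractions by nonnegative least squares
#'
#' Per bulk sample, the CPM profile is fit on the type centroids by NNLS and
#' coefficients are normalized to sum to one. Purity is the malignant
#' fraction. The `method` argument makes the estimator pluggable: pass a
#' function `(bulk_cpm, centroids) -> fractions` or a precomputed
#' samples x types fraction matrix (e.g. from an external deconvolution
#' tool) to substitute the built-in solver.
#'
#' @param bulk a `bulk_cohort` or genes x samples count matrix.
#' @param centroids genes x types centroid matrix (CPM scale).
#' @param method `"nnls"`, a function, or a precomputed fraction matrix.
#' @param malignant_type centroid column treated as malignant for purity.
#' @return list with `fractions` (samples x types, rows sum to 1) and
#'   `purity`; when `bulk` is a `bulk_cohort` the cohort is returned in
#'   `cohort` with both fields filled.
#' @export
estimate_fractions <- function(bulk, centroids, method = "nnls",
                               malignant_type = "malignant") {
  cohort <- NULL
  if (inherits(bulk, "bulk_cohort")) { cohort <- bulk; bulk <- bulk$counts }
  genes <- intersect(rownames(centroids), rownames(bulk))
  stop_if_not(length(genes) == nrow(centroids),
              "centroid genes must be a subset of bulk genes")
  tot <- colSums(bulk)
  stop_if_not(all(tot > 0), "all-zero bulk sample(s): %s",
              paste(colnames(bulk)[tot == 0], collapse = ", "))
  cpm <- sweep(bulk[genes, , drop = FALSE], 2, tot, "/") * 1e6
  A <- centroids[genes, , drop = FALSE]
  fr <- if (is.matrix(method)) {
    method
  } else if (is.function(method)) {
    method(cpm, A)
  } else {
    t(apply(cpm, 2, function(b) {
      co <- tryCatch(pracma::lsqnonneg(A, b)$x,
                     error = function(e) {
                       warning("NNLS failed; ridge fallback used")
                       pmax(solve(crossprod(A) + diag(1e-6 * sum(A^2), ncol(A)),
                                  crossprod(A, b)), 0)
                     })
      as.numeric(co)
    }))
  }
  colnames(fr) <- colnames(A)
  rownames(fr) <- colnames(bulk)
  fr <- fr / rowSums(fr)
  purity <- if (malignant_type %in% colnames(fr)) fr[, malignant_type]
  else rep(NA_real_, nrow(fr))
  if (!is.null(cohort)) {
    cohort$fractions <- fr
    cohort$purity <- purity
    return(list(fractions = fr, purity = purity, cohort = cohort))
  }
  list(fractions = fr, purity = purity)
}

#' Adjust signature scores for confounding cell-type fractions
#'
#' Each score is regressed by ordinary least squares on the stated
#' confounder fractions (e.g. macrophage and T-cell fractions for an IFN
#' score) and the residuals are returned as final scores. Collinear
#' confounders are dropped with a warning.
#'
#' @param scores numeric vector (or samples x scores matrix) of per-sample
#'   signature scores.
#' @param confounders samples x confounders numeric matrix.
#' @return residuals in the shape of `scores`.
#' @export
residual_adjust <- function(scores, confounders) {
  confounders <- as.matrix(confounders)
  n <- if (is.matrix(scores)) nrow(scores) else length(scores)
  stop_if_not(n >= ncol(confounders) + 2,
              "need at least confounders + 2 samples")
  fit <- stats::lm(scores ~ confounders)
  alias <- is.na(stats::coef(fit))
  if (any(alias)) warning("collinear confounder(s) dropped from the adjustment")
  stats::resid(fit)
}

#' Infer per-sample malignant expression profiles from bulk data
#'
#' On the linear CPM scale, the expected contribution of the confounding
#' cell types (by default macrophages and T cells) is subtracted from each
#' bulk profile and the remainder is divided by the sample's purity.
#' Negative values are clamped to zero and flagged; samples with purity at
#' or below `min_purity` are flagged unreliable. Set `log_space = TRUE` to
#' subtract on the log2(CPM/10+1) scale instead.
#'
#' @param bulk a `bulk_cohort` or genes x samples count matrix.
#' @param centroids genes x types centroid matrix (CPM scale).
#' @param fractions samples x types fraction matrix.
#' @param purity per-sample malignant fraction.
#' @param confounder_types centroid columns whose contribution is removed.
#' @param min_purity unreliability threshold.
#' @param log_space subtract on the log scale?
#' @return list with `adjusted` (genes x samples, CPM scale),
#'   `adjusted_log` (log2(CPM/10+1)), `clamped_fraction` per sample,
#'   `unreliable` samples.
#' @export
malignant_profile_adjust <- function(bulk, centroids, fractions, purity,
                                     confounder_types = c("macrophage", "T_CD8",
                                                          "T_helper", "T_reg"),
                                     min_purity = 0.05, log_space = FALSE) {
  if (inherits(bulk, "bulk_cohort")) bulk <- bulk$counts
  stop_if_not(all(purity > 0), "purity must be positive")
  genes <- rownames(centroids)
  cpm <- sweep(bulk[genes, , drop = FALSE], 2, colSums(bulk), "/") * 1e6
  ct <- intersect(confounder_types, colnames(centroids))
  expd <- centroids[, ct, drop = FALSE] %*% t(fractions[, ct, drop = FALSE])
  if (log_space) {
    adj <- log2(cpm / 10 + 1) - log2(expd / 10 + 1)
    adj <- sweep(adj, 2, purity, "/")
    clamped <- colMeans(adj < 0)
    adj[adj < 0] <- 0
    lin <- (2^adj - 1) * 10
  } else {
    lin <- sweep(cpm - expd, 2, purity, "/")
    clamped <- colMeans(lin < 0)
    lin[lin < 0] <- 0
    adj <- log2(lin / 10 + 1)
  }
  unreliable <- colnames(cpm)[purity <= min_purity]
  list(adjusted = lin, adjusted_log = if (log_space) adj else log2(lin / 10 + 1),
       clamped_fraction = clamped, unreliable = unreliable)
}

#' ROC curve and area under the curve
#'
#' AUC is the mid-rank Mann-Whitney U statistic divided by
#' `n_pos * n_neg`; curve points (FPR, TPR) are emitted at every score
#' threshold.
#'
#' @param scores numeric predictor.
#' @param labels binary outcome (logical, 0/1, or factor whose second level
#'   is positive).
#' @return list with `auc` and `curve` (data.frame threshold, fpr, tpr).
#' @export
roc_auc <- function(scores, labels) {
  pos <- as_binary_labels(labels)
  stop_if_not(any(pos) && any(!pos), "both classes must be present")
  n_pos <- sum(pos); n_neg <- sum(!pos)
  r <- rank(scores)
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  th <- sort(unique(scores), decreasing = TRUE)
  curve <- data.frame(
    threshold = c(Inf, th),
    fpr = c(0, vapply(th, function(t) mean(scores[!pos] >= t), 0)),
    tpr = c(0, vapply(th, function(t) mean(scores[pos] >= t), 0)))
  list(auc = auc, curve = curve)
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels == max(labels))
  f <- as.factor(labels)
  stop_if_not(nlevels(f) == 2, "labels must be binary")
  f == levels(f)[2]
}

#' Compare candidate outcome predictors by ROC AUC and a joint linear model
#'
#' Each feature's AUC against the binary outcome is computed, and all
#' features enter a joint linear probability model (OLS of the 0/1 outcome)
#' whose coefficients are tested by t-test. Collinear features trigger a
#' warning.
#'
#' @param features samples x features numeric matrix (named columns).
#' @param labels binary outcome.
#' @return list with `auc` (named per feature) and `model` (data.frame:
#'   feature, estimate, t, p).
#' @export
predictor_comparison <- function(features, labels) {
  features <- as.matrix(features)
  stop_if_not(ncol(features) >= 2, "need at least two features")
  stop_if_not(ncol(features) <= nrow(features) - 2,
              "more features than samples allow")
  y <- as.numeric(as_binary_labels(labels))
  aucs <- apply(features, 2, function(f) roc_auc(f, labels)$auc)
  df <- data.frame(y = y, features, check.names = FALSE)
  fit <- stats::lm(y ~ ., data = df)
  if (any(is.na(stats::coef(fit)))) warning("collinear feature(s) in the joint model")
  sm <- summary(fit)$coefficients
  sm <- sm[setdiff(rownames(sm), "(Intercept)"), , drop = FALSE]
  list(auc = aucs,
       model = data.frame(feature = rownames(sm), estimate = sm[, 1],
                          t = sm[, 3], p = sm[, 4],
                          stringsAsFactors = FALSE, row.names = NULL))
}
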