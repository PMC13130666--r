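## ---------------------------------------------------------------------------
## Expression-bin-matched relative signature scoring.
## ---------------------------------------------------------------------------

#' Parameters for bin-matched signature scoring
#'
#' Genes are stratified into `n_bins` equal-frequency bins of mean
#' expression; each signature gene contributes `controls_per_gene` control
#' genes drawn from its own bin (with replacement when the bin holds fewer
#' genes). One control draw is made per signature per call, shared across
#' cells, and is deterministic under `seed`.
#'
#' @param n_bins number of mean-expression bins (>= 2).
#' @param controls_per_gene control genes sampled per signature gene (>= 1).
#' @param seed RNG seed for the control draw.
#' @return object of class `signature_score_params`.
#' @export
signature_score_params <- function(n_bins = 30L, controls_per_gene = 100L,
                                   seed = 1L) {
  stop_if_not(n_bins >= 2, "n_bins must be >= 2")
  stop_if_not(controls_per_gene >= 1, "controls_per_gene must be >= 1")
  structure(list(n_bins = as.integer(n_bins),
                 controls_per_gene = as.integer(controls_per_gene),
                 seed = as.integer(seed)),
            class = "signature_score_params")
}

#' Score cells for a gene signature against bin-matched controls
#'
#' The per-cell score is the mean expression of the signature genes minus
#' the mean expression of a control gene set matched on average expression:
#' all genes are stratified into expression bins by their mean, and for each
#' signature gene `controls_per_gene` genes are sampled from its bin. A
#' positive score means the signature is expressed above genes of comparable
#' abundance in that cell.
#'
#' @param norm a `normalized_matrix` (or plain genes x cells matrix with
#'   rownames).
#' @param signature character vector of gene symbols.
#' @param params a [signature_score_params()].
#' @return numeric per-cell score vector (named by cell when colnames exist).
#' @export
score_signature <- function(norm, signature, params = signature_score_params()) {
  v <- if (inherits(norm, "normalized_matrix")) norm$values else norm
  sig <- intersect(signature, rownames(v))
  if (length(sig) == 0)
    stop_if_not(FALSE, "no signature genes present in the matrix (missing: %s)",
                paste(utils::head(signature, 5), collapse = ", "))
  bins <- expression_bins(v, params$n_bins)
  ctrl <- with_seed(params$seed, unlist(lapply(sig, function(g) {
    pool <- which(bins == bins[g])
    sample(pool, params$controls_per_gene,
           replace = length(pool) < params$controls_per_gene)
  })))
  sig_mean <- colMeans(v[sig, , drop = FALSE])
  ctrl_mean <- colMeans(v[ctrl, , drop = FALSE])
  sig_mean - ctrl_mean
}

## equal-frequency bins of gene mean expression; returns a named per-gene
## bin index
expression_bins <- function(v, n_bins) {
  m <- rowMeans(v)
  br <- stats::quantile(m, probs = seq(0, 1, length.out = n_bins + 1))
  br <- unique(br)
  b <- findInterval(m, br, rightmost.closed = TRUE, all.inside = TRUE)
  names(b) <- rownames(v)
  b
}

#' Score one signature per column of a signature list
#'
#' Convenience wrapper returning a cells x signatures score matrix.
#'
#' @inheritParams score_signature
#' @param signatures named list of gene sets.
#' @return matrix cells x signatures.
#' @export
score_signatures <- function(norm, signatures, params = signature_score_params()) {
  sapply(signatures, function(g) score_signature(norm, g, params = params))
}
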