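## ---------------------------------------------------------------------------
## Per-sample NMF and cross-patient metaprogram discovery.
##
## Heterogeneity within a cell type is decomposed per sample into additive
## nonnegative factors; factors recurring across patients (by Jaccard overlap
## of their top-gene lists) are metaclustered and distilled into consensus
## metaprogram signatures.
## ---------------------------------------------------------------------------

#' Parameters for NMF factorization and metaprogram derivation
#'
#' @param rank number of factors per sample.
#' @param restarts NMF restarts; the solution with the lowest Frobenius
#'   approximation error is kept.
#' @param top_genes genes defining each factor (by basis weight).
#' @param min_cells_per_factor factors attracting fewer cells are removed.
#' @param jaccard_min factors without a Jaccard overlap at least this large
#'   with any other factor are removed as sample-specific.
#' @param patient_majority consensus genes must appear in factors of
#'   strictly more than this fraction of represented patients.
#' @param min_cells_per_sample samples with fewer cells of the type under
#'   study are skipped.
#' @param sparsity L1 penalty weight on the coefficient matrix.
#' @param max_iter,tol stopping rule for the multiplicative updates.
#' @param tree_cut height at which the average-linkage (1 - Jaccard) tree is
#'   cut into metaclusters.
#' @param seed RNG seed.
#' @return object of class `nmf_params`.
#' @export
nmf_params <- function(rank = 10L, restarts = 20L, top_genes = 100L,
                       min_cells_per_factor = 10L, jaccard_min = 0.2,
                       patient_majority = 0.5, min_cells_per_sample = 30L,
                       sparsity = 0.01, max_iter = 200L, tol = 1e-5,
                       tree_cut = 0.8, seed = 1L) {
  stop_if_not(rank >= 2, "rank must be >= 2")
  stop_if_not(jaccard_min > 0 && jaccard_min < 1, "jaccard_min must be in (0,1)")
  structure(list(rank = as.integer(rank), restarts = as.integer(restarts),
                 top_genes = as.integer(top_genes),
                 min_cells_per_factor = as.integer(min_cells_per_factor),
                 jaccard_min = jaccard_min, patient_majority = patient_majority,
                 min_cells_per_sample = as.integer(min_cells_per_sample),
                 sparsity = sparsity, max_iter = as.integer(max_iter),
                 tol = tol, tree_cut = tree_cut, seed = as.integer(seed)),
            class = "nmf_params")
}

## sparse NMF by multiplicative updates: minimize ||V - WH||_F^2 +
## lambda * sum(H) over W,H >= 0. The basis W is initialised randomly; H is
## initialised from W and V so the factorization is invariant to cell order.
nmf_once <- function(V, rank, lambda, max_iter, tol, seed) {
  eps <- 1e-9
  W <- with_seed(seed, matrix(stats::runif(nrow(V) * rank, 0, max(V)), ncol = rank))
  H <- pmax(crossprod(W, V), 0) / (sum(W * W) + eps)
  err_old <- Inf
  for (it in seq_len(max_iter)) {
    W <- W * (V %*% t(H)) / (W %*% (H %*% t(H)) + eps)
    H <- H * (crossprod(W, V)) / (crossprod(W, W) %*% H + lambda + eps)
    if (it %% 10 == 0 || it == max_iter) {
      err <- sqrt(sum((V - W %*% H)^2))
      if (is.finite(err_old) && abs(err_old - err) < tol * max(err, 1)) break
      err_old <- err
    }
  }
  list(W = W, H = H, error = sqrt(sum((V - W %*% H)^2)))
}

#' Factorize one sample's expression slice into additive programs
#'
#' The input slice (already filtered, batch-corrected and centered) has its
#' negative values set to zero and is decomposed at the configured rank by
#' sparse NMF (L1 penalty on the coefficient side). The best of `restarts`
#' runs by Frobenius error is kept; each factor is reported as its top
#' `top_genes` genes by basis weight (or all positive-weight genes if
#' fewer).
#'
#' @param values genes x cells centered matrix for one sample and cell type.
#' @param sample,patient identifiers stored with the factors.
#' @param params an [nmf_params()].
#' @return list of factor entries (`sample`, `patient`, `factor`, `genes`,
#'   `error`, `basis` weights), or `NULL` (with a message) when the sample
#'   has fewer than `min_cells_per_sample` cells.
#' @export
run_sample_nmf <- function(values, sample = "S1", patient = sample,
                           params = nmf_params()) {
  if (ncol(values) < params$min_cells_per_sample) {
    message(sprintf("sample %s skipped: %d < %d cells", sample,
                    ncol(values), params$min_cells_per_sample))
    return(NULL)
  }
  V <- pmax(values, 0)
  runs <- lapply(seq_len(params$restarts), function(r)
    nmf_once(V, params$rank, params$sparsity, params$max_iter, params$tol,
             seed = derive_seed(params$seed, 100L + r)))
  best <- runs[[which.min(vapply(runs, `[[`, 0, "error"))]]
  lapply(seq_len(params$rank), function(k) {
    w <- best$W[, k]
    names(w) <- rownames(values)
    pos <- w[w > 0]
    genes <- names(sort(pos, decreasing = TRUE))[
      seq_len(min(params$top_genes, length(pos)))]
    list(sample = sample, patient = patient, factor = k, genes = genes,
         error = best$error, basis = w)
  })
}

#' Assign cells to the factor whose genes are most highly expressed
#'
#' Each cell goes to the factor maximizing the mean (centered) expression of
#' the factor's gene list; factors attracting fewer than
#' `min_cells_per_factor` cells are marked not kept.
#'
#' @param values genes x cells centered matrix.
#' @param factors list of factor entries (see [run_sample_nmf()]) or a list
#'   of gene-symbol vectors.
#' @param params an [nmf_params()].
#' @return list with `assignment` (per-cell factor index), `kept` (logical
#'   per factor) and `n_cells` per factor.
#' @export
assign_cells_to_factors <- function(values, factors, params = nmf_params()) {
  gene_lists <- factor_gene_lists(factors)
  stop_if_not(length(gene_lists) >= 1, "need at least one factor")
  sc <- sapply(gene_lists, function(g) {
    g <- intersect(g, rownames(values))
    colMeans(values[g, , drop = FALSE])
  })
  if (is.null(dim(sc))) sc <- matrix(sc, ncol = length(gene_lists))
  assignment <- max.col(sc, ties.method = "first")
  n_cells <- tabulate(assignment, nbins = length(gene_lists))
  list(assignment = assignment, kept = n_cells >= params$min_cells_per_factor,
       n_cells = n_cells)
}

factor_gene_lists <- function(factors) {
  if (length(factors) && is.list(factors[[1]]) && !is.null(factors[[1]]$genes))
    lapply(factors, `[[`, "genes")
  else factors
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

#' Metacluster factors across samples by Jaccard similarity
#'
#' Pairwise Jaccard similarities between factor gene lists are computed;
#' factors without any partner at `jaccard_min` are dropped as
#' sample-specific. The remaining factors are clustered hierarchically on
#' (1 - Jaccard) distance with average linkage and the tree is cut at
#' `tree_cut`; only metaclusters spanning at least two patients proceed.
#'
#' @param factors flat list of factor entries from [run_sample_nmf()]
#'   (concatenated across samples), each carrying `patient` and `genes`.
#' @param params an [nmf_params()].
#' @return list of metaclusters, each a list with `members` (factor
#'   entries) and `patients`; empty list (with a message) when all factors
#'   are dropped.
#' @export
cluster_factors <- function(factors, params = nmf_params()) {
  stop_if_not(length(factors) >= 2, "need at least two retained factors")
  gl <- factor_gene_lists(factors)
  n <- length(gl)
  J <- diag(1, n)
  for (i in seq_len(n)) for (j in seq_len(i - 1))
    J[i, j] <- J[j, i] <- jaccard(gl[[i]], gl[[j]])
  has_partner <- apply(J - diag(1, n), 1, max) >= params$jaccard_min
  if (!any(has_partner)) {
    message("all factors dropped: no Jaccard partner")
    return(list())
  }
  keep <- which(has_partner)
  if (length(keep) == 1) {
    message("all factors dropped: no cluster of size >= 2")
    return(list())
  }
  hc <- stats::hclust(stats::as.dist(1 - J[keep, keep]), method = "average")
  grp <- stats::cutree(hc, h = params$tree_cut)
  out <- lapply(sort(unique(grp)), function(g) {
    members <- factors[keep[grp == g]]
    pats <- unique(vapply(members, `[[`, "", "patient"))
    list(members = members, patients = pats)
  })
  Filter(function(mc) length(mc$patients) >= 2, out)
}

#' Derive consensus metaprogram signatures from metaclusters
#'
#' Within each metacluster, a gene enters the metaprogram when it appears in
#' the factors of strictly more than `patient_majority` of the patients
#' represented in the cluster. Metaclusters with an empty consensus are
#' discarded with a message.
#'
#' @param metaclusters output of [cluster_factors()].
#' @param params an [nmf_params()].
#' @return named list of metaprograms (`MP1`, `MP2`, ...), each with
#'   `genes`, `patients`, and `members` (the contributing factors).
#' @export
derive_metaprograms <- function(metaclusters, params = nmf_params()) {
  out <- list()
  for (mc in metaclusters) {
    pats <- mc$patients
    by_pat <- lapply(pats, function(p) {
      unique(unlist(lapply(Filter(function(f) f$patient == p, mc$members),
                           `[[`, "genes")))
    })
    counts <- table(unlist(by_pat))
    genes <- names(counts)[counts > params$patient_majority * length(pats)]
    if (length(genes) == 0) {
      message("metacluster discarded: empty consensus")
      next
    }
    out[[length(out) + 1L]] <- list(genes = sort(genes), patients = pats,
                                    members = mc$members)
  }
  if (length(out)) names(out) <- paste0("MP", seq_along(out))
  out
}

#' Assign cells to metaprograms by bin-matched signature scores
#'
#' Every cell is scored for each metaprogram signature (see
#' [score_signature()]) and assigned to the top-scoring one; exact ties
#' break deterministically to the first metaprogram in name order and are
#' flagged. Per-(patient, timepoint) metaprogram fractions are tabulated.
#'
#' @param norm a centered `normalized_matrix` of the cells to assign.
#' @param metaprograms output of [derive_metaprograms()] (or a named list of
#'   gene sets).
#' @param score_params a [signature_score_params()].
#' @return list with `assignment` (data.frame: cell_id, metaprogram, score,
#'   tied), `scores` (cells x metaprograms), and `fractions` (data.frame per
#'   patient/timepoint/metaprogram with `fraction` and `n_cells`).
#' @export
assign_cells_to_metaprograms <- function(norm, metaprograms,
                                         score_params = signature_score_params()) {
  stop_if_not(length(metaprograms) > 0, "metaprograms must be nonempty")
  sigs <- lapply(metaprograms, function(m) if (is.list(m)) m$genes else m)
  sc <- score_signatures(norm, sigs, params = score_params)
  top <- max.col(sc, ties.method = "first")
  tied <- apply(sc, 1, function(r) sum(r == max(r)) > 1)
  cm <- norm$cell_meta
  assignment <- data.frame(cell_id = cm$cell_id,
                           metaprogram = colnames(sc)[top],
                           score = sc[cbind(seq_len(nrow(sc)), top)],
                           tied = tied, stringsAsFactors = FALSE)
  grp <- paste(cm$patient, cm$timepoint, sep = "\r")
  fr <- do.call(rbind, lapply(unique(grp), function(g) {
    i <- grp == g
    tab <- table(factor(assignment$metaprogram[i], colnames(sc)))
    data.frame(patient = cm$patient[i][1], timepoint = cm$timepoint[i][1],
               metaprogram = names(tab), n_cells = as.integer(tab),
               fraction = as.numeric(tab) / sum(i),
               stringsAsFactors = FALSE)
  }))
  list(assignment = assignment, scores = sc, fractions = fr)
}
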