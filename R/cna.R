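## ---------------------------------------------------------------------------
## Expression-based CNA inference, subclone calling, malignancy classification
## ---------------------------------------------------------------------------

#' Parameters for CNA inference and malignancy calling
#'
#' @param window moving-average window in genes.
#' @param truncate symmetric truncation bound on centered expression before
#'   smoothing.
#' @param denoise_band half-width of the band set to zero after reference
#'   adjustment.
#' @param event_threshold absolute arm-mean above which a cluster carries a
#'   copy-number event.
#' @param merge_max_diff maximum per-arm mean difference for merging clusters
#'   with identical event sets.
#' @param min_cluster minimum cluster size; smaller clusters are merged into
#'   their nearest neighbor.
#' @param signal_top_fraction fraction of genes (by absolute CNA) entering
#'   the per-cell CNA signal.
#' @param corr_top_fraction fraction of top-signal epithelial cells defining
#'   the correlation reference profile.
#' @param stromal_exceed_max strict upper bound on the fraction of stromal
#'   reference cells allowed above each malignancy cutoff.
#' @param knn_k neighbors for the subclone over-clustering graph.
#' @param n_pcs principal components for the subclone embedding.
#' @param resolution Louvain resolution for the over-clustering; moderate
#'   values suffice because arm-event merging consolidates the clusters.
#' @param seed RNG seed for clustering.
#' @return object of class `cna_params`.
#' @export
cna_params <- function(window = 100L, truncate = 3, denoise_band = 0.15,
                       event_threshold = 0.15, merge_max_diff = 0.15,
                       min_cluster = 10L, signal_top_fraction = 2 / 3,
                       corr_top_fraction = 0.25, stromal_exceed_max = 0.01,
                       knn_k = 15L, n_pcs = 10L, resolution = 0.5,
                       seed = 1L) {
  p <- list(window = as.integer(window), truncate = truncate,
            denoise_band = denoise_band, event_threshold = event_threshold,
            merge_max_diff = merge_max_diff, min_cluster = as.integer(min_cluster),
            signal_top_fraction = signal_top_fraction,
            corr_top_fraction = corr_top_fraction,
            stromal_exceed_max = stromal_exceed_max,
            knn_k = as.integer(knn_k), n_pcs = as.integer(n_pcs),
            resolution = resolution, seed = as.integer(seed))
  stop_if_not(p$window > 0 && p$truncate > 0 && p$denoise_band > 0,
              "CNA parameters must be positive")
  stop_if_not(p$signal_top_fraction > 0 && p$signal_top_fraction <= 1 &&
                p$corr_top_fraction > 0 && p$corr_top_fraction <= 1,
              "fractions must be in (0,1]")
  structure(p, class = "cna_params")
}

#' Infer smoothed CNA profiles against stromal references
#'
#' Per patient: expression values are re-centered (per gene, within the
#' patient), truncated to `[-truncate, truncate]`, and smoothed per
#' chromosome with a centered `window`-gene moving average (windows shrink
#' at chromosome edges; chromosomes shorter than the window fall back to a
#' chromosome-wide mean and are logged), then each cell's smoothed profile
#' is re-centered at its median. Mean smoothed profiles of each
#' stromal reference type define a diploid reference band; every cell's
#' value is adjusted by subtracting the highest reference value when above
#' the band and the lowest when below it (values inside the band become
#' zero, so adjustment never flips a sign), and adjusted values within
#' `[-denoise_band, denoise_band]` are zeroed.
#'
#' @param norm a `normalized_matrix` whose `gene_meta` carries `chromosome`,
#'   `arm` and `order` (genes must be sorted by chromosome and order).
#' @param cell_role per-cell character: `"epithelial"` for cells to be
#'   classified, a stromal type name (e.g. `"fibroblast"`) for reference
#'   cells; anything else (including NA) is ignored.
#' @param params a [cna_params()].
#' @param gene_center,cell_center disable the per-gene (within-patient) or
#'   per-cell (median) re-centering steps; both default on and exist mainly
#'   so small hand-computed examples can bypass them.
#' @return object of class `cna_workspace`: adjusted CNA matrix (genes x
#'   cells) for all epithelial and stromal cells, roles, patient labels,
#'   gene table, per-patient reference profiles.
#' @export
infer_cna_profiles <- function(norm, cell_role, params = cna_params(),
                               gene_center = TRUE, cell_center = TRUE) {
  gm <- norm$gene_meta
  stop_if_not(!is.null(gm$chromosome) && !is.null(gm$order),
              "gene_meta must carry chromosome and order")
  o <- order(match(gm$chromosome, unique(gm$chromosome)), gm$order)
  stop_if_not(all(o == seq_along(o)),
              "genes must be ordered by chromosome and position")
  stop_if_not(length(cell_role) == ncol(norm$values),
              "cell_role must label every cell")

  keep <- !is.na(cell_role) & cell_role != ""
  v_all <- norm$values[, keep, drop = FALSE]
  role <- cell_role[keep]
  cm <- norm$cell_meta[keep, , drop = FALSE]
  chr <- gm$chromosome
  chr_idx <- split(seq_len(nrow(gm)), factor(chr, unique(chr)))
  short <- names(chr_idx)[lengths(chr_idx) < params$window]
  if (length(short))
    message("chromosome(s) shorter than the smoothing window (truncated windows): ",
            paste(short, collapse = ", "))

  cna <- matrix(0, nrow(v_all), ncol(v_all), dimnames = dimnames(v_all))
  refs <- list()
  for (pat in unique(cm$patient)) {
    ci <- which(cm$patient == pat)
    stromal <- ci[!(role[ci] %in% "epithelial")]
    stop_if_not(length(stromal) > 0, "patient %s has no stromal reference cells", pat)
    v <- v_all[, ci, drop = FALSE]
    if (gene_center) v <- v - rowMeans(v)
    v[v > params$truncate] <- params$truncate
    v[v < -params$truncate] <- -params$truncate
    sm <- v
    for (ix in chr_idx)
      sm[ix, ] <- running_mean_rows(v[ix, , drop = FALSE], params$window)
    ## re-center each cell's smoothed profile at its median: cells with net
    ## copy-number gains otherwise acquire a spurious genome-wide offset
    ## through the library-size normalization
    if (cell_center) sm <- sweep(sm, 2, apply(sm, 2, stats::median))

    stypes <- unique(role[stromal])
    stypes <- stypes[vapply(stypes, function(s)
      sum(role[ci] == s) >= params$min_cluster, TRUE)]
    if (length(stypes) == 0) stypes <- unique(role[stromal])
    ref <- sapply(stypes, function(s)
      rowMeans(sm[, which(role[ci] == s), drop = FALSE], na.rm = TRUE))
    if (is.null(dim(ref))) ref <- matrix(ref, ncol = 1, dimnames = list(NULL, stypes))
    rmax <- apply(ref, 1, max)
    rmin <- apply(ref, 1, min)

    ## band-relative adjustment: values above the highest reference keep the
    ## positive excess, values below the lowest keep the negative excess,
    ## values inside the reference band are diploid-like and set to zero
    adj <- sm
    hi <- sm > rmax
    lo <- sm < rmin
    adj[hi] <- sm[hi] - rmax[row(sm)[hi]]
    adj[lo] <- sm[lo] - rmin[row(sm)[lo]]
    adj[!hi & !lo] <- 0
    adj[abs(adj) <= params$denoise_band] <- 0
    cna[, ci] <- adj
    refs[[pat]] <- ref
  }
  structure(list(cna = cna, role = role, cell_meta = cm, gene_meta = gm,
                 reference_profiles = refs, params = params,
                 signal = NULL, correlation = NULL, subclone = NULL,
                 call = NULL, thresholds = NULL),
            class = "cna_workspace")
}

#' @export
print.cna_workspace <- function(x, ...) {
  cat(sprintf("cna_workspace: %d genes x %d cells (%d epithelial), %d patient(s)\n",
              nrow(x$cna), ncol(x$cna), sum(x$role == "epithelial"),
              length(unique(x$cell_meta$patient))))
  if (!is.null(x$subclone))
    cat("  subclones:", paste(names(table(x$subclone)), collapse = ", "), "\n")
  invisible(x)
}

## per-cell CNA signal: mean |CNA| over the top fraction of genes by |CNA|
cna_signal_of <- function(mat, top_fraction) {
  n_top <- ceiling(top_fraction * nrow(mat))
  apply(abs(mat), 2, function(a) mean(sort(a, decreasing = TRUE)[seq_len(n_top)]))
}

## correlation of each column with a reference profile; constant columns
## (or a constant reference) yield 0 and are flagged
cor_with_profile <- function(mat, profile) {
  flag <- apply(mat, 2, stats::sd) == 0 | stats::sd(profile) == 0
  r <- rep(0, ncol(mat))
  if (!all(flag))
    r[!flag] <- suppressWarnings(as.numeric(stats::cor(mat[, !flag, drop = FALSE], profile)))
  r[is.na(r)] <- 0
  list(r = r, flag = flag)
}

#' Compute per-cell CNA signal and CNA correlation
#'
#' CNA signal is the mean absolute CNA value over the cell's top
#' `signal_top_fraction` genes ranked by absolute CNA. CNA correlation is the
#' Pearson correlation between the cell's CNA profile and the mean profile
#' of the patient's top `corr_top_fraction` epithelial cells by signal.
#' Cells with a constant CNA profile get correlation 0 and are flagged.
#'
#' @param ws a `cna_workspace` from [infer_cna_profiles()].
#' @param params a [cna_params()].
#' @return the workspace with `signal`, `correlation` and
#'   `correlation_flag` filled in for every (epithelial and stromal) cell.
#' @export
compute_cna_scores <- function(ws, params = ws$params) {
  sig <- cna_signal_of(ws$cna, params$signal_top_fraction)
  corr <- rep(0, ncol(ws$cna))
  flag <- rep(FALSE, ncol(ws$cna))
  for (pat in unique(ws$cell_meta$patient)) {
    ci <- which(ws$cell_meta$patient == pat)
    epi <- ci[ws$role[ci] == "epithelial"]
    if (length(epi) == 0) next
    n_hot <- max(1L, ceiling(params$corr_top_fraction * length(epi)))
    hot <- epi[order(sig[epi], decreasing = TRUE)[seq_len(n_hot)]]
    prof <- rowMeans(ws$cna[, hot, drop = FALSE])
    cc <- cor_with_profile(ws$cna[, ci, drop = FALSE], prof)
    corr[ci] <- cc$r
    flag[ci] <- cc$flag
  }
  ws$signal <- sig
  ws$correlation <- corr
  ws$correlation_flag <- flag
  ws
}

#' Infer genetic subclones from the CNA matrix
#'
#' Per patient, the epithelial CNA matrix is filtered to the top
#' `signal_top_fraction` genes by mean absolute CNA, embedded by PCA and
#' over-clustered with Louvain community detection on a `knn_k`-nearest-
#' neighbor graph. Clusters smaller than `min_cluster` are merged into their
#' nearest cluster by a kNN vote with `k = ln(n_cells)`. Arm-level events
#' (mean CNA beyond `event_threshold`) are called per cluster, and cluster
#' pairs with identical event sets whose arm means differ by less than
#' `merge_max_diff` everywhere are merged iteratively (means and events
#' recomputed each round) until every remaining pair differs in at least one
#' arm.
#'
#' @inheritParams compute_cna_scores
#' @return the workspace with per-cell `subclone` labels
#'   (`"<patient>_<k>"`; NA for stromal cells) and a `subclone_events` list
#'   of per-subclone arm-event tables.
#' @export
infer_subclones <- function(ws, params = ws$params) {
  arm_key <- paste0(ws$gene_meta$chromosome, ws$gene_meta$arm)
  sub <- rep(NA_character_, ncol(ws$cna))
  events_out <- list()
  for (pat in unique(ws$cell_meta$patient)) {
    epi <- which(ws$cell_meta$patient == pat & ws$role == "epithelial")
    stop_if_not(length(epi) >= 2, "patient %s has too few epithelial cells", pat)
    m <- ws$cna[, epi, drop = FALSE]
    g_keep <- order(rowMeans(abs(m)), decreasing = TRUE)[
      seq_len(ceiling(params$signal_top_fraction * nrow(m)))]
    g_keep <- sort(g_keep)
    mf <- m[g_keep, , drop = FALSE]
    arms <- arm_key[g_keep]

    k <- min(params$knn_k, length(epi) - 1L)
    if (k < params$knn_k)
      message(sprintf("patient %s: k reduced to %d (few cells)", pat, k))
    emb <- pca_embed(mf, params$n_pcs)
    cl <- as.integer(with_seed(derive_seed(params$seed, 11L),
                               igraph::membership(igraph::cluster_louvain(
                                 knn_graph(emb, k), resolution = params$resolution))))

    cl <- merge_small_clusters(cl, emb, params$min_cluster,
                               k_nn = max(1L, round(log(length(epi)))))
    cl <- merge_clusters_by_events(cl, mf, arms, params)

    sizes <- sort(table(cl), decreasing = TRUE)
    relab <- stats::setNames(seq_along(sizes), names(sizes))
    sub[epi] <- sprintf("%s_%d", pat, relab[as.character(cl)])
    ev <- arm_events(mf, arms, sub[epi], params$event_threshold)
    events_out[[pat]] <- ev
  }
  ws$subclone <- sub
  ws$subclone_events <- events_out
  ws
}

## reassign clusters below the minimum size by majority vote among each
## cell's k nearest neighbors in the retained clusters
merge_small_clusters <- function(cl, emb, min_cluster, k_nn) {
  repeat {
    sizes <- table(cl)
    small <- names(sizes)[sizes < min_cluster]
    if (length(small) == 0 || length(sizes) == 1) break
    s <- small[which.min(sizes[small])]
    from <- which(cl == as.integer(s))
    others <- which(cl != as.integer(s))
    d <- as.matrix(stats::dist(emb))[from, others, drop = FALSE]
    votes <- unlist(lapply(seq_along(from), function(i) {
      nn <- others[order(d[i, ])[seq_len(min(k_nn, length(others)))]]
      cl[nn]
    }))
    cl[from] <- as.integer(names(which.max(table(votes))))
  }
  cl
}

## per-cluster arm means and event calls
arm_means <- function(mat, arms, cl) {
  ua <- unique(arms)
  t(sapply(sort(unique(cl)), function(ci) {
    prof <- rowMeans(mat[, cl == ci, drop = FALSE])
    vapply(ua, function(a) mean(prof[arms == a]), 0)
  }))
}

arm_events <- function(mat, arms, cl, threshold) {
  am <- arm_means(mat, arms, cl)
  ev <- sign(am) * (abs(am) > threshold)
  rownames(ev) <- rownames(am) <- sort(unique(cl))
  list(means = am, events = ev)
}

merge_clusters_by_events <- function(cl, mat, arms, params) {
  repeat {
    ids <- sort(unique(cl))
    if (length(ids) == 1) break
    ae <- arm_events(mat, arms, cl, params$event_threshold)
    merged <- FALSE
    best <- NULL; best_d <- Inf
    for (i in seq_along(ids)) for (j in seq_len(i - 1)) {
      same <- all(ae$events[i, ] == ae$events[j, ])
      dmax <- max(abs(ae$means[i, ] - ae$means[j, ]))
      if (same && dmax < params$merge_max_diff && dmax < best_d) {
        best <- c(ids[i], ids[j]); best_d <- dmax
      }
    }
    if (!is.null(best)) {
      cl[cl == best[1]] <- best[2]
      merged <- TRUE
    }
    if (!merged) break
  }
  cl
}

#' Classify epithelial cells as malignant, non-malignant, or unresolved
#'
#' For each inferred subclone, a correlation reference profile is built from
#' the subclone's own top `corr_top_fraction` cells by CNA signal, and the
#' patient's stromal reference cells are scored with the same signal and
#' correlation definitions. Cutoffs are then set at the smallest values such
#' that strictly fewer than `stromal_exceed_max` of the stromal cells exceed
#' each cutoff. Epithelial cells above both cutoffs are malignant, below
#' both non-malignant, and above exactly one unresolved.
#'
#' @inheritParams compute_cna_scores
#' @return the workspace with a per-cell `call`
#'   (malignant/non_malignant/unresolved; NA for stromal cells) and a
#'   `thresholds` data.frame (per patient and subclone: both cutoffs plus
#'   the realized stromal exceedance fractions).
#' @export
classify_malignant <- function(ws, params = ws$params) {
  stop_if_not(!is.null(ws$subclone), "run infer_subclones() first")
  stop_if_not(!is.null(ws$signal), "run compute_cna_scores() first")
  call <- rep(NA_character_, ncol(ws$cna))
  thr <- list()
  for (pat in unique(ws$cell_meta$patient)) {
    ci <- which(ws$cell_meta$patient == pat)
    stromal <- ci[ws$role[ci] != "epithelial"]
    stop_if_not(length(stromal) > 0, "patient %s has no stromal reference", pat)
    subs <- unique(stats::na.omit(ws$subclone[ci]))
    for (s in subs) {
      members <- ci[!is.na(ws$subclone[ci]) & ws$subclone[ci] == s]
      n_hot <- max(1L, ceiling(params$corr_top_fraction * length(members)))
      hot <- members[order(ws$signal[members], decreasing = TRUE)[seq_len(n_hot)]]
      prof <- rowMeans(ws$cna[, hot, drop = FALSE])

      cc_epi <- cor_with_profile(ws$cna[, members, drop = FALSE], prof)
      cc_str <- cor_with_profile(ws$cna[, stromal, drop = FALSE], prof)

      thr_sig <- strict_quantile_threshold(ws$signal[stromal], params$stromal_exceed_max)
      thr_cor <- strict_quantile_threshold(cc_str$r, params$stromal_exceed_max)

      above_sig <- ws$signal[members] > thr_sig
      above_cor <- cc_epi$r > thr_cor
      call[members] <- ifelse(above_sig & above_cor, "malignant",
                              ifelse(!above_sig & !above_cor, "non_malignant",
                                     "unresolved"))
      thr[[length(thr) + 1L]] <- data.frame(
        patient = pat, subclone = s, n_cells = length(members),
        signal_cutoff = thr_sig, correlation_cutoff = thr_cor,
        stromal_exceed_signal = mean(ws$signal[stromal] > thr_sig),
        stromal_exceed_correlation = mean(cc_str$r > thr_cor),
        stringsAsFactors = FALSE)
    }
  }
  ws$call <- call
  ws$thresholds <- do.call(rbind, thr)
  ws
}

## smallest observed value such that strictly fewer than `max_frac` of the
## values exceed it: the (m+1)-th largest with m = ceiling(max_frac*n) - 1
strict_quantile_threshold <- function(x, max_frac) {
  n <- length(x)
  m <- max(0L, ceiling(max_frac * n) - 1L)
  sort(x, decreasing = TRUE)[min(m + 1L, n)]
}

#' Chi-square association between subclone identity and timepoint
#'
#' Per patient, a chi-square test of independence on the subclone x
#' timepoint contingency table (no continuity correction). When any expected
#' count is zero the test is rerun with a simulated p-value and flagged.
#'
#' @param subclone per-cell subclone labels (NA for non-epithelial cells).
#' @param timepoint per-cell timepoint (`"pre"`/`"post"`).
#' @param patient per-cell patient labels.
#' @return data.frame per patient: `chi2`, `df`, `p`, `simulated_p`,
#'   `n_subclones`.
#' @export
subclone_timepoint_association <- function(subclone, timepoint, patient) {
  keep <- !is.na(subclone)
  out <- lapply(unique(patient[keep]), function(pat) {
    i <- keep & patient == pat
    tab <- table(subclone[i], timepoint[i])
    if (nrow(tab) < 2 || ncol(tab) < 2)
      return(data.frame(patient = pat, chi2 = NA, df = NA, p = NA,
                        simulated_p = FALSE, n_subclones = nrow(tab)))
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sim <- any(expected == 0)
    ct <- if (sim)
      stats::chisq.test(tab, simulate.p.value = TRUE, B = 2000)
    else stats::chisq.test(tab, correct = FALSE)
    data.frame(patient = pat, chi2 = unname(ct$statistic),
               df = unname(ct$parameter %||% NA), p = ct$p.value,
               simulated_p = sim, n_subclones = nrow(tab),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Count malignant subclones per patient
#'
#' A genetic subclone is reported as malignant when the majority of its
#' cells are classified malignant; the event-free cluster of non-malignant
#' epithelial cells (and stray unresolved cells) is thereby excluded.
#'
#' @param ws a `cna_workspace` after [classify_malignant()].
#' @return named integer vector (per patient) of malignant subclone counts.
#' @export
count_malignant_subclones <- function(ws) {
  stop_if_not(!is.null(ws$call), "run classify_malignant() first")
  pats <- unique(ws$cell_meta$patient)
  out <- vapply(pats, function(p) {
    i <- which(ws$cell_meta$patient == p & !is.na(ws$subclone))
    subs <- unique(ws$subclone[i])
    sum(vapply(subs, function(s) {
      j <- i[ws$subclone[i] == s]
      mean(ws$call[j] == "malignant", na.rm = TRUE) > 0.5
    }, TRUE))
  }, 1L)
  names(out) <- pats
  out
}
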