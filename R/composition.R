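## ---------------------------------------------------------------------------
## Pre/post-treatment composition statistics over cell states.
## ---------------------------------------------------------------------------

#' Parameters for composition statistics
#'
#' @param min_cells_fraction_test minimum confidently assigned cells a
#'   patient needs at each timepoint to enter a fraction-shift test.
#' @param min_cells_score_test minimum cells per timepoint for per-patient
#'   signature-delta tests.
#' @param fc_significance_floor fold-change below which a significant delta
#'   is not marked (the 1.3 rule).
#' @param de_p,de_abs_log2fc per-patient significance criteria for the
#'   recurrent-DE tally.
#' @param recurrence_fraction fraction of patients in which a gene must be
#'   consistently significant to be called recurrent.
#' @param fc_scale how the 1.3 fold-change floor is interpreted for
#'   signature scores: `"log2"` treats score deltas as log2 fold-changes
#'   (|delta| > log2(floor)); `"linear"` compares the ratio of positively
#'   shifted mean scores.
#' @return object of class `composition_params`.
#' @export
composition_params <- function(min_cells_fraction_test = 20L,
                               min_cells_score_test = 50L,
                               fc_significance_floor = 1.3,
                               de_p = 0.05, de_abs_log2fc = 1.0,
                               recurrence_fraction = 0.5,
                               fc_scale = c("log2", "linear")) {
  stop_if_not(min_cells_fraction_test > 0 && fc_significance_floor > 0 &&
                de_p > 0 && de_abs_log2fc > 0,
              "composition thresholds must be positive")
  structure(list(min_cells_fraction_test = as.integer(min_cells_fraction_test),
                 min_cells_score_test = as.integer(min_cells_score_test),
                 fc_significance_floor = fc_significance_floor,
                 de_p = de_p, de_abs_log2fc = de_abs_log2fc,
                 recurrence_fraction = recurrence_fraction,
                 fc_scale = match.arg(fc_scale)),
            class = "composition_params")
}

#' Paired test of metaprogram fraction shifts after treatment
#'
#' Per metaprogram, patients with both timepoints and at least
#' `min_cells_fraction_test` assigned cells at each are retained; a paired
#' t-test compares post vs pre fractions across those patients. With fewer
#' than three eligible patients the test is skipped with a reason.
#'
#' @param fractions data.frame with columns `patient`, `timepoint`
#'   ("pre"/"post"), `metaprogram`, `fraction`, `n_cells` (e.g. from
#'   [assign_cells_to_metaprograms()]).
#' @param params a [composition_params()].
#' @return data.frame per metaprogram: `n_patients`, `mean_delta`
#'   (post - pre), `t`, `p`, `q`, `zero_variance`, `skipped_reason`;
#'   excluded patients are listed in `attr(, "exclusions")`.
#' @export
metaprogram_fraction_shift <- function(fractions, params = composition_params()) {
  mps <- unique(fractions$metaprogram)
  excl <- list()
  rows <- lapply(mps, function(mp) {
    f <- fractions[fractions$metaprogram == mp, ]
    pre <- f[f$timepoint == "pre", ]; post <- f[f$timepoint == "post", ]
    pats <- intersect(pre$patient, post$patient)
    ok <- vapply(pats, function(p)
      pre$n_cells[pre$patient == p] >= params$min_cells_fraction_test &&
        post$n_cells[post$patient == p] >= params$min_cells_fraction_test, TRUE)
    excl[[mp]] <<- pats[!ok]
    pats <- pats[ok]
    if (length(pats) < 3)
      return(data.frame(metaprogram = mp, n_patients = length(pats),
                        mean_delta = NA, t = NA, p = NA,
                        zero_variance = FALSE,
                        skipped_reason = "fewer than 3 eligible patients",
                        stringsAsFactors = FALSE))
    d <- post$fraction[match(pats, post$patient)] -
      pre$fraction[match(pats, pre$patient)]
    if (stats::sd(d) == 0)
      return(data.frame(metaprogram = mp, n_patients = length(pats),
                        mean_delta = mean(d), t = 0, p = 1,
                        zero_variance = TRUE, skipped_reason = NA,
                        stringsAsFactors = FALSE))
    tt <- stats::t.test(d)
    data.frame(metaprogram = mp, n_patients = length(pats),
               mean_delta = mean(d), t = unname(tt$statistic), p = tt$p.value,
               zero_variance = FALSE, skipped_reason = NA,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, "BH")
  attr(out, "exclusions") <- excl
  out
}

#' Per-patient signature-score deltas with the fold-change rule
#'
#' For each patient with at least `min_cells_score_test` cells at both
#' timepoints and each signature, the difference of mean scores (post -
#' pre) is computed with a two-sided t-test across cells. A delta is marked
#' significant only when the p-value threshold passes AND the fold change
#' exceeds `fc_significance_floor`. The summary includes the average over
#' patients and the responder-minus-non-responder difference of group
#' means.
#'
#' @param scores cells x signatures score matrix.
#' @param cell_meta data.frame per cell with `patient`, `timepoint`.
#' @param response named character vector (per patient, "R"/"NR"), optional.
#' @param params a [composition_params()].
#' @param p_threshold significance level for the per-patient t-test.
#' @return list with `delta` (patients x signatures), `p`, `significant`
#'   matrices, `included` patients, and a `summary` data.frame (average row
#'   and, when `response` is given, the R - NR row).
#' @export
signature_delta_matrix <- function(scores, cell_meta, response = NULL,
                                   params = composition_params(),
                                   p_threshold = 0.05) {
  pats <- unique(cell_meta$patient)
  eligible <- vapply(pats, function(p)
    sum(cell_meta$patient == p & cell_meta$timepoint == "pre") >=
      params$min_cells_score_test &&
      sum(cell_meta$patient == p & cell_meta$timepoint == "post") >=
      params$min_cells_score_test, TRUE)
  pats <- pats[eligible]
  sig_names <- colnames(scores)
  delta <- p <- matrix(NA_real_, length(pats), length(sig_names),
                       dimnames = list(pats, sig_names))
  for (pa in pats) for (sg in sig_names) {
    a <- scores[cell_meta$patient == pa & cell_meta$timepoint == "post", sg]
    b <- scores[cell_meta$patient == pa & cell_meta$timepoint == "pre", sg]
    delta[pa, sg] <- mean(a) - mean(b)
    p[pa, sg] <- if (stats::sd(c(a, b)) == 0) 1 else
      stats::t.test(a, b)$p.value
  }
  if (params$fc_scale == "log2") {
    fc_ok <- abs(delta) > log2(params$fc_significance_floor)
  } else {
    ## shift scores to be positive before forming the ratio of means
    fc_ok <- delta
    for (pa in pats) for (sg in sig_names) {
      a <- scores[cell_meta$patient == pa & cell_meta$timepoint == "post", sg]
      b <- scores[cell_meta$patient == pa & cell_meta$timepoint == "pre", sg]
      off <- min(c(a, b)); off <- if (off < 0) -off + 1e-6 else 0
      r <- (mean(a) + off + 1e-12) / (mean(b) + off + 1e-12)
      fc_ok[pa, sg] <- max(r, 1 / r) > params$fc_significance_floor
    }
    fc_ok <- fc_ok > 0
  }
  significant <- p < p_threshold & fc_ok
  summary <- data.frame(signature = sig_names,
                        average_delta = colMeans(delta),
                        stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(response)) {
    rr <- response[pats]
    summary$r_minus_nr <- colMeans(delta[rr == "R", , drop = FALSE]) -
      colMeans(delta[rr == "NR", , drop = FALSE])
  }
  list(delta = delta, p = p, significant = significant,
       included = pats, summary = summary)
}

#' Genes recurrently differentially expressed across patients
#'
#' Per patient, a gene is significant when `p < de_p` and `|log2FC| >=
#' de_abs_log2fc`; a gene is recurrent when it is significant with a
#' consistent direction in at least `recurrence_fraction` of patients.
#'
#' @param de_list named list (per patient) of data.frames with columns
#'   `gene`, `log2fc`, `p` (see [differential_expression()]).
#' @param params a [composition_params()].
#' @return data.frame per gene: `n_up`, `n_down`, `n_patients`,
#'   `direction` ("up"/"down"/NA), `recurrent`.
#' @export
recurrent_de <- function(de_list, params = composition_params()) {
  n_pat <- length(de_list)
  genes <- unique(unlist(lapply(de_list, `[[`, "gene")))
  n_up <- n_down <- stats::setNames(integer(length(genes)), genes)
  for (de in de_list) {
    sig <- de$p < params$de_p & abs(de$log2fc) >= params$de_abs_log2fc
    up <- de$gene[sig & de$log2fc > 0]
    dn <- de$gene[sig & de$log2fc < 0]
    n_up[up] <- n_up[up] + 1L
    n_down[dn] <- n_down[dn] + 1L
  }
  need <- params$recurrence_fraction * n_pat
  rec_up <- n_up >= need; rec_dn <- n_down >= need
  direction <- ifelse(rec_up & !rec_dn, "up",
                      ifelse(rec_dn & !rec_up, "down", NA))
  data.frame(gene = genes, n_up = as.integer(n_up),
             n_down = as.integer(n_down), n_patients = n_pat,
             direction = direction,
             recurrent = !is.na(direction),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' One-sample t-test of paired deltas against zero
#'
#' @param deltas numeric vector of per-sample paired differences (e.g.
#'   post - pre log2 expression of a gene set).
#' @return list with `mean`, `t`, `df`, `p`, `n`, `zero_variance`.
#' @export
one_sample_shift_test <- function(deltas) {
  stop_if_not(length(deltas) >= 3, "need at least 3 paired deltas")
  if (stats::sd(deltas) == 0)
    return(list(mean = mean(deltas), t = NA_real_, df = length(deltas) - 1L,
                p = 1, n = length(deltas), zero_variance = TRUE))
  tt <- stats::t.test(deltas, mu = 0)
  list(mean = mean(deltas), t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value, n = length(deltas),
       zero_variance = FALSE)
}
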