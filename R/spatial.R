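## ---------------------------------------------------------------------------
## Multiplexed-imaging cell tables: CLR normalization, two-pass rule gating,
## HLA-DR positivity, radius-neighborhood statistics.
## ---------------------------------------------------------------------------

#' Construct a spatial cell table
#'
#' @param df data.frame with columns `cell_id`, `x`, `y` (pixel
#'   coordinates) and one raw mean-intensity column per marker (8-bit
#'   scale).
#' @param markers marker column names.
#' @param resolution_um_per_px image resolution in micrometers per pixel.
#' @return `df` with class `spatial_cell_table` and the resolution and
#'   marker set stored in attributes.
#' @export
spatial_cell_table <- function(df, markers, resolution_um_per_px = 0.5) {
  stop_if_not(resolution_um_per_px > 0, "resolution must be positive")
  stop_if_not(all(c("cell_id", "x", "y") %in% names(df)),
              "df needs cell_id, x, y columns")
  stop_if_not(all(is.finite(df$x)) && all(is.finite(df$y)),
              "coordinates must be finite")
  stop_if_not(all(markers %in% names(df)), "missing marker column(s)")
  stop_if_not(all(as.matrix(df[markers]) >= 0), "raw intensities must be >= 0")
  structure(df, markers = markers,
            resolution_um_per_px = resolution_um_per_px,
            class = c("spatial_cell_table", "data.frame"))
}

#' Centered log-ratio normalization of marker intensities
#'
#' Per marker (within the image), `CLR[c] = log((x[c] + 1) /
#' geometric_mean(x + 1))` with a pseudocount of 1 on the 8-bit intensity
#' scale, so true zeros stay meaningful. Markers constant at zero give CLR
#' 0 for every cell and are flagged. The log base defaults to natural log;
#' `base = 2` is available since the printed gate values are ambiguous
#' about the base.
#'
#' @param table a [spatial_cell_table()].
#' @param base logarithm base.
#' @return the table with added `clr_<marker>` columns; flagged constant
#'   markers in `attr(, "constant_markers")`.
#' @export
clr_normalize <- function(table, base = exp(1)) {
  markers <- attr(table, "markers")
  const <- character()
  for (m in markers) {
    x <- table[[m]] + 1
    clr <- log(x, base) - mean(log(x, base))
    if (all(table[[m]] == 0)) { clr[] <- 0; const <- c(const, m) }
    table[[paste0("clr_", m)]] <- clr
  }
  attr(table, "constant_markers") <- const
  table
}

clr_matrix <- function(table) {
  markers <- attr(table, "markers")
  cols <- paste0("clr_", markers)
  stop_if_not(all(cols %in% names(table)), "run clr_normalize() first")
  m <- as.matrix(as.data.frame(table)[cols])
  colnames(m) <- markers
  m
}

#' Default two-pass gating rules
#'
#' Reads the packaged hierarchical gate definitions (hand-gated CLR cutoffs
#' for Treg, CD8/CD4 T cells, NK, macrophage, B, tumor and stroma, plus the
#' stricter second-pass lymphoid rules with CD8/CD4 ratio and
#' second-marker requirements) from a JSON file, so the rules are data, not
#' code.
#'
#' @param path optional path to an alternative rules JSON.
#' @return a gate rule set (list with `pass1`, `pass2`, `fallback`).
#' @export
default_gate_rules <- function(path = NULL) {
  path <- path %||% system.file("extdata", "codex_gate_rules.json",
                                package = "tumorstates", mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = FALSE)
}

## evaluate one rule (conjunction of CLR predicates, optional any-of block
## and optional intensity-ratio predicate) on all cells
eval_rule <- function(rule, clr, raw) {
  ok <- rep(TRUE, nrow(clr))
  for (pr in rule$all %||% list()) {
    stop_if_not(pr$marker %in% colnames(clr), "missing marker column: %s", pr$marker)
    v <- clr[, pr$marker]
    ok <- ok & (if (pr$op == ">") v > pr$value else v < pr$value)
  }
  if (!is.null(rule$any)) {
    any_ok <- rep(FALSE, nrow(clr))
    for (pr in rule$any) {
      stop_if_not(pr$marker %in% colnames(clr), "missing marker column: %s", pr$marker)
      v <- clr[, pr$marker]
      any_ok <- any_ok | (if (pr$op == ">") v > pr$value else v < pr$value)
    }
    ok <- ok & any_ok
  }
  if (!is.null(rule$ratio)) {
    r <- (raw[, rule$ratio$num] + 1) / (raw[, rule$ratio$den] + 1)
    ok <- ok & (if (rule$ratio$op == ">") r > rule$ratio$value
                else r < rule$ratio$value)
  }
  ok
}

apply_rules <- function(rules, clr, raw, else_label) {
  lab <- rep(NA_character_, nrow(clr))
  for (rule in rules) {
    hit <- is.na(lab) & eval_rule(rule, clr, raw)
    lab[hit] <- rule$phenotype
  }
  lab[is.na(lab)] <- else_label
  lab
}

#' Two-pass hierarchical phenotype gating
#'
#' Pass 1 applies the ordered gate hierarchy (Treg, CD8 T, CD4 T, NK,
#' macrophage, CD4 fallback, B, tumor; everything else is stroma). Cells
#' initially typed as a lymphoid class are re-gated in pass 2 with the
#' stricter criteria (CD8/CD4 intensity ratio, second-T-marker
#' requirements); cells failing all pass-2 rules fall back to the
#' macrophage/tumor/stroma criteria. Every cell receives exactly one
#' label.
#'
#' @param table a CLR-normalized [spatial_cell_table()].
#' @param rules a gate rule set (see [default_gate_rules()]).
#' @return data.frame per cell: `cell_id`, `pass1`, `phenotype`.
#' @export
phenotype_cells <- function(table, rules = default_gate_rules()) {
  clr <- clr_matrix(table)
  raw <- as.matrix(as.data.frame(table)[attr(table, "markers")])
  pass1 <- apply_rules(rules$pass1, clr, raw, rules$else_label %||% "Stroma")
  final <- pass1
  regate <- pass1 %in% unlist(rules$pass2$applies_to)
  if (any(regate)) {
    sub_clr <- clr[regate, , drop = FALSE]
    sub_raw <- raw[regate, , drop = FALSE]
    lab <- rep(NA_character_, sum(regate))
    for (rule in rules$pass2$rules) {
      hit <- is.na(lab) & eval_rule(rule, sub_clr, sub_raw)
      lab[hit] <- rule$phenotype
    }
    ## failures are passed back to the macrophage/tumor/stroma criteria
    fb <- is.na(lab)
    if (any(fb)) {
      fb_rules <- Filter(function(r) r$phenotype %in% unlist(rules$fallback),
                         rules$pass1)
      lab[fb] <- apply_rules(fb_rules, sub_clr[fb, , drop = FALSE],
                             sub_raw[fb, , drop = FALSE],
                             rules$else_label %||% "Stroma")
    }
    final[regate] <- lab
  }
  data.frame(cell_id = table$cell_id, pass1 = pass1, phenotype = final,
             stringsAsFactors = FALSE)
}

#' Call HLA-DR positivity from CLR values
#'
#' A cell is HLA-DR positive when its CLR strictly exceeds `threshold`.
#' When phenotypes are supplied, the positive fraction among tumor cells is
#' reported per sample.
#'
#' @param table a CLR-normalized [spatial_cell_table()].
#' @param phenotype optional per-cell phenotype labels.
#' @param threshold CLR cutoff (strict inequality).
#' @param marker HLA-DR marker name.
#' @param tumor_label phenotype counted as tumor.
#' @return list with `positive` (logical per cell) and, when phenotypes are
#'   given, `tumor_positive_fraction`.
#' @export
call_hladr <- function(table, phenotype = NULL, threshold = 0.5,
                       marker = "HLA-DR", tumor_label = "Tumor") {
  col <- paste0("clr_", marker)
  stop_if_not(col %in% names(table), "run clr_normalize() first")
  pos <- table[[col]] > threshold
  out <- list(positive = pos)
  if (!is.null(phenotype))
    out$tumor_positive_fraction <- mean(pos[phenotype == tumor_label])
  out
}

#' Counts of each phenotype within a radius of every cell
#'
#' Uses a uniform grid spatial index (bin size = radius) so the expected
#' runtime is sub-quadratic; distances are Euclidean between centroids and
#' the cell itself is excluded. The physical radius (`radius_px *
#' resolution`) is recorded in the attributes.
#'
#' @param table a [spatial_cell_table()].
#' @param phenotype per-cell phenotype labels.
#' @param radius_px neighborhood radius in pixels (60 px at 0.5 um/px =
#'   30 um).
#' @return cells x phenotypes count matrix; `attr(, "radius_um")` holds the
#'   physical radius.
#' @export
neighborhood_counts <- function(table, phenotype, radius_px = 60) {
  x <- table$x; y <- table$y
  n <- length(x)
  lev <- sort(unique(phenotype))
  ph <- match(phenotype, lev)
  counts <- matrix(0L, n, length(lev), dimnames = list(table$cell_id, lev))
  gx <- floor(x / radius_px); gy <- floor(y / radius_px)
  key <- paste(gx, gy)
  cells_by_bin <- split(seq_len(n), key)
  r2 <- radius_px^2
  for (i in seq_len(n)) {
    cand <- integer()
    for (dx in -1:1) for (dy in -1:1) {
      k <- paste(gx[i] + dx, gy[i] + dy)
      cand <- c(cand, cells_by_bin[[k]])
    }
    cand <- cand[cand != i]
    if (!length(cand)) next
    d2 <- (x[cand] - x[i])^2 + (y[cand] - y[i])^2
    hit <- cand[d2 <= r2]
    if (length(hit))
      counts[i, ] <- tabulate(ph[hit], nbins = length(lev))
  }
  attr(counts, "radius_px") <- radius_px
  attr(counts, "radius_um") <- radius_px * attr(table, "resolution_um_per_px")
  counts
}

#' Compare neighborhood composition around HLA-DR+ vs HLA-DR- tumor cells
#'
#' For each neighbor phenotype, the mean neighbor count around HLA-DR
#' positive tumor cells is compared to the mean around negative ones: the
#' ratio and a one-tailed Student's t-test (alternative: positive greater)
#' are reported. Neighbor types where either group has fewer than two cells
#' are skipped.
#'
#' @param counts cells x phenotypes matrix from [neighborhood_counts()].
#' @param hladr_positive logical per cell.
#' @param is_tumor logical per cell restricting the comparison to tumor
#'   cells.
#' @return data.frame per neighbor type: `mean_pos`, `mean_neg`, `ratio`,
#'   `t`, `p`, `skipped`.
#' @export
compare_neighborhoods <- function(counts, hladr_positive, is_tumor) {
  pos <- which(is_tumor & hladr_positive)
  neg <- which(is_tumor & !hladr_positive)
  stop_if_not(length(pos) > 0 && length(neg) > 0,
              "both HLA-DR groups must be nonempty among tumor cells")
  out <- lapply(colnames(counts), function(ty) {
    a <- counts[pos, ty]; b <- counts[neg, ty]
    if (length(a) < 2 || length(b) < 2)
      return(data.frame(neighbor = ty, mean_pos = mean(a), mean_neg = mean(b),
                        ratio = NA, t = NA, p = NA, skipped = TRUE))
    if (stats::sd(a) == 0 && stats::sd(b) == 0)
      return(data.frame(neighbor = ty, mean_pos = mean(a), mean_neg = mean(b),
                        ratio = if (mean(b) > 0) mean(a) / mean(b) else NA,
                        t = 0, p = 0.5, skipped = FALSE))
    tt <- stats::t.test(a, b, alternative = "greater")
    data.frame(neighbor = ty, mean_pos = mean(a), mean_neg = mean(b),
               ratio = if (mean(b) > 0) mean(a) / mean(b) else NA,
               t = unname(tt$statistic), p = tt$p.value, skipped = FALSE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
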