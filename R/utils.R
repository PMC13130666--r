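#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific seed from a global seed
#'
#' Stages of the pipeline draw their random numbers from seeds derived from a
#' single global seed plus a stage counter, so each stage is individually
#' reproducible. The derived seed always stays inside the 32-bit integer
#' range.
#'
#' @param seed integer global seed.
#' @param stage integer stage counter (0, 1, 2, ...).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stage = 0L) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(stage) * 104729) %% 2147483629)
}

## run `expr` under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

stop_if_not <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}

## centered moving average over the rows of `x` (genes x cells), window
## truncated (shrunk) at the edges so every row keeps a value.
running_mean_rows <- function(x, window) {
  n <- nrow(x)
  if (n == 0L) return(x)
  half <- floor(window / 2)
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(lo + window - 1L, n)
  lo <- pmax(hi - window + 1L, 1L)
  cs <- apply(x, 2, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, ncol = ncol(x))
  top <- cs[hi, , drop = FALSE]
  bot <- rbind(0, cs)[lo, , drop = FALSE]
  sweep(top - bot, 1, hi - lo + 1, "/")
}

## vectorised Welch / pooled two-sample t-test across the rows of two matrices
row_t_test <- function(a, b, var_equal = FALSE) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  if (var_equal) {
    sp <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(ma))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- (ma - mb) / se
  p <- 2 * stats::pt(-abs(t), df)
  zero_var <- va + vb == 0
  t[zero_var] <- 0
  p[zero_var] <- 1
  list(mean_a = ma, mean_b = mb, t = t, df = df, p = p, zero_var = zero_var)
}

## md5 hash of an R object via its JSON serialisation (used in run manifests)
params_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE), f)
  unname(tools::md5sum(f))
}
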