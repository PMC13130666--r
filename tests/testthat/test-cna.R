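## normalized matrix on one toy chromosome with explicit roles
toy_norm <- function(values, arm = NULL) {
  ng <- nrow(values)
  gm <- data.frame(symbol = paste0("g", seq_len(ng)), chromosome = "chr1",
                   arm = arm %||% rep("p", ng), order = seq_len(ng))
  cm <- data.frame(cell_id = paste0("c", seq_len(ncol(values))),
                   patient = "P01")
  rownames(values) <- gm$symbol
  normalized_matrix(values, gm, cm, centered = TRUE)
}

test_that("an all-zero centered matrix yields an all-zero CNA matrix", {
  v <- matrix(0, 150, 30)
  roles <- rep(c("epithelial", "fibroblast"), c(15, 15))
  ws <- infer_cna_profiles(toy_norm(v), roles, cna_params(window = 50))
  expect_true(all(ws$cna == 0))
})

test_that("moving-average smoothing matches the hand-computed block oracle", {
  ## 300-gene chromosome, +2 planted on genes 51-250 (200 consecutive),
  ## stromal references flat at a +0.5 noise ceiling
  ng <- 300
  n_epi <- 12; n_str <- 12
  v <- cbind(matrix(0, ng, n_epi), matrix(0.5, ng, n_str))
  v[51:250, seq_len(n_epi)] <- 2
  roles <- rep(c("epithelial", "fibroblast"), c(n_epi, n_str))
  ws <- infer_cna_profiles(toy_norm(v), roles, cna_params(),
                           gene_center = FALSE, cell_center = FALSE)
  ## interior of the block: the 100-gene window sits fully inside -> 2,
  ## adjusted by the stromal ceiling to 1.5
  interior <- 101:200
  expect_equal(unname(ws$cna[interior, 1]), rep(1.5, length(interior)))
  ## independent running-mean oracle for one epithelial column
  x <- v[, 1]
  oracle <- vapply(seq_len(ng), function(i) {
    half <- 50; lo <- max(i - half, 1); hi <- min(lo + 99, ng); lo <- max(hi - 99, 1)
    mean(x[lo:hi])
  }, 0)
  adj <- ifelse(oracle > 0.5, oracle - 0.5, ifelse(oracle < 0.5, oracle - 0.5, 0))
  adj[abs(adj) <= 0.15] <- 0
  expect_equal(unname(ws$cna[, 1]), adj)
})

test_that("adjusted values inside the denoising band are zeroed", {
  ng <- 120
  v <- cbind(matrix(0.10, ng, 10), matrix(0, ng, 10))
  roles <- rep(c("epithelial", "fibroblast"), c(10, 10))
  ws <- infer_cna_profiles(toy_norm(v), roles, cna_params(window = 40),
                           gene_center = FALSE, cell_center = FALSE)
  expect_true(all(ws$cna == 0))
  ## and the workspace invariant: values are 0 or beyond the band
  fx <- fx_cna2()
  nz <- fx$cna[fx$cna != 0]
  expect_true(all(abs(nz) > cna_params()$denoise_band))
})

test_that("smoothing is linear: doubling the input doubles window values", {
  set.seed(5)
  v <- matrix(rnorm(200 * 20, sd = 0.2), 200, 20)
  roles <- rep(c("epithelial", "fibroblast"), c(10, 10))
  p <- cna_params(window = 50, denoise_band = 1e-9)
  w1 <- infer_cna_profiles(toy_norm(v), roles, p,
                           gene_center = FALSE, cell_center = FALSE)
  ## with references scaled too, the band-adjusted values double as well
  w2 <- infer_cna_profiles(toy_norm(2 * v), roles, p,
                           gene_center = FALSE, cell_center = FALSE)
  expect_equal(w2$cna, 2 * w1$cna, tolerance = 1e-10)
})

test_that("CNA signal and correlation match small-instance oracles", {
  set.seed(6)
  m <- matrix(rnorm(9 * 6), 9, 6)
  ws <- structure(list(cna = m, role = rep(c("epithelial", "fibroblast"), c(4, 2)),
                       cell_meta = data.frame(patient = rep("P01", 6)),
                       gene_meta = data.frame(chromosome = "chr1", arm = "p",
                                              order = 1:9),
                       params = cna_params()),
                  class = "cna_workspace")
  out <- compute_cna_scores(ws)
  n_top <- ceiling(2 / 3 * 9)
  oracle <- apply(abs(m), 2, function(a) mean(sort(a, decreasing = TRUE)[1:n_top]))
  expect_equal(out$signal, oracle)
  ## a cell with |CNA| = 1 everywhere has signal exactly 1
  ws$cna[, 1] <- (-1)^(1:9)
  expect_equal(compute_cna_scores(ws)$signal[1], 1)
  ## correlation of the profile equal to the hot-cell mean is 1
  hot <- order(oracle[1:4], decreasing = TRUE)[1]
  prof_cells <- which(out$role == "epithelial")[hot]
  expect_equal(out$correlation[prof_cells], 1)
  ## constant profiles are flagged and set to zero
  ws2 <- ws; ws2$cna[, 2] <- 0
  out2 <- compute_cna_scores(ws2)
  expect_true(out2$correlation_flag[2])
  expect_equal(out2$correlation[2], 0)
})

test_that("clusters with identical events merge only below the mean-difference cap", {
  arms <- rep(c("chr1p", "chr1q"), each = 40)
  base <- c(rep(0.5, 40), rep(0, 40))
  ## clusters A and B share the chr1p gain but differ by 0.2 in its mean
  mA <- matrix(rep(base, 12), ncol = 12)
  mB <- matrix(rep(base + c(rep(0.2, 40), rep(0, 40)), 12), ncol = 12)
  m <- cbind(mA, mB)
  cl <- rep(c(1L, 2L), each = 12)
  p <- cna_params()
  out <- tumorstates:::merge_clusters_by_events(cl, m, arms, p)
  expect_equal(length(unique(out)), 2)   # 0.2 >= 0.15: kept apart
  ## at 0.1 difference they merge
  mB2 <- matrix(rep(base + c(rep(0.1, 40), rep(0, 40)), 12), ncol = 12)
  out2 <- tumorstates:::merge_clusters_by_events(cl, cbind(mA, mB2), arms, p)
  expect_equal(length(unique(out2)), 1)
})

test_that("malignancy calls obey the two-threshold rule and stromal bound", {
  ws <- fx_cna2()
  thr <- ws$thresholds
  ## strictly fewer than 1% of stromal cells exceed every chosen cutoff
  expect_true(all(thr$stromal_exceed_signal < 0.01))
  expect_true(all(thr$stromal_exceed_correlation < 0.01))
  ## calls are consistent with the per-subclone thresholds
  for (k in sample(nrow(thr), min(4, nrow(thr)))) {
    members <- which(!is.na(ws$subclone) & ws$subclone == thr$subclone[k])
    above_sig <- ws$signal[members] > thr$signal_cutoff[k]
    call <- ws$call[members]
    expect_true(all(call[!above_sig] %in% c("non_malignant", "unresolved")))
    expect_true(all(call[above_sig] %in% c("malignant", "unresolved")))
  }
  ## stromal cells have no malignancy call
  expect_true(all(is.na(ws$call[ws$role != "epithelial"])))
})

test_that("subclone recovery and malignancy accuracy hold on the shared cohort", {
  ws <- fx_cna2()
  fx <- fx_cohort2()
  tr <- fx$truth[match(ws$cell_meta$cell_id, fx$truth$cell_id), ]
  epi <- which(ws$role == "epithelial")
  acc <- mean((ws$call[epi] == "malignant") == tr$malignant[epi])
  expect_gte(acc, 0.95)
  expect_true(all(count_malignant_subclones(ws) == 2))
})

test_that("chi-square links subclones to timepoints as constructed", {
  ## identical composition pre/post: independence
  sub <- rep(c("s1", "s2"), each = 40)
  tp <- rep(c("pre", "post"), 40)
  r <- subclone_timepoint_association(sub, tp, rep("P1", 80))
  expect_gt(r$p, 0.9)
  ## a post-exclusive subclone at n = 20 per group is significant
  sub2 <- rep(c("s1", "s2"), each = 20)
  tp2 <- rep(c("pre", "post"), each = 20)
  r2 <- subclone_timepoint_association(sub2, tp2, rep("P1", 40))
  expect_lt(r2$p, 0.05)
  ## hand-computed 2x2 oracle: [[10,0],[0,10]] -> chi2 = 20 uncorrected
  sub3 <- rep(c("a", "b"), each = 10)
  tp3 <- rep(c("pre", "post"), each = 10)
  r3 <- subclone_timepoint_association(sub3, tp3, rep("P1", 20))
  expect_equal(r3$chi2, 20)
})
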