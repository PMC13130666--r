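test_that("reference construction enforces type, stratum and gene rules", {
  set.seed(1)
  ng <- 120
  n_a <- 120; n_b <- 99; n_c <- 110   # per-type cell counts
  counts <- matrix(rpois(ng * (n_a + n_b + n_c), 5), ng)
  rownames(counts) <- paste0("g", 1:ng)
  colnames(counts) <- paste0("c", 1:ncol(counts))
  cm <- data.frame(cell_id = colnames(counts), patient = "P1",
                   timepoint = "pre", platform = "5prime", tcr = FALSE,
                   sample = rep(c("S1", "S2"), length.out = ncol(counts)))
  gm <- data.frame(symbol = rownames(counts), chromosome = "chr1", arm = "p",
                   order = 1:ng, mito = FALSE)
  ac <- annotated_counts(counts, cm, gm)
  ty <- rep(c("typeA", "typeB", "typeC"), c(n_a, n_b, n_c))
  bulk <- matrix(rpois(ng * 10, 20), ng, 10, dimnames = list(rownames(counts), NULL))
  bulk["g5", ] <- 0; bulk["g5", 1:4] <- 3   # detected in only 4 bulk samples
  p <- reference_matrix_params(min_cells_per_type = 100,
                               max_cells_per_sample_type = 50)
  ref <- build_reference(ac, ty, bulk, p)
  ## typeB (99 < 100) is dropped, typeA and typeC retained
  expect_setequal(colnames(ref$centroids), c("typeA", "typeC"))
  ## 60 cells of a type in one stratum are downsampled to 50
  expect_true(all(table(ref$cell_type,
                        cm$sample[match(ref$cells, cm$cell_id)]) <= 50))
  ## the gene present in only 4 bulk samples is dropped
  expect_false("g5" %in% ref$genes)
  ## dendritic subtypes merge into one DC category
  ty2 <- ty; ty2[1:120] <- rep(c("pDC", "cDC"), 60)
  ref2 <- build_reference(ac, ty2, bulk, p)
  expect_true("DC" %in% colnames(ref2$centroids))
})

test_that("NNLS inverts noiseless mixtures and handles degenerate input", {
  set.seed(2)
  ng <- 200
  A <- matrix(rexp(ng * 3), ng, 3, dimnames = list(paste0("g", 1:ng),
                                                   c("t1", "t2", "malignant")))
  A <- sweep(A, 2, colSums(A), "/") * 1e6
  fr <- c(0.5, 0.3, 0.2)
  bulk <- A %*% fr * 3
  colnames(bulk) <- "s1"
  est <- estimate_fractions(bulk, A)
  expect_equal(as.numeric(est$fractions), fr, tolerance = 1e-6)
  expect_equal(unname(est$purity), 0.2, tolerance = 1e-6)
  ## a pure centroid returns fraction one for that type
  pure <- estimate_fractions(matrix(A[, 2], dimnames = list(rownames(A), "s")), A)
  expect_equal(as.numeric(pure$fractions), c(0, 1, 0), tolerance = 1e-6)
  expect_error(estimate_fractions(matrix(0, ng, 1,
                                         dimnames = list(rownames(A), "z")), A),
               "all-zero")
  ## a precomputed fraction table passes straight through the adapter
  ext <- matrix(c(0.6, 0.4, 0), 1, dimnames = list("s1", colnames(A)))
  est2 <- estimate_fractions(bulk, A, method = ext)
  expect_equal(as.numeric(est2$fractions), c(0.6, 0.4, 0))
})

test_that("residual adjustment removes confounders exactly and is orthogonal", {
  set.seed(3)
  n <- 40
  conf <- cbind(mac = runif(n), tc = runif(n))
  ## a score exactly linear in the confounder leaves ~zero residuals
  s1 <- 2 + 3 * conf[, "mac"]
  expect_lt(max(abs(residual_adjust(s1, conf))), 1e-10)
  ## an independent score returns itself, centered
  s2 <- rnorm(n)
  r2 <- residual_adjust(s2, conf)
  expect_gt(cor(r2, s2), 0.9)
  expect_lt(max(abs(crossprod(scale(conf, scale = FALSE), r2))), 1e-8)
  expect_warning(residual_adjust(s2, cbind(conf, conf[, 1])), "collinear")
})

test_that("malignant profile adjustment inverts noiseless bulk mixtures", {
  set.seed(4)
  ng <- 150
  genes <- paste0("g", 1:ng)
  cen <- matrix(rexp(ng * 3), ng, 3,
                dimnames = list(genes, c("macrophage", "T_CD8", "malignant")))
  cen <- sweep(cen, 2, colSums(cen), "/") * 1e6
  fr <- rbind(s1 = c(0.3, 0.2, 0.5), s2 = c(0.1, 0.1, 0.8))
  colnames(fr) <- colnames(cen)
  bulk <- cen %*% t(fr)
  out <- malignant_profile_adjust(bulk, cen, fr, purity = fr[, "malignant"],
                                  confounder_types = c("macrophage", "T_CD8"))
  expect_equal(out$adjusted, cen[, c("malignant", "malignant")],
               tolerance = 1e-6, ignore_attr = TRUE)
  ## purity one and no immune contribution: adjusted equals the bulk CPM
  fr1 <- rbind(s = c(0, 0, 1)); colnames(fr1) <- colnames(cen)
  b1 <- cen %*% t(fr1)
  out1 <- malignant_profile_adjust(b1, cen, fr1, purity = 1,
                                   confounder_types = c("macrophage", "T_CD8"))
  expect_equal(unname(out1$adjusted[, 1]), unname(b1[, 1]), tolerance = 1e-6)
  ## purity 0.5 doubles the residual malignant signal
  fr2 <- rbind(s = c(0.3, 0.2, 0.5)); colnames(fr2) <- colnames(cen)
  b2 <- cen %*% t(fr2)
  out2 <- malignant_profile_adjust(b2, cen, fr2, purity = 0.5,
                                   confounder_types = c("macrophage", "T_CD8"))
  expect_equal(unname(out2$adjusted[, 1]), unname(cen[, "malignant"]),
               tolerance = 1e-6)
  ## low purity flagged
  out3 <- malignant_profile_adjust(b2, cen, fr2, purity = 0.04,
                                   confounder_types = "macrophage")
  expect_equal(out3$unreliable, "s")
})

test_that("ROC AUC equals brute-force pair counting and the midrank U statistic", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 1, 0, 1))$auc, 0.75)
  set.seed(5)
  for (i in 1:25) {
    n <- sample(5:50, 1)
    s <- sample(1:20, n, replace = TRUE)   # ties on purpose
    l <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(l) || all(l)) next
    pairs <- outer(s[l], s[!l], function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(roc_auc(s, l)$auc, mean(pairs))
  }
  ## labels independent of scores: AUC near 1/2
  s <- rnorm(1000); l <- sample(c(TRUE, FALSE), 1000, TRUE)
  expect_lt(abs(roc_auc(s, l)$auc - 0.5), 0.05)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(6)
  for (i in 1:10) {
    s <- rnorm(60)
    l <- rbinom(60, 1, 0.4)
    if (!any(l == 1) || !any(l == 0)) next
    ref <- as.numeric(suppressMessages(pROC::auc(l, s, direction = "<")))
    expect_equal(roc_auc(s, l)$auc, ref, tolerance = 1e-12)
  }
})

test_that("predictor comparison surfaces the informative feature", {
  set.seed(7)
  n <- 40
  y <- rbinom(n, 1, 0.5)
  f <- cbind(signal = y + rnorm(n, 0, 0.4),
             noise1 = rnorm(n), noise2 = rnorm(n))
  out <- predictor_comparison(f, y)
  expect_equal(names(which.max(out$auc)), "signal")
  expect_lt(out$model$p[out$model$feature == "signal"], 0.05)
  ## a feature equal to the label dominates completely
  out2 <- suppressWarnings(   # a perfect fit makes lm's summary complain
    predictor_comparison(cbind(exact = y, noise = rnorm(n)), y))
  expect_equal(unname(out2$auc["exact"]), 1)
  suppressWarnings(
    expect_warning(predictor_comparison(cbind(a = y, b = y, c = rnorm(n)), y),
                   "collinear"))
  expect_error(predictor_comparison(matrix(rnorm(8), 2), c(0, 1)), "features")
})

test_that("the adjusted malignant score beats the T fraction across replicates", {
  ## end-to-end benchmark: +1 sd responder effect on malignant IFN/MHC-II
  ## activity with a +0.5 sd T-cell-fraction confounder; 100-patient bulk
  ## cohorts give the AUC comparison adequate power
  wins <- vapply(1:50, function(seed) {
    cfg <- sim_config(n_genes = 2000, seed = seed,
                      bulk = list(n_patients = 100L, n_responders = 33L,
                                  n_paired = 0L))
    bk <- simulate_bulk_cohort(cfg)
    ctr <- bk$truth$centroids
    ctr <- sweep(ctr, 2, colSums(ctr), "/") * 1e6
    est <- estimate_fractions(bk$bulk, ctr)
    prof <- malignant_profile_adjust(bk$bulk, ctr, est$fractions,
                                     pmax(est$purity, 0.05))
    ifn <- intersect(default_program_spec()$IFN_MHC2$genes,
                     rownames(prof$adjusted_log))
    score <- colMeans(prof$adjusted_log[ifn, ])
    tfr <- rowSums(est$fractions[, c("T_CD8", "T_helper", "T_reg", "NK")])
    lab <- bk$bulk$sample_meta$response == "R"
    roc_auc(score, lab)$auc > roc_auc(tfr, lab)$auc
  }, TRUE)
  expect_gte(mean(wins), 0.9)
})
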