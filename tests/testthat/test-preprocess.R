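## build a cell column with a prescribed number of detected genes and a
## prescribed mitochondrial count share
make_cell <- function(n_genes_total, n_detected, mito_umis = 0) {
  x <- integer(n_genes_total)
  if (n_detected > 0) x[seq_len(n_detected)] <- 2L
  x[n_genes_total] <- mito_umis   # last gene is mitochondrial
  x
}

test_that("QC thresholds follow lineage and mitochondrial rules", {
  ng <- 1500
  counts <- cbind(
    a = make_cell(ng, 999),    # non-lymphoid, below 1000 genes -> removed
    b = make_cell(ng, 1000),   # non-lymphoid at threshold -> kept
    c = make_cell(ng, 500),    # lymphoid at threshold -> kept
    d = make_cell(ng, 499),    # lymphoid below 500 -> removed
    e = make_cell(ng, 1200, mito_umis = 630),  # ~21% mito -> removed
    f = make_cell(ng, 1200, mito_umis = 480))  # ~17% mito -> kept
  ac <- toy_counts(counts, mito = 1500)
  lineage <- c("non_lymphoid", "non_lymphoid", "lymphoid", "lymphoid",
               "non_lymphoid", "non_lymphoid")
  out <- qc_filter_cells(ac, lineage)
  expect_setequal(out$cell_meta$cell_id, c("b", "c", "f"))
  log <- attr(out, "qc_log")
  expect_equal(log$removed_reason[log$cell_id == "a"], "low_gene_count")
  expect_equal(log$removed_reason[log$cell_id == "e"], "high_mito")
  expect_error(qc_filter_cells(ac, c(lineage[-1], NA)), "missing lineage")
})

test_that("QC filter matches a brute-force oracle on a random fixture", {
  set.seed(1)
  ng <- 1200
  counts <- sapply(1:200, function(i)
    make_cell(ng, sample(300:1200, 1), sample(0:400, 1)))
  ac <- toy_counts(counts, mito = ng)
  lineage <- sample(c("lymphoid", "non_lymphoid"), 200, TRUE)
  p <- qc_params()
  out <- qc_filter_cells(ac, lineage, p)
  ngene <- ac$cell_meta$n_genes_detected
  mito <- ac$cell_meta$mito_fraction
  keep_oracle <- ifelse(lineage == "lymphoid",
                        ngene >= p$min_genes_lymphoid,
                        ngene >= p$min_genes_nonlymphoid) &
    mito <= p$max_mito
  expect_identical(out$cell_meta$cell_id, ac$cell_meta$cell_id[keep_oracle])
})

test_that("gene filter applies the mean-expression OR prevalence rule", {
  set.seed(2)
  n_cells <- 60
  base <- matrix(rpois(20 * n_cells, 40), 20, n_cells)  # high background
  g_prev <- integer(n_cells); g_prev[1:20] <- 5L        # 5 UMIs in exactly 20 cells
  g_prev19 <- integer(n_cells); g_prev19[1:19] <- 5L    # one cell short
  g_zero <- integer(n_cells)
  g_dense <- rep(2L, n_cells)                           # low counts, every cell
  counts <- rbind(base, g_prev, g_prev19, g_zero, g_dense)
  ac <- toy_counts(counts)
  tot <- colSums(counts)
  dense_mean <- mean(log2(g_dense / tot * 1e6 + 1))
  out <- filter_genes(ac)
  kept <- out$gene_meta$symbol
  expect_true("g_prev" %in% kept)
  expect_false("g_prev19" %in% kept)
  expect_false("g_zero" %in% kept)
  ## the dense gene passes through the mean criterion alone
  expect_gte(dense_mean, 4)
  expect_true("g_dense" %in% kept)
})

test_that("log2(CPM/10+1) normalization matches closed forms and centers", {
  counts <- matrix(0L, 3, 2, dimnames = list(c("g1", "g2", "g3"), c("a", "b")))
  counts["g1", "a"] <- 10L; counts["g2", "a"] <- 99990L
  counts["g1", "b"] <- 50L; counts["g2", "b"] <- 99950L
  ac <- toy_counts(counts)
  norm <- normalize_log2cpm(ac, center = FALSE)
  ## 10 UMIs of 100,000 -> CPM 100 -> log2(100/10 + 1) = log2(11)
  expect_equal(norm$values["g1", "a"], log2(11))
  expect_equal(norm$values["g3", "a"], 0)   # zero count -> 0
  cen <- normalize_log2cpm(ac, center = TRUE)
  expect_true(all(abs(rowMeans(cen$values)) < 1e-8))
  ## centering is idempotent
  again <- cen$values - rowMeans(cen$values)
  expect_equal(again, cen$values, tolerance = 1e-12)
  counts[, "a"] <- 0L
  expect_error(normalize_log2cpm(toy_counts(counts)), "zero total")
})

test_that("platform centering removes planted 3' offsets per patient", {
  set.seed(3)
  ng <- 50
  v <- matrix(rnorm(ng * 80), ng, dimnames = list(paste0("g", 1:ng), NULL))
  cm <- data.frame(cell_id = paste0("c", 1:80),
                   patient = rep(c("P1", "P2"), each = 40),
                   platform = rep(rep(c("3prime", "5prime"), each = 20), 2))
  delta1 <- rnorm(ng, 2, 0.1); delta2 <- rnorm(ng, -1, 0.1)
  v[, 1:20] <- v[, 1:20] + delta1        # P1 3' offset
  v[, 41:60] <- v[, 41:60] + delta2      # P2 3' offset, different
  norm <- normalized_matrix(v, cell_meta = cm)
  out <- batch_correct_platform(norm, rep("T", 80))
  for (pat in c("P1", "P2")) {
    i3 <- cm$patient == pat & cm$platform == "3prime"
    i5 <- cm$patient == pat & cm$platform == "5prime"
    expect_lt(max(abs(rowMeans(out$values[, i3]) - rowMeans(out$values[, i5]))),
              1e-8)
  }
  ## 5' cells are untouched, bit for bit
  expect_identical(out$values[, cm$platform == "5prime"],
                   v[, cm$platform == "5prime"])
  ## patient with a single platform stays unchanged
  cm2 <- cm; cm2$platform[cm2$patient == "P2"] <- "5prime"
  out2 <- batch_correct_platform(normalized_matrix(v, cell_meta = cm2),
                                 rep("T", 80))
  expect_identical(out2$values[, cm2$patient == "P2"],
                   v[, cm2$patient == "P2"])
})

test_that("differential expression handles null, planted and degenerate genes", {
  set.seed(4)
  v <- matrix(rnorm(100 * 60), 100, 60,
              dimnames = list(paste0("g", 1:100), NULL))
  grp <- rep(c("A", "B"), each = 30)
  ## identical groups: zero fold changes, q-values 1
  null_de <- differential_expression(cbind(v[, 1:30], v[, 1:30]), grp)
  expect_true(all(null_de$log2fc == 0))
  expect_true(all(null_de$q == 1))
  ## a planted 1-log2 shift is the top hit
  v2 <- v; v2["g7", grp == "A"] <- v2["g7", grp == "A"] + 2
  v2["g50", ] <- 5   # zero variance in both groups
  de <- differential_expression(v2, grp)
  expect_equal(de$gene[which.min(de$q)], "g7")
  expect_true(de$zero_variance[de$gene == "g50"])
  expect_equal(de$p[de$gene == "g50"], 1)
  expect_error(differential_expression(v[, 1:3], c("A", "A", "B")), "2 cells")
})

test_that("cluster-based typing resolves simulated types and flags rule breakers", {
  fx <- fx_cohort2()
  ct <- assign_cell_types(fx$norm, cluster_k = 25, seed = 1)
  truth_type <- fx$truth$type
  truth_type[truth_type == "malignant"] <- "epithelial_normal"
  tnk <- c("T_CD8", "T_helper", "T_reg", "NK")
  ok <- !ct$unresolved
  hit <- ct$type[ok] == truth_type[ok] |
    (ct$type[ok] %in% tnk & truth_type[ok] %in% tnk)
  expect_gte(mean(hit), 0.9)
  expect_lt(mean(ct$unresolved), 0.35)

  ## rule (a): every TCR+ cell in a non-T/NK cluster is unresolved
  tcr <- fx$norm$cell_meta$tcr
  in_tnk <- ct$cluster_type %in% tnk
  expect_true(all(ct$unresolved[tcr & !in_tnk]))
  ## rule (c) only fires when the margin is below 1.15x and discordant
  amb <- which(ct$unresolved_reason == "ambiguous_second_discordant")
  if (length(amb))
    expect_true(all(ct$top_score[amb] < 1.15 * ct$second_score[amb]))
  ## fibroblast top scores inside epithelial clusters are retained
  fib_in_epi <- ct$top_type == "fibroblast" &
    ct$cluster_type == "epithelial_normal" & !tcr
  expect_false(any(ct$unresolved_reason[fib_in_epi] %in% "top_score_discordant"))
  expect_error(assign_cell_types(fx$norm, marker_sets = list(a = character())),
               "empty marker set")
})
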