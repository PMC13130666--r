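test_that("simulation is byte-identical under a fixed seed", {
  cfg <- sim_config(n_patients = 1, cells_per_sample = 60, n_genes = 600,
                    seed = 9)
  a <- simulate_single_cell_cohort(cfg)
  b <- simulate_single_cell_cohort(cfg)
  expect_identical(as.matrix(a$counts$counts), as.matrix(b$counts$counts))
  expect_identical(a$truth, b$truth)
  sa <- simulate_spatial_table(cfg)
  sb <- simulate_spatial_table(cfg)
  expect_identical(sa$table, sb$table)
})

test_that("config validation rejects inconsistent settings", {
  expect_error(sim_config(malignant_fraction = 1.2), "malignant_fraction")
  expect_error(sim_config(n_genes = 100), "reserved")
  ps <- default_program_spec()
  ps$IFN_MHC2$genes[1] <- "CD3D"   # collides with a marker gene
  expect_error(sim_config(program_spec = ps), "disjoint")
  bad <- default_cna_blocks(); bad$amplitude[1] <- Inf
  expect_error(sim_config(cna_block_spec = bad), "finite")
})

test_that("without CNA blocks malignant and stromal cells share mean profiles", {
  cfg <- sim_config(n_patients = 1, cells_per_sample = 1200, n_genes = 600,
                    cna_block_spec = default_cna_blocks()[0, ],
                    subclones_per_patient = 1, malignant_fraction = 0.5,
                    program_spec = list(), seed = 3)
  sim <- simulate_single_cell_cohort(cfg)
  cnt <- as.matrix(sim$counts$counts)
  ## library-normalize so profiles are comparable, keep filler genes only
  cpm <- sweep(cnt, 2, colSums(cnt), "/")
  filler <- grep("^G[0-9]", rownames(cnt), value = TRUE)
  mal <- rowMeans(cpm[filler, sim$truth$malignant])
  str <- rowMeans(cpm[filler, sim$truth$type == "fibroblast"])
  ## mean absolute log-ratio across ~500 genes should be small
  expect_lt(mean(abs(log2(mal / str))), 0.25)
  expect_lt(abs(mean(log2(mal / str))), 0.05)
})

test_that("a planted +1 block doubles malignant expression of its genes", {
  cfg <- sim_config(n_patients = 1, cells_per_sample = 1200, n_genes = 2000,
                    cna_block_spec = data.frame(arm = "chr1p", amplitude = 1),
                    subclones_per_patient = 1, malignant_fraction = 0.5,
                    program_spec = list(), seed = 4)
  sim <- simulate_single_cell_cohort(cfg)
  cnt <- as.matrix(sim$counts$counts)
  gm <- sim$counts$gene_meta
  block <- gm$symbol[gm$chromosome == "chr1" & gm$arm == "p" &
                       grepl("^G[0-9]", gm$symbol)]
  expect_gte(length(block), 150)
  mal <- mean(cnt[block, sim$truth$malignant])
  str <- mean(cnt[block, !sim$truth$malignant])
  expect_gt(mal / str, 1.8)
  expect_lt(mal / str, 2.2)
})

test_that("raising the block amplitude strictly raises the malignant log-ratio", {
  ratios <- vapply(c(0.5, 1, 1.5), function(amp) {
    cfg <- sim_config(n_patients = 1, cells_per_sample = 1100, n_genes = 1000,
                      cna_block_spec = data.frame(arm = "chr1p", amplitude = amp),
                      subclones_per_patient = 1, malignant_fraction = 0.5,
                      program_spec = list(), seed = 5)
    sim <- simulate_single_cell_cohort(cfg)
    cnt <- as.matrix(sim$counts$counts)
    gm <- sim$counts$gene_meta
    block <- gm$symbol[gm$chromosome == "chr1" & gm$arm == "p" &
                         grepl("^G[0-9]", gm$symbol)]
    log2(mean(cnt[block, sim$truth$malignant]) /
           mean(cnt[block, !sim$truth$malignant]))
  }, 0)
  expect_true(all(diff(ratios) > 0))
})

test_that("bulk fractions are conserved and mixtures follow the centroids", {
  cfg <- sim_config(n_genes = 1000, seed = 6)
  bk <- simulate_bulk_cohort(cfg)
  expect_true(all(abs(rowSums(bk$truth$fractions) - 1) < 1e-9))

  ## zero-noise known-fraction mixtures equal the matrix-product oracle
  cfg0 <- sim_config(n_genes = 1000, seed = 6,
                     program_spec = list(), bulk = list(noise_sd = 0))
  types <- c(names(default_type_fractions()), "malignant")
  fr <- matrix(0, 3, length(types), dimnames = list(NULL, types))
  fr[1, "macrophage"] <- 1                       # pure macrophage sample
  fr[2, c("T_CD8", "malignant")] <- c(0.3, 0.7)
  fr[3, c("T_CD8", "malignant")] <- c(0.7, 0.3)  # swapped
  bk0 <- simulate_bulk_cohort(cfg0, truth_fractions = fr)
  oracle <- bk0$truth$centroids %*% t(fr) * cfg0$bulk$library_size
  expect_equal(unname(bk0$bulk$counts), unname(oracle), tolerance = 1e-12)
  ## pure macrophage profile is the macrophage centroid up to scale
  expect_equal(bk0$bulk$counts[, 1] / sum(bk0$bulk$counts[, 1]),
               bk0$truth$centroids[, "macrophage"], tolerance = 1e-12,
               ignore_attr = TRUE)
  ## swapped T fractions order the T-marker totals accordingly
  t_markers <- intersect(c("CD3D", "CD3E", "CD2"), rownames(bk0$bulk$counts))
  expect_lt(sum(bk0$bulk$counts[t_markers, 2]), sum(bk0$bulk$counts[t_markers, 3]))
  expect_error(simulate_bulk_cohort(cfg0, truth_fractions = -fr), "nonnegative")
})

test_that("planted Tregs clear the Treg gate after CLR in >=95% of draws", {
  cfg <- sim_config(seed = 7, spatial = list(
    n_cells = 6000L,
    phenotype_fractions = c(Tumor = 0.3, Macrophage = 0.1, `CD8 T cell` = 0.1,
                            `CD4 T cell` = 0.1, Treg = 0.25, `B cell` = 0.05,
                            `NK cell` = 0.02, Stroma = 0.08)))
  sp <- simulate_spatial_table(cfg)
  tab <- clr_normalize(sp$table)
  tregs <- sp$truth$phenotype == "Treg"
  expect_gte(sum(tregs), 1000)
  pass <- tab$clr_FOXP3[tregs] > 1.4 & tab$clr_CD4[tregs] > 1.1
  expect_gte(mean(pass), 0.95)
  expect_error(
    simulate_spatial_table(sim_config(spatial = list(resolution_um_per_px = 0))),
    "resolution")
})

test_that("zero planted enrichment leaves HLA-DR neighborhoods null", {
  cfg <- sim_config(seed = 8, spatial = list(cd4_enrichment = 0))
  sp <- simulate_spatial_table(cfg)
  tab <- clr_normalize(sp$table)
  ph <- phenotype_cells(tab)
  dr <- call_hladr(tab, ph$phenotype)
  nb <- neighborhood_counts(tab, ph$phenotype)
  cmp <- compare_neighborhoods(nb, dr$positive, ph$phenotype == "Tumor")
  expect_gt(cmp$p[cmp$neighbor == "CD4 T cell"], 0.05)
})
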