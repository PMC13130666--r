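## Shared fixtures, built lazily and cached for the whole test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

## two-patient cohort taken through QC, normalization and batch correction
fx_cohort2 <- function() fixture("cohort2", function() {
  cfg <- sim_config(n_patients = 2, cells_per_sample = 250, n_genes = 2000,
                    seed = 42)
  sim <- simulate_single_cell_cohort(cfg)
  lin <- initial_lineage(sim$counts)
  qcd <- filter_genes(qc_filter_cells(sim$counts, lin$lineage))
  norm <- normalize_log2cpm(qcd)
  lin2 <- initial_lineage(qcd)
  norm <- batch_correct_platform(norm, lin2$type)
  truth <- sim$truth[match(qcd$cell_meta$cell_id, sim$truth$cell_id), ]
  list(config = cfg, sim = sim, qcd = qcd, norm = norm, truth = truth,
       lineage = lin2)
})

## full default cohort (5 patients x 1,000 cells) with the same processing
fx_cohort5 <- function() fixture("cohort5", function() {
  cfg <- sim_config(seed = 42)
  sim <- simulate_single_cell_cohort(cfg)
  lin <- initial_lineage(sim$counts)
  qcd <- filter_genes(qc_filter_cells(sim$counts, lin$lineage))
  norm <- normalize_log2cpm(qcd)
  truth <- sim$truth[match(qcd$cell_meta$cell_id, sim$truth$cell_id), ]
  list(config = cfg, sim = sim, qcd = qcd, norm = norm, truth = truth)
})

## CNA workspace of the two-patient cohort, scored and classified
fx_cna2 <- function() fixture("cna2", function() {
  fx <- fx_cohort2()
  role <- sim_cell_roles(fx$truth)
  ws <- infer_cna_profiles(fx$norm, role, cna_params(seed = 42))
  ws <- compute_cna_scores(ws)
  ws <- infer_subclones(ws)
  classify_malignant(ws)
})

## map simulator truth types to CNA roles (epithelial vs stromal references)
sim_cell_roles <- function(truth) {
  ifelse(truth$type %in% c("malignant", "epithelial_normal"), "epithelial",
         ifelse(truth$type %in% c("fibroblast", "myofibroblast", "endothelial"),
                truth$type, NA))
}

## tiny annotated_counts built by hand
toy_counts <- function(counts, patient = "P01", mito = NULL) {
  n_g <- nrow(counts); n_c <- ncol(counts)
  rownames(counts) <- rownames(counts) %||% paste0("g", seq_len(n_g))
  colnames(counts) <- colnames(counts) %||% paste0("c", seq_len(n_c))
  gm <- data.frame(symbol = rownames(counts), chromosome = "chr1",
                   arm = "p", order = seq_len(n_g),
                   mito = seq_len(n_g) %in% (mito %||% integer()))
  cm <- data.frame(cell_id = colnames(counts),
                   patient = rep_len(patient, n_c),
                   timepoint = "pre", platform = "5prime", tcr = FALSE)
  annotated_counts(counts, cm, gm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
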