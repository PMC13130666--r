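## ---------------------------------------------------------------------------
## Synthetic tumor-cohort generator
##
## All downstream stages (CNA inference, NMF metaprograms, T-cell gating,
## deconvolution, spatial gating) are exercised on data from this module, so
## the generator plants every kind of signal those stages are designed to
## recover: arm-level CNA blocks with subclone structure, additive expression
## programs in malignant cells, canonical marker genes per cell type, platform
## batch shifts, bulk mixtures with known fractions, and spatial tables with
## known phenotype gates and neighborhood enrichments.
## ---------------------------------------------------------------------------

#' Default planted arm-level CNA blocks
#'
#' Three arm-level events (a chr1p gain, a chr2q loss, a chr3p gain), each of
#' amplitude 1 on the log2 expected-count scale (i.e. a 2-fold dosage change).
#' Subclone k of a patient carries the first `n_blocks - k + 1` events, so
#' consecutive subclones always differ by exactly one chromosome arm.
#'
#' @return data.frame with columns `arm` (e.g. `"chr1p"`) and `amplitude`.
#' @export
default_cna_blocks <- function() {
  data.frame(arm = c("chr1p", "chr2q", "chr3p"),
             amplitude = c(1, -1, 1),
             stringsAsFactors = FALSE)
}

#' Default planted expression programs
#'
#' Three 30-gene additive programs modeled on recurrent malignant HNSCC cell
#' states: an IFN/MHC-II program (MHC class II plus interferon-response
#' genes), a partial-EMT program, and an epithelial-senescence (EpiSen)
#' program. Every malignant cell is dominated by one program state whose
#' activity (the log2 fold added to the program genes) is a truncated
#' normal draw with the stated `mean` and `sd`, while the other programs
#' stay at low background activity; `post_effect` tilts the state weights
#' (log scale) in post-treatment samples.
#'
#' @return named list of programs, each with `genes`, `mean`, `sd`,
#'   `post_effect`.
#' @export
default_program_spec <- function() {
  ifn <- c("HLA-DRA", "HLA-DRB1", "HLA-DPA1", "HLA-DPB1", "HLA-DQA1",
           "HLA-DQB1", "CD74", "HLA-DMA", "CXCL9", "CXCL10", "CXCL11",
           "TAP1", "TAP2", "IFIT1", "IFIT3", "IRF1", "STAT1", "GBP1",
           "GBP2", "ISG15", "MX1", "OAS1", "PSMB8", "PSMB9", "B2M",
           "IFI6", "IFI27", "RSAD2", "XAF1", "BST2")
  pemt <- c("LAMC2", "LAMA3", "LAMB3", "INHBA", "PLAU", "COL17A1", "ITGA5",
            "ITGA6", "ITGB1", "ITGB4", "MMP1", "MMP10", "PDPN", "TNC",
            "FN1", "SERPINE1", "TGFBI", "CDH13", "VIM", "SNAI2", "MMP2",
            "P4HA2", "PLOD2", "SEMA3C", "DST", "EMP3", "CAV1", "IGFBP3",
            "TNFRSF12A", "SLC7A8")
  episen <- c("S100A8", "S100A9", "SPRR1A", "SPRR1B", "SPRR2A", "CDKN1A",
              "KRT6A", "KRT6B", "KRT16", "KRT17", "LCN2", "CLDN4", "CLDN7",
              "SLPI", "PI3", "CSTB", "ANXA1", "KRT13", "EMP1", "MAL",
              "CEACAM6", "TACSTD2", "GPRC5A", "SDCBP2", "TMPRSS11E",
              "RHCG", "A2ML1", "CRCT1", "LYPD3", "CSTA")
  list(
    IFN_MHC2 = list(genes = ifn,    mean = 2, sd = 0.5, post_effect = 0.5),
    pEMT     = list(genes = pemt,   mean = 2, sd = 0.5, post_effect = -0.3),
    EpiSen   = list(genes = episen, mean = 2, sd = 0.5, post_effect = 0)
  )
}

#' Default canonical marker genes per cell type
#'
#' @return named list of character vectors of marker symbols. Lineage markers
#'   shared across T subsets (CD3D/CD3E/CD2) appear in several sets.
#' @export
default_marker_spec <- function() {
  list(
    epithelial_normal = c("EPCAM", "KRT5", "KRT14", "CDH1", "DSP", "PKP1"),
    fibroblast    = c("COL1A1", "COL1A2", "COL3A1", "DCN", "LUM", "PDGFRA"),
    myofibroblast = c("ACTA2", "TAGLN", "MYL9", "MYH11", "CNN1"),
    endothelial   = c("PECAM1", "VWF", "CDH5", "CLDN5", "EGFL7"),
    macrophage    = c("CD68", "CD14", "LYZ", "AIF1", "FCGR2A", "C1QA"),
    T_CD8    = c("CD3D", "CD3E", "CD2", "CD8A", "CD8B", "GZMK"),
    T_helper = c("CD3D", "CD3E", "CD2", "CD4", "IL7R", "CCR7"),
    T_reg    = c("CD3D", "CD3E", "CD2", "FOXP3", "IL2RA", "CTLA4"),
    NK = c("GNLY", "NKG7", "KLRD1", "NCR1", "PRF1"),
    B  = c("MS4A1", "CD79A", "CD79B", "CD19", "BANK1")
  )
}

#' Default non-malignant cell-type composition
#'
#' Proportions of the non-malignant compartment of each simulated sample.
#' @return named numeric vector summing to 1.
#' @export
default_type_fractions <- function() {
  c(epithelial_normal = 0.10, fibroblast = 0.17, myofibroblast = 0.05,
    endothelial = 0.08, macrophage = 0.12, T_CD8 = 0.17, T_helper = 0.11,
    T_reg = 0.05, NK = 0.04, B = 0.11)
}

## cell types whose QC threshold is the lymphoid one
LYMPHOID_TYPES <- c("T_CD8", "T_helper", "T_reg", "NK", "B")

#' Simulation configuration
#'
#' Bundles every knob of the synthetic cohort generator. Defaults define the
#' reference study conditions used throughout the package's tests: 5 patients
#' with a pre- and a post-treatment sample of 500 cells each (1,000 cells per
#' patient), 5,000 genes on 5 chromosomes, 30% malignant cells carrying three
#' arm-level CNA blocks of amplitude 1 split across two subclones, three
#' 30-gene additive malignant programs, negative-binomial counts with
#' gene-level dispersion 0.5 and lognormal library sizes around 5,000 UMIs.
#'
#' @param n_patients number of patients.
#' @param cells_per_sample cells per sample (each patient contributes a
#'   pre- and a post-treatment sample).
#' @param n_genes,n_chromosomes genome size; genes are split evenly across
#'   chromosomes and each chromosome into a p and a q arm.
#' @param malignant_fraction proportion of malignant cells per sample.
#' @param subclones_per_patient number of genetic subclones; must not exceed
#'   the number of CNA blocks so that subclones differ in at least one arm.
#' @param cna_block_spec data.frame of planted events, see
#'   [default_cna_blocks()]. Amplitudes are log2 fold-changes applied to
#'   expected counts of all genes on the arm.
#' @param program_spec named list of additive programs, see
#'   [default_program_spec()].
#' @param marker_spec named list of canonical markers, see
#'   [default_marker_spec()].
#' @param type_fractions non-malignant composition, see
#'   [default_type_fractions()].
#' @param marker_log2_boost log2 fold-change of a marker gene in its own cell
#'   type over baseline.
#' @param batch_shift_sd sd of the per-gene additive log2 shift applied to
#'   3'-sequenced cells (the platform batch effect).
#' @param dispersion negative-binomial gene-level dispersion (size =
#'   1/dispersion).
#' @param library_size_meanlog,library_size_sdlog lognormal library-size
#'   parameters.
#' @param low_quality_fraction fraction of planted low-quality cells (high
#'   mitochondrial load, ~600 UMIs).
#' @param subclone_timepoint_tilt log-odds tilt linking subclone identity to
#'   timepoint, so subclone composition shifts pre to post.
#' @param bulk,spatial parameter sublists for the bulk-mixture and spatial
#'   generators; see [simulate_bulk_cohort()] and [simulate_spatial_table()].
#' @param seed integer seed; all generator randomness derives from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 5L,
                       cells_per_sample = 500L,
                       n_genes = 5000L,
                       n_chromosomes = 5L,
                       malignant_fraction = 0.3,
                       subclones_per_patient = 2L,
                       cna_block_spec = default_cna_blocks(),
                       program_spec = default_program_spec(),
                       marker_spec = default_marker_spec(),
                       type_fractions = default_type_fractions(),
                       marker_log2_boost = 5,
                       batch_shift_sd = 0.3,
                       dispersion = 0.5,
                       library_size_meanlog = log(5000),
                       library_size_sdlog = 0.3,
                       low_quality_fraction = 0.05,
                       subclone_timepoint_tilt = 1.0,
                       bulk = list(),
                       spatial = list(),
                       seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              cells_per_sample = as.integer(cells_per_sample),
              n_genes = as.integer(n_genes),
              n_chromosomes = as.integer(n_chromosomes),
              malignant_fraction = malignant_fraction,
              subclones_per_patient = as.integer(subclones_per_patient),
              cna_block_spec = cna_block_spec,
              program_spec = program_spec,
              marker_spec = marker_spec,
              type_fractions = type_fractions,
              marker_log2_boost = marker_log2_boost,
              batch_shift_sd = batch_shift_sd,
              dispersion = dispersion,
              library_size_meanlog = library_size_meanlog,
              library_size_sdlog = library_size_sdlog,
              low_quality_fraction = low_quality_fraction,
              subclone_timepoint_tilt = subclone_timepoint_tilt,
              bulk = utils::modifyList(default_bulk_params(), bulk),
              spatial = utils::modifyList(default_spatial_params(), spatial),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

default_bulk_params <- function() {
  list(n_patients = 25L, n_responders = 8L, n_paired = 18L,
       library_size = 3e6, noise_sd = 0.15,
       responder_activity_shift = 1.0, responder_tcell_shift = 0.5,
       fraction_concentration = 60)
}

default_spatial_params <- function() {
  list(n_cells = 4000L, width_px = 2000, height_px = 2000,
       resolution_um_per_px = 0.5, noise_sd = 0.2,
       hladr_positive_fraction = 0.4, cd4_enrichment = 0.35,
       phenotype_fractions = c(Tumor = 0.40, Macrophage = 0.12,
                               `CD8 T cell` = 0.10, `CD4 T cell` = 0.12,
                               Treg = 0.05, `B cell` = 0.06,
                               `NK cell` = 0.04, Stroma = 0.11))
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    stop_if_not(n_patients > 0 && cells_per_sample > 0 && n_genes > 0 &&
                  n_chromosomes > 0, "all counts must be positive")
    stop_if_not(malignant_fraction > 0 && malignant_fraction < 1,
                "malignant_fraction must be in (0,1)")
    stop_if_not(all(is.finite(cna_block_spec$amplitude)),
                "CNA block amplitudes must be finite")
    stop_if_not(subclones_per_patient >= 1, "need at least one subclone")
    if (nrow(cna_block_spec) > 0)
      stop_if_not(subclones_per_patient <= nrow(cna_block_spec) ||
                    subclones_per_patient == 1L,
                  "subclones_per_patient must not exceed the number of CNA blocks")
    stop_if_not(batch_shift_sd >= 0, "batch_shift_sd must be nonnegative")
    prog_genes <- unlist(lapply(program_spec, `[[`, "genes"))
    mark_genes <- unlist(marker_spec)
    stop_if_not(!anyDuplicated(prog_genes),
                "program gene sets must be disjoint from each other")
    overlap <- intersect(prog_genes, mark_genes)
    stop_if_not(length(overlap) == 0,
                "program gene sets must be disjoint from marker genes (%s)",
                paste(utils::head(overlap, 3), collapse = ", "))
    n_reserved <- length(prog_genes) + length(unique(mark_genes)) + 10L
    stop_if_not(n_genes >= n_reserved + n_chromosomes * 2L,
                "n_genes too small for the reserved marker/program/mito genes")
  })
  invisible(cfg)
}

## Gene annotation table plus baseline expression weights. Marker and program
## genes are interleaved evenly along the genome (as real signature genes are)
## so that they never mimic a contiguous copy-number event; ten mitochondrial
## genes sit at the end of the last chromosome.
build_gene_table <- function(cfg) {
  n <- cfg$n_genes
  per_chr <- rep(n %/% cfg$n_chromosomes, cfg$n_chromosomes)
  per_chr[cfg$n_chromosomes] <- per_chr[cfg$n_chromosomes] + n %% cfg$n_chromosomes
  chrom <- rep(paste0("chr", seq_len(cfg$n_chromosomes)), per_chr)
  order_in_chr <- unlist(lapply(per_chr, seq_len))
  arm <- ifelse(order_in_chr <= rep(per_chr %/% 2, per_chr), "p", "q")

  symbol <- paste0("G", match(chrom, unique(chrom)), ".", order_in_chr)
  mito_idx <- (n - 9L):n
  symbol[mito_idx] <- paste0("MT-", seq_along(mito_idx))

  markers <- unique(unlist(cfg$marker_spec))
  progs <- unlist(lapply(cfg$program_spec, `[[`, "genes"))
  reserved <- c(markers, progs)
  slots <- setdiff(seq_len(n), mito_idx)
  pos <- slots[round(seq(1, length(slots), length.out = length(reserved)))]
  symbol[pos] <- reserved

  data.frame(symbol = symbol, chromosome = chrom, arm = arm,
             order = order_in_chr,
             mito = seq_len(n) %in% mito_idx,
             stringsAsFactors = FALSE)
}

## genes x types matrix of expected relative expression (library-normalised)
type_expected_profiles <- function(cfg, gene_table, base_weight) {
  types <- names(cfg$type_fractions)
  W <- matrix(base_weight, nrow = nrow(gene_table), ncol = length(types),
              dimnames = list(gene_table$symbol, types))
  for (ty in types) {
    mk <- intersect(cfg$marker_spec[[ty]], gene_table$symbol)
    W[mk, ty] <- W[mk, ty] * 2^cfg$marker_log2_boost
  }
  sweep(W, 2, colSums(W), "/")
}

## per-gene log2 fold vector for the CNA events of one subclone
subclone_blocks <- function(cfg, k) {
  nb <- nrow(cfg$cna_block_spec)
  if (nb == 0) return(cfg$cna_block_spec[0, ])
  cfg$cna_block_spec[seq_len(max(1L, nb - k + 1L)), , drop = FALSE]
}

cna_fold_vector <- function(blocks, gene_table) {
  fold <- rep(1, nrow(gene_table))
  key <- paste0(gene_table$chromosome, gene_table$arm)
  for (i in seq_len(nrow(blocks)))
    fold[key == blocks$arm[i]] <- 2^blocks$amplitude[i]
  fold
}

## The expression model (gene table, baseline weights, type profiles,
## platform shift) is drawn once from the config seed and shared by the
## single-cell and bulk generators, so single-cell-derived centroids match
## the bulk generative model.
cohort_model <- function(config) {
  with_seed(derive_seed(config$seed, 0L), {
    gt <- build_gene_table(config)
    n_genes <- nrow(gt)
    base_w <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1)
    names(base_w) <- gt$symbol
    markers <- unique(unlist(config$marker_spec))
    progs <- unlist(lapply(config$program_spec, `[[`, "genes"))
    base_w[markers] <- 0.25
    base_w[progs] <- 1.2   # program genes are well-expressed
    ## mitochondrial genes: ~5% of UMIs in healthy cells
    base_w[gt$mito] <- sum(base_w[!gt$mito]) * 0.05 / 0.95 / sum(gt$mito)
    list(gene_table = gt,
         base_w = base_w,
         profiles = type_expected_profiles(config, gt, base_w),
         platform_shift = stats::rnorm(n_genes, 0, config$batch_shift_sd))
  })
}

#' Simulate a multi-patient single-cell cohort with known ground truth
#'
#' Generates UMI counts for `n_patients` patients, each with a pre- and a
#' post-treatment sample. Counts are negative-binomial around cell-type mean
#' profiles scaled to a lognormal library size; malignant cells multiply
#' expected counts by `2^amplitude` over their subclone's planted arm-level
#' CNA blocks and by `2^activity` over program genes; 3'-platform cells
#' receive an additive per-gene log2 shift. A small planted fraction of
#' low-quality cells carries high mitochondrial load and ~600 UMIs.
#'
#' @param config a [sim_config()].
#' @return list with `counts` (an [annotated_counts()] object) and `truth`, a
#'   data.frame of per-cell ground truth (type, malignant flag, subclone,
#'   program activities, TCR flag, low-quality flag).
#' @export
simulate_single_cell_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  model <- cohort_model(config)
  with_seed(derive_seed(config$seed, 1L), {
    gt <- model$gene_table
    n_genes <- nrow(gt)
    W <- model$profiles
    platform_shift <- model$platform_shift
    fold_by_subclone <- lapply(seq_len(config$subclones_per_patient),
                               function(k) cna_fold_vector(subclone_blocks(config, k), gt))
    prog_names <- names(config$program_spec)
    prog_idx <- lapply(config$program_spec,
                       function(p) match(p$genes, gt$symbol))

    all_counts <- list(); meta <- list(); truth <- list()
    for (pat in seq_len(config$n_patients)) {
      patient <- sprintf("P%02d", pat)
      for (tp in c("pre", "post")) {
        nc <- config$cells_per_sample
        frac <- config$type_fractions
        if (tp == "post") {  # modest T-compartment shift after treatment
          frac[["T_CD8"]] <- frac[["T_CD8"]] * 1.25
          frac[["T_helper"]] <- frac[["T_helper"]] * 0.8
          frac <- frac / sum(frac)
        }
        is_mal <- stats::runif(nc) < config$malignant_fraction
        type <- character(nc)
        type[!is_mal] <- sample(names(frac), sum(!is_mal), TRUE, prob = frac)
        type[is_mal] <- "malignant"

        s <- config$subclones_per_patient
        tilt <- config$subclone_timepoint_tilt
        w_sub <- exp((if (tp == "pre") rev(seq_len(s)) else seq_len(s)) * tilt / max(1, s - 1))
        subclone <- rep(NA_integer_, nc)
        subclone[is_mal] <- sample.int(s, sum(is_mal), TRUE, prob = w_sub)

        platform <- sample(c("3prime", "5prime"), nc, TRUE)
        lowq <- stats::runif(nc) < config$low_quality_fraction
        lib <- stats::rlnorm(nc, config$library_size_meanlog, config$library_size_sdlog)
        lib[lowq] <- 600
        tcr_prob <- ifelse(type %in% c("T_CD8", "T_helper", "T_reg"), 0.85,
                           ifelse(type == "NK", 0.02, 0.005))
        tcr <- stats::runif(nc) < tcr_prob

        ## each malignant cell is dominated by one program state (activity
        ## ~ N(mean, sd)) with low background activity of the others; the
        ## timepoint effect tilts the state weights after treatment
        act <- matrix(0, nc, length(prog_names),
                      dimnames = list(NULL, prog_names))
        state <- rep(NA_character_, nc)
        if (length(prog_names) && any(is_mal)) {
          w_state <- vapply(config$program_spec, function(pg)
            exp(if (tp == "post") pg$post_effect else 0), 0)
          state[is_mal] <- sample(prog_names, sum(is_mal), TRUE, prob = w_state)
          for (j in seq_along(prog_names)) {
            pg <- config$program_spec[[j]]
            dom <- is_mal & state == prog_names[j]
            act[dom, j] <- pmax(0, stats::rnorm(sum(dom), pg$mean, pg$sd))
            bg <- is_mal & state != prog_names[j]
            act[bg, j] <- pmax(0, stats::rnorm(sum(bg), 0.2, 0.2))
          }
        }

        mu <- matrix(0, n_genes, nc)
        for (ci in seq_len(nc)) {
          ty <- if (type[ci] == "malignant") "epithelial_normal" else type[ci]
          p0 <- W[, ty]
          mult <- rep(1, n_genes)
          if (type[ci] == "malignant") {
            mult <- fold_by_subclone[[subclone[ci]]]
            for (j in seq_along(prog_names))
              if (act[ci, j] > 0)
                mult[prog_idx[[j]]] <- mult[prog_idx[[j]]] * 2^act[ci, j]
          }
          if (platform[ci] == "3prime") mult <- mult * 2^platform_shift
          if (lowq[ci]) mult[gt$mito] <- mult[gt$mito] * 10
          mu[, ci] <- lib[ci] * p0 * mult
        }
        cnt <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion),
                      n_genes, nc)

        ids <- sprintf("%s_%s_c%04d", patient, tp, seq_len(nc))
        all_counts[[length(all_counts) + 1L]] <- cnt
        meta[[length(meta) + 1L]] <- data.frame(
          cell_id = ids, patient = patient, timepoint = tp,
          sample = paste(patient, tp, sep = "_"), platform = platform,
          tcr = tcr, stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <- data.frame(
          cell_id = ids, type = type, malignant = type == "malignant",
          subclone = subclone, program_state = state, tcr = tcr,
          low_quality = lowq, stringsAsFactors = FALSE)
        truth[[length(truth)]] <- cbind(truth[[length(truth)]],
                                        as.data.frame(act))
      }
    }
    counts <- do.call(cbind, all_counts)
    cell_meta <- do.call(rbind, meta)
    truth <- do.call(rbind, truth)
    rownames(counts) <- gt$symbol
    colnames(counts) <- cell_meta$cell_id
    ac <- annotated_counts(Matrix::Matrix(counts, sparse = TRUE), cell_meta, gt)
    list(counts = ac, truth = truth)
  })
}

#' Simulate a bulk RNA-seq cohort from known cell-type fractions
#'
#' Bulk expected profiles are fraction-weighted sums of the cell-type expected
#' profiles used by [simulate_single_cell_cohort()], scaled to a bulk library
#' size and perturbed by multiplicative lognormal noise. Responder samples
#' receive elevated malignant IFN/MHC-II program activity and (as a planted
#' confounder) a higher T-cell fraction. With `noise_sd = 0` the count matrix
#' is exactly the fraction-by-centroid matrix product.
#'
#' @param config a [sim_config()]; the `bulk` sublist holds cohort size,
#'   noise, and the responder effect sizes.
#' @param truth_fractions optional samples x cell-types matrix of fractions
#'   (rows must sum to 1, no negatives); when omitted, fractions are drawn
#'   from a Dirichlet model around the configured composition.
#' @return list with `bulk` (a `bulk_cohort`: numeric counts, log2(CPM/10+1)
#'   expression, sample metadata) and `truth` (fractions, malignant program
#'   activity, response labels).
#' @export
simulate_bulk_cohort <- function(config, truth_fractions = NULL) {
  stopifnot(inherits(config, "sim_config"))
  bp <- config$bulk
  model <- cohort_model(config)
  with_seed(derive_seed(config$seed, 2L), {
    gt <- model$gene_table
    W <- model$profiles

    ## malignant centroid: epithelial base, subclone-averaged CNA dosage,
    ## mean program activity
    folds <- sapply(seq_len(config$subclones_per_patient),
                    function(k) cna_fold_vector(subclone_blocks(config, k), gt))
    mal <- W[, "epithelial_normal"] * rowMeans(folds)
    for (pg in config$program_spec)
      mal[match(pg$genes, gt$symbol)] <-
        mal[match(pg$genes, gt$symbol)] * 2^pg$mean
    centroids <- cbind(W, malignant = mal / sum(mal))
    types <- colnames(centroids)

    if (is.null(truth_fractions)) {
      n_pat <- bp$n_patients
      resp_pat <- seq_len(bp$n_responders)
      smp <- data.frame(patient = sprintf("B%02d", seq_len(n_pat)),
                        timepoint = "pre", stringsAsFactors = FALSE)
      if (bp$n_paired > 0)
        smp <- rbind(smp, data.frame(patient = sprintf("B%02d", seq_len(bp$n_paired)),
                                     timepoint = "post", stringsAsFactors = FALSE))
      smp$response <- ifelse(match(smp$patient, sprintf("B%02d", seq_len(n_pat))) %in%
                               resp_pat, "R", "NR")
      smp$sample <- paste(smp$patient, smp$timepoint, sep = "_")
      alpha0 <- c(config$type_fractions * 0.65, malignant = 0.35)
      fr <- t(sapply(seq_len(nrow(smp)), function(i) {
        a <- alpha0
        if (smp$response[i] == "R") {
          ## shift the total T fraction by responder_tcell_shift standard
          ## deviations of its Dirichlet sampling distribution
          tt <- c("T_CD8", "T_helper", "T_reg", "NK")
          p_t <- sum(a[tt])
          sd_t <- sqrt(p_t * (1 - p_t) / (bp$fraction_concentration + 1))
          a[tt] <- a[tt] * (p_t + bp$responder_tcell_shift * sd_t) / p_t
        }
        g <- stats::rgamma(length(a), shape = a * bp$fraction_concentration)
        g / sum(g)
      }))
      colnames(fr) <- names(alpha0)
      fr <- fr[, types, drop = FALSE]
    } else {
      stop_if_not(all(truth_fractions >= 0), "fractions must be nonnegative")
      stop_if_not(all(abs(rowSums(truth_fractions) - 1) < 1e-9),
                  "fractions per sample must sum to 1")
      fr <- truth_fractions[, types, drop = FALSE]
      smp <- data.frame(patient = sprintf("B%02d", seq_len(nrow(fr))),
                        timepoint = "pre",
                        response = rep(c("R", "NR"), length.out = nrow(fr)))
      smp$sample <- paste(smp$patient, smp$timepoint, sep = "_")
    }
    n_smp <- nrow(fr)

    ## per-sample malignant IFN/MHC-II activity (first configured program)
    ifn <- if (length(config$program_spec)) config$program_spec[[1]] else NULL
    activity <- if (is.null(ifn)) rep(0, n_smp) else
      stats::rnorm(n_smp, ifn$mean, ifn$sd) +
        ifelse(smp$response == "R", bp$responder_activity_shift * ifn$sd, 0)
    ifn_idx <- if (is.null(ifn)) integer() else match(ifn$genes, gt$symbol)

    counts <- matrix(0, nrow(gt), n_smp,
                     dimnames = list(gt$symbol, smp$sample))
    for (i in seq_len(n_smp)) {
      mal_i <- centroids[, "malignant"]
      if (length(ifn_idx))
        mal_i[ifn_idx] <- mal_i[ifn_idx] * 2^(activity[i] - ifn$mean)
      cen_i <- centroids
      cen_i[, "malignant"] <- mal_i / sum(mal_i)
      mu <- as.numeric(cen_i %*% fr[i, ]) * bp$library_size
      noise <- if (bp$noise_sd > 0) exp(stats::rnorm(nrow(gt), 0, bp$noise_sd)) else 1
      counts[, i] <- mu * noise
    }

    bulk <- structure(list(counts = counts,
                           expression = log2cpm(counts),
                           sample_meta = smp,
                           fractions = NULL, purity = NULL),
                      class = "bulk_cohort")
    truth <- list(fractions = fr, activity = activity,
                  response = smp$response, sample = smp$sample,
                  centroids = centroids)
    list(bulk = bulk, truth = truth)
  })
}

#' Simulate a segmented multiplexed-imaging cell table
#'
#' Places cells uniformly in a rectangle at a stated pixel resolution and
#' draws per-marker mean intensities so that, after CLR normalization, the
#' configured phenotype gates separate the planted classes. Marker
#' log-intensities are drawn around per-phenotype target CLR values
#' (centered by the planted composition so realized CLR values match the
#' targets); a planted enrichment attaches a fraction of CD4 T cells to
#' HLA-DR-positive tumor cells.
#'
#' @param config a [sim_config()]; the `spatial` sublist holds the cell
#'   count, field size, resolution (micrometers per pixel), intensity noise,
#'   HLA-DR-positive tumor fraction, and the CD4 enrichment strength.
#' @return list with `table` (a `spatial_cell_table` data.frame: id, x, y,
#'   raw marker intensities, with resolution in the attributes) and `truth`
#'   (planted phenotype, HLA-DR status, enrichment flag).
#' @export
simulate_spatial_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sp <- config$spatial
  stop_if_not(sp$resolution_um_per_px > 0, "resolution must be positive")
  with_seed(derive_seed(config$seed, 3L), {
    frac <- sp$phenotype_fractions / sum(sp$phenotype_fractions)
    n <- sp$n_cells
    pheno <- sample(names(frac), n, TRUE, prob = frac)

    ## split tumor into HLA-DR positive / negative subpopulations
    is_tum <- pheno == "Tumor"
    hladr_pos <- rep(NA, n)
    hladr_pos[is_tum] <- stats::runif(sum(is_tum)) < sp$hladr_positive_fraction

    targets <- spatial_clr_targets()
    markers <- colnames(targets)
    ## effective class used to index the target matrix
    cls <- pheno
    cls[is_tum & hladr_pos] <- "Tumor_DRpos"
    cls[is_tum & !hladr_pos] <- "Tumor_DRneg"
    cls_frac <- table(factor(cls, rownames(targets))) / n
    ## center targets by realized composition so realized CLR == target
    m <- as.numeric(cls_frac %*% targets)
    L <- sweep(targets, 2, m, "-")

    logint <- L[cls, , drop = FALSE] +
      matrix(stats::rnorm(n * length(markers), 0, sp$noise_sd), n)
    raw <- pmin(exp(logint + log(10)) - 1, 255)
    raw[raw < 0] <- 0
    colnames(raw) <- markers

    x <- stats::runif(n, 0, sp$width_px)
    y <- stats::runif(n, 0, sp$height_px)
    ## planted neighborhood enrichment: move a fraction of CD4 T cells next
    ## to HLA-DR+ tumor cells
    attached <- rep(FALSE, n)
    cd4 <- which(pheno == "CD4 T cell")
    anchors <- which(is_tum & hladr_pos)
    if (sp$cd4_enrichment > 0 && length(anchors) > 0 && length(cd4) > 0) {
      pick <- cd4[stats::runif(length(cd4)) < sp$cd4_enrichment]
      anc <- sample(anchors, length(pick), replace = TRUE)
      r <- stats::runif(length(pick), 5, 45)
      th <- stats::runif(length(pick), 0, 2 * pi)
      x[pick] <- pmin(pmax(x[anc] + r * cos(th), 0), sp$width_px)
      y[pick] <- pmin(pmax(y[anc] + r * sin(th), 0), sp$height_px)
      attached[pick] <- TRUE
    }

    tab <- data.frame(cell_id = sprintf("cell%05d", seq_len(n)),
                      x = x, y = y, stringsAsFactors = FALSE)
    tab <- cbind(tab, as.data.frame(raw, optional = TRUE))
    tab <- spatial_cell_table(tab, markers = markers,
                              resolution_um_per_px = sp$resolution_um_per_px)
    truth <- data.frame(cell_id = tab$cell_id, phenotype = pheno,
                        hladr_positive = hladr_pos, attached = attached,
                        stringsAsFactors = FALSE)
    list(table = tab, truth = truth)
  })
}

## per-phenotype target CLR values; positive entries sit comfortably above the
## gating thresholds, everything else stays near a negative baseline.
spatial_clr_targets <- function() {
  markers <- c("FOXP3", "CD4", "CD8", "CD3e", "NKG2A", "CD14", "CD163",
               "CD68", "CD16a", "CD20", "TP63", "PanCK", "GZMK", "GZMB",
               "TCF1", "PD1", "TOX", "HLA-DR")
  classes <- c("Treg", "CD8 T cell", "CD4 T cell", "NK cell", "Macrophage",
               "B cell", "Tumor_DRpos", "Tumor_DRneg", "Stroma")
  tg <- matrix(-0.5, length(classes), length(markers),
               dimnames = list(classes, markers))
  tg["Treg", c("FOXP3", "CD4", "CD3e")] <- c(2.4, 2.0, 1.9)
  tg["CD8 T cell", c("CD8", "CD3e", "GZMK", "PD1")] <- c(2.6, 1.9, 1.9, 1.5)
  tg["CD4 T cell", c("CD4", "CD3e", "PD1", "TCF1")] <- c(2.2, 1.9, 1.6, 1.5)
  tg["NK cell", c("NKG2A", "GZMB")] <- c(2.2, 1.9)
  tg["Macrophage", c("CD14", "CD68", "CD163", "CD16a")] <- c(2.4, 2.3, 2.1, 1.9)
  tg["B cell", "CD20"] <- 2.6
  tg[c("Tumor_DRpos", "Tumor_DRneg"), c("PanCK", "TP63")] <-
    matrix(c(2.3, 1.9), 2, 2, byrow = TRUE)
  tg["Tumor_DRpos", "HLA-DR"] <- 1.4
  tg["Tumor_DRneg", "HLA-DR"] <- -0.8
  tg
}
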