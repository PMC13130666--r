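## ---------------------------------------------------------------------------
## Pipeline orchestration: simulate -> preprocess -> CNA -> metaprograms ->
## lymphoid -> composition -> bulk -> spatial with one config and one seed.
## ---------------------------------------------------------------------------

#' Pipeline configuration
#'
#' Collects per-stage parameter blocks, stage toggles, an output directory
#' and the global seed that fans out to every stochastic stage via
#' [derive_seed()].
#'
#' @param sim a [sim_config()].
#' @param qc a [qc_params()].
#' @param cna a [cna_params()].
#' @param nmf an [nmf_params()].
#' @param tsub a [t_subset_params()].
#' @param comp a [composition_params()].
#' @param ref a [reference_matrix_params()].
#' @param score a [signature_score_params()].
#' @param stages character subset of `c("simulate", "preprocess", "cna",
#'   "metaprograms", "lymphoid", "composition", "bulk", "spatial")`.
#' @param out_dir output directory for artifacts and the run manifest
#'   (`NULL` for in-memory only).
#' @param seed global seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), qc = qc_params(),
                            cna = cna_params(), nmf = nmf_params(),
                            tsub = t_subset_params(),
                            comp = composition_params(),
                            ref = reference_matrix_params(),
                            score = signature_score_params(),
                            stages = c("simulate", "preprocess", "cna",
                                       "metaprograms", "lymphoid",
                                       "composition", "bulk", "spatial"),
                            out_dir = NULL, seed = 1L) {
  structure(list(sim = sim, qc = qc, cna = cna, nmf = nmf, tsub = tsub,
                 comp = comp, ref = ref, score = score, stages = stages,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Executes the enabled stages in dependency order on one simulated cohort.
#' Each stage records a manifest entry (stage name, parameter hash, seed,
#' output dimensions); identical configs reproduce identical results. A
#' stage failure halts the run naming the failing stage; results of earlier
#' stages are retained in the returned object.
#'
#' @param config a [pipeline_config()].
#' @return list of per-stage results plus `manifest` (data.frame).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  res <- list()
  manifest <- list()
  seed <- config$seed
  note <- function(stage, params, dims) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, params_hash = params_hash(params), seed = seed,
      n_rows = dims[1], n_cols = dims[2], stringsAsFactors = FALSE)
  }
  run_stage <- function(stage, fn) {
    if (!stage %in% config$stages) return(invisible(NULL))
    tryCatch(fn(), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
  }

  run_stage("simulate", function() {
    config$sim$seed <- seed
    sim <- simulate_single_cell_cohort(config$sim)
    res$sim <<- sim
    note("simulate", unclass(config$sim)[c("n_patients", "cells_per_sample",
                                           "n_genes", "seed")], dim(sim$counts))
  })

  run_stage("preprocess", function() {
    sim <- res$sim
    lin <- initial_lineage(sim$counts, config$sim$marker_spec)
    qcd <- qc_filter_cells(sim$counts, lin$lineage, config$qc)
    qcd <- filter_genes(qcd, config$qc)
    norm <- normalize_log2cpm(qcd, center = TRUE)
    lin_kept <- lin$type[match(qcd$cell_meta$cell_id, sim$counts$cell_meta$cell_id)]
    norm <- batch_correct_platform(norm, lin_kept)
    res$qc <<- qcd
    res$norm <<- norm
    res$lineage <<- lin_kept
    ## cluster-based typing on the corrected matrix
    res$types <<- assign_cell_types(norm, config$sim$marker_spec,
                                    cluster_k = min(200L, ncol(norm$values) %/% 5),
                                    score_params = config$score,
                                    seed = derive_seed(seed, 21L))
    note("preprocess", unclass(config$qc), dim(norm$values))
  })

  run_stage("cna", function() {
    truth <- res$sim$truth[match(res$qc$cell_meta$cell_id,
                                 res$sim$truth$cell_id), ]
    role <- ifelse(truth$type %in% c("malignant", "epithelial_normal"),
                   "epithelial",
                   ifelse(truth$type %in% c("fibroblast", "myofibroblast",
                                            "endothelial"), truth$type, NA))
    cp <- config$cna
    cp$seed <- derive_seed(seed, 31L)
    ws <- infer_cna_profiles(res$norm, role, cp)
    ws <- compute_cna_scores(ws)
    ws <- infer_subclones(ws)
    ws <- classify_malignant(ws)
    res$cna <<- ws
    note("cna", unclass(cp), dim(ws$cna))
  })

  run_stage("metaprograms", function() {
    ws <- res$cna
    mal <- ws$cell_meta$cell_id[!is.na(ws$call) & ws$call == "malignant"]
    np <- config$nmf
    np$seed <- derive_seed(seed, 41L)
    factors <- list()
    for (smp in unique(res$norm$cell_meta$sample)) {
      cells <- intersect(mal, res$norm$cell_meta$cell_id[
        res$norm$cell_meta$sample == smp])
      if (length(cells) < np$min_cells_per_sample) next
      idx <- match(cells, res$norm$cell_meta$cell_id)
      v <- res$norm$values[, idx, drop = FALSE]
      v <- v - rowMeans(v)
      fs <- run_sample_nmf(v, sample = smp,
                           patient = res$norm$cell_meta$patient[idx[1]],
                           params = np)
      if (is.null(fs)) next
      asg <- assign_cells_to_factors(v, fs, np)
      factors <- c(factors, fs[asg$kept])
    }
    res$factors <<- factors
    mcs <- cluster_factors(factors, np)
    res$metaprograms <<- derive_metaprograms(mcs, np)
    if (length(res$metaprograms)) {
      idx <- match(mal, res$norm$cell_meta$cell_id)
      nm <- res$norm
      nm$values <- nm$values[, idx, drop = FALSE]
      nm$cell_meta <- nm$cell_meta[idx, , drop = FALSE]
      res$mp_assignment <<- assign_cells_to_metaprograms(nm, res$metaprograms,
                                                         config$score)
    }
    note("metaprograms", unclass(np),
         c(length(factors), length(res$metaprograms)))
  })

  run_stage("lymphoid", function() {
    tnk <- which(res$lineage %in% c("T_CD8", "T_helper", "T_reg", "NK"))
    if (length(tnk) < 20) return(invisible(NULL))
    nm <- res$norm
    nm$values <- nm$values[, tnk, drop = FALSE]
    nm$cell_meta <- nm$cell_meta[tnk, , drop = FALSE]
    split <- split_t_nk(nm, config$tsub, config$score)
    t_cells <- tnk[split$class == "T"]
    cnts <- res$qc$counts[, t_cells, drop = FALSE]
    stringent <- stringent_t_rules(cnts)
    rescue <- knn_rescue(res$norm$values[, t_cells, drop = FALSE],
                         stringent, cnts, config$tsub)
    rescue$cell_id <- res$qc$cell_meta$cell_id[t_cells]
    res$t_nk <<- split
    res$t_subsets <<- rescue
    note("lymphoid", unclass(config$tsub), c(length(tnk), length(t_cells)))
  })

  run_stage("composition", function() {
    if (is.null(res$mp_assignment)) return(invisible(NULL))
    fr <- res$mp_assignment$fractions
    res$fraction_shift <<- metaprogram_fraction_shift(fr, config$comp)
    note("composition", unclass(config$comp), dim(fr))
  })

  run_stage("bulk", function() {
    config$sim$seed <- derive_seed(seed, 51L)
    bk <- simulate_bulk_cohort(config$sim)
    truth_type <- res$sim$truth$type[match(res$qc$cell_meta$cell_id,
                                           res$sim$truth$cell_id)]
    rp <- config$ref
    rp$min_cells_per_type <- min(rp$min_cells_per_type,
                                 max(50L, ncol(res$qc$counts) %/% 20))
    ref <- build_reference(res$qc, truth_type, bk$bulk, rp)
    est <- estimate_fractions(bk$bulk, ref$centroids)
    ifn_genes <- config$sim$program_spec[[1]]$genes
    prof <- malignant_profile_adjust(bk$bulk, ref$centroids, est$fractions,
                                     est$purity)
    score <- colMeans(prof$adjusted_log[
      intersect(ifn_genes, rownames(prof$adjusted_log)), , drop = FALSE])
    pre <- bk$bulk$sample_meta$timepoint == "pre"
    roc <- roc_auc(score[pre], bk$bulk$sample_meta$response[pre] == "R")
    res$bulk <<- list(cohort = bk, reference = ref, fractions = est,
                      malignant_profile = prof, score = score, roc = roc)
    note("bulk", unclass(rp), dim(bk$bulk$counts))
  })

  run_stage("spatial", function() {
    config$sim$seed <- seed
    sp <- simulate_spatial_table(config$sim)
    tab <- clr_normalize(sp$table)
    ph <- phenotype_cells(tab)
    dr <- call_hladr(tab, ph$phenotype)
    nb <- neighborhood_counts(tab, ph$phenotype)
    cmp <- compare_neighborhoods(nb, dr$positive, ph$phenotype == "Tumor")
    res$spatial <<- list(sim = sp, table = tab, phenotypes = ph, hladr = dr,
                         neighborhoods = nb, comparison = cmp)
    note("spatial", unclass(config$sim$spatial), dim(nb))
  })

  res$manifest <- do.call(rbind, manifest)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(res$manifest, file.path(config$out_dir, "manifest.csv"),
                     row.names = FALSE)
    if (!is.null(res$cna))
      utils::write.csv(data.frame(cell_id = res$cna$cell_meta$cell_id,
                                  subclone = res$cna$subclone,
                                  call = res$cna$call),
                       file.path(config$out_dir, "cna_calls.csv"),
                       row.names = FALSE)
    if (!is.null(res$metaprograms) && length(res$metaprograms))
      write_gmt(lapply(res$metaprograms, `[[`, "genes"),
                file.path(config$out_dir, "metaprograms.gmt"))
  }
  res
}
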