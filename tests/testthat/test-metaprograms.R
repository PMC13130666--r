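test_that("rank-2 planted factorization is recovered", {
  set.seed(1)
  ng <- 300; nc <- 80
  w1 <- c(runif(40, 2, 4), rep(0, ng - 40))
  w2 <- c(rep(0, ng - 40), runif(40, 2, 4))
  h1 <- runif(nc); h2 <- runif(nc)
  V <- outer(w1, h1) + outer(w2, h2)
  rownames(V) <- paste0("g", 1:ng)
  fs <- run_sample_nmf(V, params = nmf_params(rank = 2, restarts = 5,
                                              top_genes = 40, max_iter = 500,
                                              min_cells_per_sample = 10))
  true1 <- rownames(V)[1:40]; true2 <- rownames(V)[261:300]
  j <- sapply(fs, function(f) c(tumorstates:::jaccard(f$genes, true1),
                                tumorstates:::jaccard(f$genes, true2)))
  expect_gte(max(j[1, ]), 0.8)
  expect_gte(max(j[2, ]), 0.8)
})

test_that("the best-of-restarts error is the minimum over individual runs", {
  set.seed(2)
  V <- matrix(runif(100 * 30), 100, 30, dimnames = list(paste0("g", 1:100), NULL))
  p <- nmf_params(rank = 3, restarts = 4, min_cells_per_sample = 10,
                  max_iter = 50, seed = 7)
  fs <- run_sample_nmf(V, params = p)
  singles <- vapply(seq_len(p$restarts), function(r)
    tumorstates:::nmf_once(V, p$rank, p$sparsity, p$max_iter, p$tol,
                           seed = derive_seed(p$seed, 100L + r))$error, 0)
  expect_equal(fs[[1]]$error, min(singles))
})

test_that("samples below the cell minimum are skipped with a message", {
  V <- matrix(runif(50 * 29), 50, 29, dimnames = list(paste0("g", 1:50), NULL))
  expect_message(out <- run_sample_nmf(V, sample = "S29"), "skipped")
  expect_null(out)
})

test_that("factor gene lists are invariant to cell order", {
  set.seed(3)
  V <- matrix(runif(120 * 40), 120, 40, dimnames = list(paste0("g", 1:120), NULL))
  p <- nmf_params(rank = 3, restarts = 2, min_cells_per_sample = 10,
                  max_iter = 100, seed = 5)
  a <- run_sample_nmf(V, params = p)
  b <- run_sample_nmf(V[, sample(40)], params = p)
  expect_identical(lapply(a, `[[`, "genes"), lapply(b, `[[`, "genes"))
})

test_that("cells go to the factor with the highest mean expression", {
  set.seed(4)
  v <- matrix(rnorm(30 * 25), 30, 25, dimnames = list(paste0("g", 1:30), NULL))
  lists <- list(f1 = paste0("g", 1:10), f2 = paste0("g", 11:20),
                f3 = paste0("g", 21:30))
  ## a cell expressing only factor-1 genes is forced to factor 1
  v[1:10, 1] <- 5; v[11:30, 1] <- -5
  out <- assign_cells_to_factors(v, lists, nmf_params(min_cells_per_factor = 1))
  expect_equal(out$assignment[1], 1L)
  ## exhaustive argmax oracle
  oracle <- apply(sapply(lists, function(g) colMeans(v[g, ])), 1, which.max)
  expect_equal(out$assignment, unname(oracle))
  ## a factor attracting fewer than the minimum is not kept
  few <- assign_cells_to_factors(v, lists, nmf_params(min_cells_per_factor = 10))
  expect_identical(few$kept, few$n_cells >= 10)
})

test_that("Jaccard metaclustering groups and drops factors as constructed", {
  mk <- function(genes, patient) list(sample = patient, patient = patient,
                                      factor = 1, genes = genes)
  ## identical lists: same metacluster
  g <- paste0("g", 1:20)
  ## three lists with pairwise Jaccard 0.6 / 0.6 / ~0.54 plus one disjoint
  core <- paste0("x", 1:12)
  A <- c(core, paste0("ab", 1:3), paste0("ac", 1:3), paste0("ua", 1:2))
  B <- c(core, paste0("ab", 1:3), paste0("bc", 1:2), paste0("ub", 1:3))
  C <- c(core, paste0("ac", 1:3), paste0("bc", 1:2), paste0("uc", 1:3))
  expect_equal(tumorstates:::jaccard(A, B), 15 / 25)
  expect_equal(tumorstates:::jaccard(B, C), 14 / 26)
  lone <- paste0("z", 1:20)
  factors <- list(mk(A, "P1"), mk(B, "P2"), mk(C, "P3"), mk(lone, "P4"))
  mcs <- cluster_factors(factors, nmf_params())
  expect_length(mcs, 1)
  expect_setequal(mcs[[1]]$patients, c("P1", "P2", "P3"))
  ## disjoint factor has no partner at 0.2 and is gone
  expect_false("P4" %in% unlist(lapply(mcs, `[[`, "patients")))
  ## identical duplicated lists always co-cluster
  mcs2 <- cluster_factors(list(mk(g, "P1"), mk(g, "P2")), nmf_params())
  expect_length(mcs2, 1)
})

test_that("metaprogram consensus keeps strict patient majorities only", {
  mk <- function(genes, patient, id) list(sample = paste0(patient, "_s"),
                                          patient = patient, factor = id,
                                          genes = genes)
  shared <- paste0("s", 1:5)      # in all 4 patients
  three <- paste0("t", 1:5)       # in 3 of 4
  two <- paste0("w", 1:5)         # in exactly 2 of 4
  f <- list(mk(c(shared, three, two), "P1", 1),
            mk(c(shared, three, two), "P2", 1),
            mk(c(shared, three), "P3", 1),
            mk(shared, "P4", 1))
  mp <- derive_metaprograms(list(list(members = f,
                                      patients = c("P1", "P2", "P3", "P4"))))
  expect_setequal(mp$MP1$genes, c(shared, three))
  ## order of factors does not matter
  mp2 <- derive_metaprograms(list(list(members = rev(f),
                                       patients = c("P4", "P3", "P2", "P1"))))
  expect_setequal(mp2$MP1$genes, mp$MP1$genes)
  ## single-patient metaclusters never reach derive (cluster_factors filters)
  mcs <- cluster_factors(list(mk(shared, "P1", 1), mk(shared, "P1", 2)),
                         nmf_params())
  expect_length(mcs, 0)
})

test_that("metaprogram assignment partitions cells and breaks ties stably", {
  set.seed(5)
  mu <- rnorm(400, 0, 2)
  v <- matrix(rnorm(400 * 60, mean = mu), 400, 60,
              dimnames = list(paste0("g", 1:400), paste0("c", 1:60)))
  cm <- data.frame(cell_id = colnames(v),
                   patient = rep(c("P1", "P2"), each = 30),
                   timepoint = rep(c("pre", "post"), 30))
  norm <- normalized_matrix(v, cell_meta = cm, centered = TRUE)
  mps <- list(MPa = paste0("g", 1:30), MPb = paste0("g", 31:60))
  out <- assign_cells_to_metaprograms(norm, mps)
  fr <- out$fractions
  sums <- tapply(fr$fraction, paste(fr$patient, fr$timepoint), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  ## identical signatures tie on every cell: first name wins, flagged
  tie <- assign_cells_to_metaprograms(norm, list(A = mps$MPa, B = mps$MPa))
  expect_true(all(tie$assignment$metaprogram == "A"))
  expect_true(all(tie$assignment$tied))
})
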