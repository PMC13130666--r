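spatial_markers <- c("FOXP3", "CD4", "CD8", "CD3e", "NKG2A", "CD14", "CD163",
                     "CD68", "CD16a", "CD20", "TP63", "PanCK", "GZMK", "GZMB",
                     "TCF1", "PD1", "TOX", "HLA-DR")

## spatial table straight from a matrix of CLR values (raw intensities are
## reconstructed consistently so ratio predicates see matching values)
table_from_clr <- function(clr) {
  n <- nrow(clr)
  raw <- exp(clr + log(20)) - 1
  raw[raw < 0] <- 0
  df <- data.frame(cell_id = paste0("c", seq_len(n)),
                   x = runif(n, 0, 100), y = runif(n, 0, 100),
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(raw, optional = TRUE))
  tab <- spatial_cell_table(df, markers = colnames(clr))
  for (m in colnames(clr)) tab[[paste0("clr_", m)]] <- clr[, m]
  tab
}


## independent oracle for the printed two-pass gate hierarchy
gate_oracle <- function(z, raw) {
  pass1 <- function(v) {
    if (v["FOXP3"] > 1.4 && v["CD4"] > 1.1) return("Treg")
    if (v["CD8"] > 1.4 && v["CD3e"] > 1.0) return("CD8 T cell")
    if (v["CD4"] > 1.1 && v["CD3e"] > 1.1 && v["CD8"] < 1.4) return("CD4 T cell")
    if (v["NKG2A"] > 1.1 && v["CD3e"] < 1.1) return("NK cell")
    if ((v["CD14"] > 1.4 || v["CD163"] > 1.4 || v["CD68"] > 1.4 ||
         v["CD16a"] > 1.4) && v["CD20"] < 1.5) return("Macrophage")
    if (v["CD4"] > 1.1) return("CD4 T cell")
    if (v["CD20"] > 1.5) return("B cell")
    if (v["TP63"] > 1.0 || v["PanCK"] > 1.0) return("Tumor")
    "Stroma"
  }
  mts <- function(v) {   # macrophage/tumor/stroma fallback
    if ((v["CD14"] > 1.4 || v["CD163"] > 1.4 || v["CD68"] > 1.4 ||
         v["CD16a"] > 1.4) && v["CD20"] < 1.5) return("Macrophage")
    if (v["TP63"] > 1.0 || v["PanCK"] > 1.0) return("Tumor")
    "Stroma"
  }
  vapply(seq_len(nrow(z)), function(i) {
    v <- z[i, ]; r <- raw[i, ]
    p1 <- pass1(v)
    if (!p1 %in% c("CD8 T cell", "CD4 T cell", "Treg", "B cell", "NK cell"))
      return(p1)
    ratio <- (r["CD8"] + 1) / (r["CD4"] + 1)
    if (v["FOXP3"] > 1.4) return("Treg")
    if (v["NKG2A"] > 1.1 && v["CD3e"] < 1.1 && v["CD8"] < 1.4) return("NK cell")
    if (v["CD8"] > 1.4 && v["CD3e"] > 0.9 && ratio > 1.5 &&
        (v["GZMK"] > 1.1 || v["GZMB"] > 1.1 || v["TCF1"] > 0.9 ||
         v["PD1"] > 0.9 || v["CD8"] > 2)) return("CD8 T cell")
    if (v["CD4"] > 1.1 && v["CD3e"] > 0.9 && ratio < 1.5 &&
        (v["PD1"] > 0.9 || v["TOX"] > 0.9 || v["TCF1"] > 0.9))
      return("CD4 T cell")
    if (v["CD20"] > 1.5) return("B cell")
    mts(v)
  }, "")
}

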