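# Shared fixtures built in code at test time.

# tiny count matrix with explicit annotations
tiny_matrix <- function() {
  counts <- Matrix::sparseMatrix(i = c(1, 3), j = c(1, 2), x = c(5, 2),
                                 dims = c(3, 2))
  genes <- data.frame(gene_id = c("g1", "g2", "g3"),
                      symbol = c("MT-CO1", "ACTB", "CD3D"),
                      biotype = "protein_coding",
                      is_mito = c(TRUE, FALSE, FALSE),
                      is_ribo = FALSE, stringsAsFactors = FALSE)
  count_matrix(counts, genes, c("AAAC-1", "AAAG-1"))
}

# write a 10x triplet directory from raw pieces (used to exercise the reader
# with malformed inputs)
write_raw_10x <- function(dir, header, triplets, barcodes, features) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(c("%%MatrixMarket matrix coordinate integer general", header,
               triplets), file.path(dir, "matrix.mtx"))
  writeLines(barcodes, file.path(dir, "barcodes.tsv"))
  writeLines(features, file.path(dir, "features.tsv"))
  dir
}

# small synthetic sample reused across module tests (cached per session)
.test_sim_cache <- new.env(parent = emptyenv())
small_sim <- function() {
  if (is.null(.test_sim_cache$sim)) {
    spec <- synthetic_spec(
      n_cells = c(Melanoma = 340, T.cell = 260, Macrophage = 120,
                  B.cell = 100, NK = 60, Endothelial = 40),
      subclone_sizes = c(100, 90, 80, 70),
      n_low_genes = 30, n_high_mito = 25, n_doublet = 10, seed = 7)
    .test_sim_cache$sim <- simulate_sample(spec)
  }
  .test_sim_cache$sim
}

# QC-filtered and normalized small sample, with truth aligned to passing cells
small_norm <- function() {
  if (is.null(.test_sim_cache$norm)) {
    sim <- small_sim()
    mf <- filter_genes(sim$matrix)
    fc <- filter_cells(mf, min_genes = 400, mito_threshold = 0.25,
                       doublet_labels = sim$doublet_labels$is_doublet)
    norm <- normalize_counts(fc$matrix)
    truth <- sim$cell_truth[match(norm$barcodes, sim$cell_truth$barcode), ]
    .test_sim_cache$norm <- list(sim = sim, fc = fc, norm = norm, truth = truth)
  }
  .test_sim_cache$norm
}

# clustering + typing on the small sample
small_clustered <- function() {
  if (is.null(.test_sim_cache$clustered)) {
    sn <- small_norm()
    pcs <- residual_pca(sn$norm, 30)
    cl <- cluster_graph(build_knn_graph(pcs, k = 30), min_size = 20, seed = 1)
    calls <- classify_cells(sn$norm, sn$sim$hierarchy)
    .test_sim_cache$clustered <- c(sn, list(cl = cl, calls = calls))
  }
  .test_sim_cache$clustered
}

# DE contrasts on the small sample
small_de <- function() {
  if (is.null(.test_sim_cache$de)) {
    sc <- small_clustered()
    des <- tumor_contrasts(sc$norm, sc$cl, sc$calls, "Melanoma")
    .test_sim_cache$de <- c(sc, list(des = des))
  }
  .test_sim_cache$de
}

# minimal normalized_matrix stand-in for rank-based functions
fake_norm <- function(corrected, barcodes = colnames(corrected)) {
  structure(list(corrected_counts = corrected, barcodes = barcodes,
                 residuals = as.matrix(corrected)), class = "normalized_matrix")
}

# random interaction/evidence fixture over a gene universe
random_snapshot <- function(genes, n_inter = 8, n_evid = 5) {
  inter <- data.frame(
    gene = sample(genes, n_inter, replace = TRUE),
    drug = sample(sprintf("DRUG%02d", 1:6), n_inter, replace = TRUE),
    interaction_type = "inhibitor", source = "synth",
    stringsAsFactors = FALSE)
  inter <- unique(inter)
  evid <- data.frame(
    gene = sample(genes, n_evid, replace = TRUE),
    drug = sample(sprintf("DRUG%02d", 1:6), n_evid, replace = TRUE),
    expression_direction = sample(c("overexpression", "underexpression"), n_evid, TRUE),
    clinical_significance = sample(c("sensitivity", "resistance"), n_evid, TRUE),
    evidence_source = "synth", stringsAsFactors = FALSE)
  structure(list(interactions = inter, evidence = unique(evid)),
            class = "interaction_snapshot")
}

# fabricated de_result over a gene universe with chosen DE genes
fake_de <- function(genes, de_up = character(0), de_down = character(0),
                    cluster = "0") {
  tab <- data.frame(gene = genes, logFC = 0, t = 0, p_value = 1, fdr = 1,
                    is_de = FALSE, stringsAsFactors = FALSE)
  tab$logFC[tab$gene %in% de_up] <- 3
  tab$logFC[tab$gene %in% de_down] <- -3
  tab$is_de <- tab$gene %in% c(de_up, de_down)
  tab$fdr[tab$is_de] <- 1e-6
  tab$p_value[tab$is_de] <- 1e-8
  structure(list(table = tab, contrast = paste0("cluster_", cluster, "_vs_nonmalignant"),
                 reference_kind = "nonmalignant", target_cluster = cluster,
                 n_target = 50, n_reference = 100, fc_cut = 2, fdr_cut = 0.01),
            class = "de_result")
}
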