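#' Default pipeline configuration
#'
#' Returns the full configuration list with every tunable parameter at its
#' default; `paths` must be filled in (input MTX directory, marker file,
#' gene-set GMT, interaction/evidence snapshots, optional doublet labels,
#' output directory).
#'
#' @param input_dir 10x MTX triplet directory.
#' @param markers marker hierarchy TSV.
#' @param gmt gene-set GMT file.
#' @param interactions,evidence offline snapshot TSVs.
#' @param doublets optional doublet-label TSV (barcode, is_doublet).
#' @param outdir output directory.
#' @param seed RNG seed for clustering and embedding.
#' @return Named list of class `run_config`.
#' @export
default_config <- function(input_dir = NULL, markers = NULL, gmt = NULL,
                           interactions = NULL, evidence = NULL,
                           doublets = NULL, outdir = NULL, seed = 1L) {
  structure(list(
    paths = list(input_dir = input_dir, markers = markers, gmt = gmt,
                 interactions = interactions, evidence = evidence,
                 doublets = doublets, outdir = outdir),
    min_genes = 400, mito_threshold = "auto",
    keep_biotypes = "protein_coding", drop_ribo = TRUE,
    theta = 100, cc_s_genes = NULL, cc_g2m_genes = NULL,
    k_neighbors = 30, n_pcs = 30, min_cluster_size = 20,
    min_score = 0.6, margin = 0.05,
    fc_cut = 2, fdr_cut = 0.01, malignant_types = "Melanoma",
    min_set_size = 5, geneset_fdr_cut = 0.05,
    seed = seed), class = "run_config")
}

pipeline_steps <- c("qc", "normalize", "cluster", "celltype", "diffexp",
                    "genesets", "drugs")

validate_config <- function(config, steps = pipeline_steps) {
  req <- c(qc = "input_dir", celltype = "markers", genesets = "gmt",
           drugs = "interactions")
  paths <- config$paths
  need <- c("input_dir", if ("celltype" %in% steps) "markers",
            if ("genesets" %in% steps) "gmt",
            if ("drugs" %in% steps) c("interactions", "evidence"))
  for (p in need) {
    if (is.null(paths[[p]]))
      sc_stop("parameter_error", "config paths$%s is not set", p)
    if (!file.exists(paths[[p]]))
      sc_stop("validation_error", "config paths$%s does not exist: %s", p, paths[[p]])
  }
  if (is.null(paths$outdir)) sc_stop("parameter_error", "config paths$outdir is not set")
  dir.create(paths$outdir, showWarnings = FALSE, recursive = TRUE)
  invisible(TRUE)
}

state_path <- function(config, step) file.path(config$paths$outdir, sprintf("state_%s.rds", step))

load_state <- function(config, step) {
  p <- state_path(config, step)
  if (!file.exists(p))
    sc_stop("missing_prerequisite", "step '%s' has not been run (missing %s)", step, p)
  readRDS(p)
}

append_log <- function(config, step, t0, inputs, outputs) {
  log_file <- file.path(config$paths$outdir, "log.tsv")
  sums <- function(fs) paste(sprintf("%s=%s", basename(fs), tools::md5sum(fs)), collapse = ";")
  line <- data.frame(step = step,
                     wall_time_s = round(as.numeric(Sys.time()) - t0, 2),
                     inputs = sums(inputs[file.exists(inputs)]),
                     outputs = sums(outputs[file.exists(outputs)]),
                     stringsAsFactors = FALSE)
  utils::write.table(line, log_file, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = !file.exists(log_file), append = file.exists(log_file))
}

#' Run one pipeline stage from persisted intermediates
#'
#' Each stage reads its prerequisites from the output directory (or the raw
#' inputs), computes its result, writes its TSV outputs and a persisted state
#' file, and appends a log entry with wall time and input/output checksums.
#'
#' @param step one of qc, normalize, cluster, celltype, diffexp, genesets,
#'   drugs.
#' @param config a [default_config()] list.
#' @return Invisibly, the step's primary result object.
#' @export
run_step <- function(step, config) {
  if (!step %in% pipeline_steps)
    sc_stop("usage_error", "unknown step '%s'; valid steps: %s", step,
            paste(pipeline_steps, collapse = ", "))
  validate_config(config, steps = step)
  out <- config$paths$outdir
  t0 <- as.numeric(Sys.time())
  res <- switch(step,
    qc = {
      m <- read_10x_mtx(config$paths$input_dir)
      dbl <- NULL
      if (!is.null(config$paths$doublets) && file.exists(config$paths$doublets)) {
        tab <- utils::read.delim(config$paths$doublets, stringsAsFactors = FALSE)
        dbl <- as.logical(tab$is_doublet[match(m$barcodes, tab$barcode)])
        dbl[is.na(dbl)] <- FALSE
      }
      mf <- filter_genes(m, config$keep_biotypes, config$drop_ribo)
      fc <- filter_cells(mf, config$min_genes, config$mito_threshold, dbl)
      write_tsv(fc$qc, file.path(out, "qc_cells.tsv"))
      saveRDS(fc, state_path(config, "qc"))
      append_log(config, "qc", t0,
                 file.path(config$paths$input_dir, c("matrix.mtx", "barcodes.tsv", "features.tsv")),
                 file.path(out, "qc_cells.tsv"))
      fc
    },
    normalize = {
      fc <- load_state(config, "qc")
      cc <- NULL
      if (!is.null(config$cc_s_genes) || !is.null(config$cc_g2m_genes))
        cc <- list(s = config$cc_s_genes, g2m = config$cc_g2m_genes)
      norm <- normalize_counts(fc$matrix, theta = config$theta, cc_genes = cc)
      write_tsv(norm$cc_scores, file.path(out, "cell_cycle.tsv"))
      saveRDS(norm, state_path(config, "normalize"))
      append_log(config, "normalize", t0, state_path(config, "qc"),
                 file.path(out, "cell_cycle.tsv"))
      norm
    },
    cluster = {
      norm <- load_state(config, "normalize")
      pcs <- residual_pca(norm, config$n_pcs)
      g <- build_knn_graph(pcs, k = config$k_neighbors)
      cl <- cluster_graph(g, min_size = config$min_cluster_size, seed = config$seed)
      emb <- embed_2d(pcs, seed = config$seed)
      write_tsv(cl$assignment, file.path(out, "clusters.tsv"))
      write_tsv(emb, file.path(out, "embedding.tsv"))
      saveRDS(cl, state_path(config, "cluster"))
      append_log(config, "cluster", t0, state_path(config, "normalize"),
                 file.path(out, c("clusters.tsv", "embedding.tsv")))
      cl
    },
    celltype = {
      norm <- load_state(config, "normalize")
      cl <- load_state(config, "cluster")
      hier <- read_marker_hierarchy(config$paths$markers)
      calls <- classify_cells(norm, hier, config$min_score, config$margin)
      comp <- summarize_composition(calls, cl)
      write_tsv(calls$calls, file.path(out, "celltype_calls.tsv"))
      write_tsv(comp$overall, file.path(out, "composition_overall.tsv"))
      write_tsv(comp$per_cluster, file.path(out, "composition_per_cluster.tsv"))
      write_tsv(comp$dominant, file.path(out, "composition_dominant.tsv"))
      saveRDS(calls, state_path(config, "celltype"))
      append_log(config, "celltype", t0,
                 c(state_path(config, "normalize"), state_path(config, "cluster"),
                   config$paths$markers),
                 file.path(out, c("celltype_calls.tsv", "composition_overall.tsv",
                                  "composition_per_cluster.tsv", "composition_dominant.tsv")))
      calls
    },
    diffexp = {
      norm <- load_state(config, "normalize")
      cl <- load_state(config, "cluster")
      calls <- load_state(config, "celltype")
      des <- tumor_contrasts(norm, cl, calls, config$malignant_types,
                             config$fc_cut, config$fdr_cut, config$min_cluster_size)
      outs <- character()
      for (nm in names(des)) {
        f <- file.path(out, sprintf("de_%s.tsv", nm))
        write_tsv(des[[nm]]$table, f)
        outs <- c(outs, f)
      }
      saveRDS(des, state_path(config, "diffexp"))
      append_log(config, "diffexp", t0,
                 state_path(config, c("normalize", "cluster", "celltype")), outs)
      des
    },
    genesets = {
      norm <- load_state(config, "normalize")
      cl <- load_state(config, "cluster")
      des <- load_state(config, "diffexp")
      sets <- read_gmt(config$paths$gmt)
      outs <- character()
      gs <- list()
      for (nm in names(des)) {
        de <- des[[nm]]
        if (!identical(de$reference_kind, "nonmalignant")) next
        gs[[nm]] <- competitive_test(de, sets, residuals = norm$residuals,
                                     min_set_size = config$min_set_size)
        f <- file.path(out, sprintf("pathways_%s.tsv", nm))
        write_tsv(gs[[nm]]$table, f)
        outs <- c(outs, f)
      }
      scores <- per_cell_set_score(norm, sets, config$min_set_size)
      sc_df <- data.frame(barcode = rownames(scores), scores, check.names = FALSE,
                          stringsAsFactors = FALSE)
      write_tsv(sc_df, file.path(out, "cell_set_scores.tsv"))
      med <- summarize_cluster_pathways(scores, cl)
      write_tsv(med, file.path(out, "cluster_pathways.tsv"))
      saveRDS(list(tests = gs, scores = scores, cluster_medians = med),
              state_path(config, "genesets"))
      append_log(config, "genesets", t0,
                 c(state_path(config, c("normalize", "cluster", "diffexp")),
                   config$paths$gmt),
                 c(outs, file.path(out, c("cell_set_scores.tsv", "cluster_pathways.tsv"))))
      list(tests = gs, scores = scores, cluster_medians = med)
    },
    drugs = {
      cl <- load_state(config, "cluster")
      des <- load_state(config, "diffexp")
      snap <- read_interaction_snapshot(config$paths$interactions, config$paths$evidence)
      vs_nonmal <- Filter(function(d) identical(d$reference_kind, "nonmalignant"), des)
      cands <- identify_candidates(vs_nonmal, snap)
      dom <- vapply(vs_nonmal, function(d) d$target_cluster, character(1))
      summ <- per_cluster_drug_summary(cands, cl, tumor_clusters = unname(dom))
      write_tsv(cands, file.path(out, "drug_candidates.tsv"))
      write_tsv(summ$summary, file.path(out, "drug_summary.tsv"))
      flags <- data.frame(barcode = rownames(summ$cell_flags), summ$cell_flags,
                          check.names = FALSE, stringsAsFactors = FALSE)
      write_tsv(flags, file.path(out, "drug_cell_flags.tsv"))
      saveRDS(list(candidates = cands, summary = summ), state_path(config, "drugs"))
      append_log(config, "drugs", t0,
                 c(state_path(config, c("cluster", "diffexp")),
                   config$paths$interactions, config$paths$evidence),
                 file.path(out, c("drug_candidates.tsv", "drug_summary.tsv",
                                  "drug_cell_flags.tsv")))
      list(candidates = cands, summary = summ)
    })
  invisible(res)
}

#' Run the complete pipeline end to end
#'
#' Validates every referenced input path up front, then executes
#' qc, normalize, cluster, celltype, diffexp, genesets and drugs in order.
#' Any step error aborts the run (earlier steps' outputs stay on disk and can
#' be resumed with [run_step()]). Finishes by writing a manifest listing
#' every produced file with its MD5 checksum.
#'
#' @param config a [default_config()] list with paths filled in.
#' @return Invisibly, the manifest data.frame.
#' @export
run_all <- function(config) {
  validate_config(config, steps = pipeline_steps)
  for (step in pipeline_steps) run_step(step, config)
  out <- config$paths$outdir
  files <- sort(setdiff(list.files(out, pattern = "\\.tsv$"),
                        c("log.tsv", "manifest.tsv")))
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(out, files))),
                         stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(out, "manifest.tsv"))
  invisible(manifest)
}
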