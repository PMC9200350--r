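#' Specification for a synthetic tumor-biopsy sample
#'
#' Defines the planted ground truth of a desk-scale synthetic droplet
#' scRNA-seq experiment emulating a tumor biopsy: several cell-type
#' populations with over-expressed marker genes, a tumor population split
#' into subclones with planted DE genes and a planted suppressed pathway,
#' two T-cell subtypes, log-normal library-size variation, a beta-distributed
#' mitochondrial read fraction, and planted QC-failure cells that each
#' violate exactly one filter with a wide margin. Counts follow a negative
#' binomial with dispersion 0.1.
#'
#' Defaults mirror a single melanoma biopsy at full scale: 4193 cells of
#' which 437 are planted low-quality (so 3756 pass QC), a melanoma
#' population at 34% of passing cells split into four subclones, and 2000
#' genes.
#'
#' @param n_cells named integer vector of passing cells per major type.
#' @param subclone_sizes integer vector partitioning the tumor population.
#' @param n_genes total genes including mito/ribo/non-coding decoys.
#' @param n_markers markers per major type.
#' @param marker_log2fc log2 over-expression of markers in their type.
#' @param n_de_per_subclone planted subclone-private DE genes.
#' @param de_log2fc log2 effect of subclone DE genes.
#' @param n_shared_de genes over-expressed in every tumor subclone (the
#'   drug-target case spanning the whole tumor population).
#' @param pathway_size size of the planted pathway gene set.
#' @param pathway_log2fc log2 suppression of the pathway in all but the
#'   first subclone (negative).
#' @param n_low_genes,n_high_mito,n_doublet planted QC failures per category.
#' @param depth_meanlog,depth_sdlog log-normal library-size parameters.
#' @param mito_shape1,mito_shape2 beta parameters of the mito fraction.
#' @param dispersion negative binomial dispersion (size = 1/dispersion).
#' @param tumor_type name of the malignant population.
#' @param seed RNG seed.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(
    n_cells = c(Melanoma = 1277, T.cell = 1130, Macrophage = 520,
                B.cell = 400, NK = 250, Endothelial = 179),
    subclone_sizes = c(400, 350, 300, 227),
    n_genes = 2000,
    n_markers = 20, marker_log2fc = 2,
    n_de_per_subclone = 30, de_log2fc = 3,
    n_shared_de = 10,
    pathway_size = 40, pathway_log2fc = -1,
    n_low_genes = 200, n_high_mito = 187, n_doublet = 50,
    depth_meanlog = log(5000), depth_sdlog = 0.3,
    mito_shape1 = 10, mito_shape2 = 190,
    dispersion = 0.1,
    tumor_type = "Melanoma",
    seed = 1L) {
  if (!tumor_type %in% names(n_cells))
    sc_stop("spec_error", "tumor_type '%s' not among cell types", tumor_type)
  if (sum(subclone_sizes) != n_cells[[tumor_type]])
    sc_stop("spec_error", "subclone sizes must sum to the tumor population size")
  n_special <- length(n_cells) * n_markers + 2 * 10 +       # majors + 2 T subtypes
    length(subclone_sizes) * n_de_per_subclone + n_shared_de + pathway_size
  n_mito <- 10; n_ribo <- 20; n_noncoding <- 50
  if (n_special + n_mito + n_ribo + n_noncoding >= n_genes)
    sc_stop("spec_error", "n_genes too small for the planted gene roles")
  structure(mget(names(formals(synthetic_spec))), class = "synthetic_spec")
}

# assign disjoint gene roles over the analysis genes; planted roles are drawn
# from `pool` (well-expressed genes, so planted fold changes survive the
# pseudocount on the count scale)
assign_gene_roles <- function(spec, symbols, pool) {
  roles <- stats::setNames(rep("background", length(symbols)), symbols)
  take <- function(n) {
    g <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    g
  }
  out <- list()
  for (ty in names(spec$n_cells)) out[[paste0("marker:", ty)]] <- take(spec$n_markers)
  out[["marker:T.mem"]] <- take(10)
  out[["marker:T.reg"]] <- take(10)
  for (s in seq_along(spec$subclone_sizes)) out[[paste0("de:subclone", s)]] <- take(spec$n_de_per_subclone)
  out[["de:shared_tumor"]] <- take(spec$n_shared_de)
  out[["pathway:SYNTH_MAPK"]] <- take(spec$pathway_size)
  for (nm in names(out)) roles[out[[nm]]] <- nm
  list(roles = roles, sets = out)
}

#' Generate a synthetic sample with planted ground truth
#'
#' Draws the count matrix described by a [synthetic_spec()] and, when
#' `dir_path` is given, writes a complete pipeline input set: the 10x-style
#' MTX triplet, doublet labels, the marker hierarchy, the gene-set GMT
#' (planted pathway plus random decoy sets), and truth tables for cells and
#' genes.
#'
#' @param spec a [synthetic_spec()].
#' @param dir_path optional output directory.
#' @return List with `matrix` ([count_matrix()]), `cell_truth`, `gene_truth`,
#'   `hierarchy`, `gene_sets`, `doublet_labels`, `sets` (planted gene role
#'   sets) and `spec`.
#' @export
simulate_sample <- function(spec, dir_path = NULL) {
  set.seed(spec$seed)
  size <- 1 / spec$dispersion
  n_mito <- 10; n_ribo <- 20; n_noncoding <- 50
  n_analysis <- spec$n_genes - n_mito - n_ribo - n_noncoding

  sym_analysis <- sprintf("GENE%04d", seq_len(n_analysis))
  sym_mito <- sprintf("MT-SYN%d", seq_len(n_mito))
  sym_ribo <- c(sprintf("RPS-SYN%d", seq_len(n_ribo / 2)),
                sprintf("RPL-SYN%d", seq_len(n_ribo / 2)))
  sym_nc <- sprintf("LINC%04d", seq_len(n_noncoding))
  symbols <- c(sym_analysis, sym_mito, sym_ribo, sym_nc)
  biotype <- c(rep("protein_coding", n_analysis + n_mito + n_ribo),
               rep("lincRNA", n_noncoding))
  genes <- data.frame(gene_id = sprintf("SYNG%05d", seq_along(symbols)),
                      symbol = symbols, biotype = biotype,
                      is_mito = startsWith(symbols, "MT-"),
                      is_ribo = startsWith(symbols, "RPS") | startsWith(symbols, "RPL"),
                      stringsAsFactors = FALSE)

  # baseline relative expression for analysis + ribo + noncoding genes
  w <- stats::setNames(stats::rlnorm(length(symbols), 0, 1), symbols)
  w[sym_mito] <- 0   # mito handled through the planted per-cell fraction

  # planted roles go to well-expressed genes (upper third of baseline
  # expression): planted fold changes are diluted by the compositional
  # renormalization of the extra planted transcript mass, and on a weakly
  # expressed gene the count-scale pseudocount would further shrink an
  # 8-fold effect below the |logFC| > 2 call
  eligible <- sample(sym_analysis[w[sym_analysis] >= stats::quantile(w[sym_analysis], 2 / 3)])
  ra <- assign_gene_roles(spec, sym_analysis, eligible)
  roles <- c(ra$roles,
             stats::setNames(rep("mito", n_mito), sym_mito),
             stats::setNames(rep("ribo", n_ribo), sym_ribo),
             stats::setNames(rep("excluded_biotype", n_noncoding), sym_nc))

  # group table: one row per (type, subclone) population of passing cells
  groups <- list()
  for (ty in names(spec$n_cells)) {
    if (ty == spec$tumor_type) {
      for (s in seq_along(spec$subclone_sizes))
        groups[[paste0(ty, ".", s)]] <- list(type = ty, subclone = s,
                                             n = spec$subclone_sizes[s])
    } else {
      groups[[ty]] <- list(type = ty, subclone = NA_integer_, n = spec$n_cells[[ty]])
    }
  }

  mult_for_group <- function(g) {
    m <- stats::setNames(rep(1, length(symbols)), symbols)
    m[ra$sets[[paste0("marker:", g$type)]]] <- 2^spec$marker_log2fc
    if (!is.na(g$subclone)) {
      m[ra$sets[[paste0("de:subclone", g$subclone)]]] <- 2^spec$de_log2fc
      m[ra$sets[["de:shared_tumor"]]] <- 2^spec$de_log2fc
      if (g$subclone > 1)
        m[ra$sets[["pathway:SYNTH_MAPK"]]] <- 2^spec$pathway_log2fc
    }
    m
  }

  draw_group <- function(g, depths, fmito, tsub = NULL) {
    m <- mult_for_group(g)
    if (!is.null(tsub)) m[ra$sets[[paste0("marker:", tsub)]]] <- 2^spec$marker_log2fc
    wg <- w * m
    p <- wg / sum(wg)
    mu <- outer(p, depths * (1 - fmito))
    cnt <- matrix(stats::rnbinom(length(mu), mu = mu, size = size), nrow = nrow(mu))
    mu_m <- outer(rep(1 / n_mito, n_mito), depths * fmito)
    cnt[match(sym_mito, symbols), ] <- matrix(
      stats::rnbinom(length(mu_m), mu = mu_m, size = size), nrow = n_mito)
    cnt
  }

  cols <- list(); truth <- list()
  for (nm in names(groups)) {
    g <- groups[[nm]]
    depths <- stats::rlnorm(g$n, spec$depth_meanlog, spec$depth_sdlog)
    fmito <- stats::rbeta(g$n, spec$mito_shape1, spec$mito_shape2)
    if (g$type == "T.cell") {
      half <- g$n %/% 2
      subty <- c(rep("T.mem", half), rep("T.reg", g$n - half))
      cnt <- cbind(draw_group(g, depths[seq_len(half)], fmito[seq_len(half)], "T.mem"),
                   draw_group(g, depths[-seq_len(half)], fmito[-seq_len(half)], "T.reg"))
    } else {
      subty <- rep(NA_character_, g$n)
      cnt <- draw_group(g, depths, fmito)
    }
    cols[[nm]] <- cnt
    truth[[nm]] <- data.frame(type = g$type, subtype = subty,
                              subclone = g$subclone, failure_category = "pass",
                              stringsAsFactors = FALSE)
  }
  pass_counts <- do.call(cbind, cols)
  pass_truth <- do.call(rbind, truth)

  # planted failures --------------------------------------------------------
  # low_genes: counts restricted to 150 genes, far below the min_genes cutoff
  lg <- matrix(0, length(symbols), spec$n_low_genes)
  for (i in seq_len(spec$n_low_genes)) {
    pick <- sample(which(biotype == "protein_coding" & !symbols %in% sym_mito), 150)
    lg[pick, i] <- stats::rnbinom(150, mu = 400 / 150, size = size)
  }
  # high_mito: mito fraction 0.7, far above the 0.25 cutoff; depth floored at
  # the median so the 30% non-mito budget still clears the gene filter widely
  ghm <- list(type = "Melanoma", subclone = 1L)
  hm_depth <- pmax(stats::rlnorm(spec$n_high_mito, spec$depth_meanlog, spec$depth_sdlog),
                   exp(spec$depth_meanlog))
  hm <- draw_group(ghm, hm_depth, rep(0.7, spec$n_high_mito))
  # doublet: sum of two random passing cells' count vectors
  p1 <- sample(ncol(pass_counts), spec$n_doublet)
  p2 <- sample(ncol(pass_counts), spec$n_doublet)
  db <- pass_counts[, p1, drop = FALSE] + pass_counts[, p2, drop = FALSE]

  counts <- cbind(pass_counts, lg, hm, db)
  fail_truth <- data.frame(
    type = c(rep(NA_character_, spec$n_low_genes + spec$n_high_mito),
             pass_truth$type[p1]),
    subtype = NA_character_,
    subclone = NA_integer_,
    failure_category = c(rep("low_genes", spec$n_low_genes),
                         rep("high_mito", spec$n_high_mito),
                         rep("doublet", spec$n_doublet)),
    stringsAsFactors = FALSE)
  cell_truth <- rbind(pass_truth, fail_truth)

  # shuffle cells so column order carries no information
  ord <- sample(ncol(counts))
  counts <- counts[, ord, drop = FALSE]
  cell_truth <- cell_truth[ord, , drop = FALSE]
  barcodes <- sprintf("CELL%05d-1", seq_len(ncol(counts)))
  cell_truth <- cbind(data.frame(barcode = barcodes, stringsAsFactors = FALSE),
                      cell_truth)
  rownames(cell_truth) <- NULL
  m <- count_matrix(Matrix::Matrix(counts, sparse = TRUE), genes, barcodes)

  # verify that each planted cell lands in its category under the emitted
  # thresholds (min_genes = 400, mito_threshold = 0.25); the construction
  # margins make this deterministic, and any violation is a generator bug
  qc_genes <- genes$biotype == "protein_coding" & !genes$is_ribo
  sub <- m$counts[qc_genes, , drop = FALSE]
  n_genes_cell <- Matrix::colSums(sub > 0)
  fm <- Matrix::colSums(sub[genes$is_mito[qc_genes], , drop = FALSE]) /
    pmax(Matrix::colSums(sub), 1)
  realized <- ifelse(n_genes_cell < 400, "low_genes",
              ifelse(fm > 0.25, "high_mito",
              ifelse(cell_truth$failure_category == "doublet", "doublet", "pass")))
  if (!identical(unname(realized), cell_truth$failure_category))
    sc_stop("spec_error", "planted QC category violated for %d cell(s)",
            sum(realized != cell_truth$failure_category))

  gene_truth <- data.frame(symbol = symbols, role = unname(roles[symbols]),
                           baseline_weight = unname(w[symbols]),
                           stringsAsFactors = FALSE)
  hierarchy <- marker_hierarchy(
    major = lapply(stats::setNames(names(spec$n_cells), names(spec$n_cells)),
                   function(ty) ra$sets[[paste0("marker:", ty)]]),
    sub = list(T.cell = list(T.mem = ra$sets[["marker:T.mem"]],
                             T.reg = ra$sets[["marker:T.reg"]])))
  # gene sets: the planted pathway plus random decoy sets of background genes
  bg <- names(roles)[roles == "background"]
  gene_sets <- c(list(SYNTH_MAPK = ra$sets[["pathway:SYNTH_MAPK"]]),
                 lapply(stats::setNames(1:5, sprintf("DECOY_SET_%d", 1:5)),
                        function(i) sample(bg, 40)))
  doublet_labels <- data.frame(barcode = barcodes,
                               is_doublet = cell_truth$failure_category == "doublet",
                               stringsAsFactors = FALSE)
  out <- list(matrix = m, cell_truth = cell_truth, gene_truth = gene_truth,
              hierarchy = hierarchy, gene_sets = gene_sets,
              doublet_labels = doublet_labels, sets = ra$sets, spec = spec)
  if (!is.null(dir_path)) write_synthetic_inputs(out, dir_path)
  out
}

write_synthetic_inputs <- function(sim, dir_path) {
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  write_10x_mtx(sim$matrix, file.path(dir_path, "counts"))
  write_tsv(sim$cell_truth, file.path(dir_path, "cell_truth.tsv"))
  write_tsv(sim$gene_truth, file.path(dir_path, "gene_truth.tsv"))
  write_tsv(sim$doublet_labels, file.path(dir_path, "doublet_labels.tsv"))
  h <- sim$hierarchy
  rows <- lapply(names(h$major), function(ty)
    data.frame(level = "major", name = ty, parent = "",
               genes = paste(h$major[[ty]], collapse = ","), stringsAsFactors = FALSE))
  for (p in names(h$sub)) for (s in names(h$sub[[p]]))
    rows[[length(rows) + 1L]] <- data.frame(level = "sub", name = s, parent = p,
                                            genes = paste(h$sub[[p]][[s]], collapse = ","),
                                            stringsAsFactors = FALSE)
  write_tsv(do.call(rbind, rows), file.path(dir_path, "markers.tsv"))
  write_gmt(sim$gene_sets, file.path(dir_path, "gene_sets.gmt"))
  invisible(dir_path)
}

#' Build an offline drug-interaction fixture matched to planted ground truth
#'
#' Produces an interaction/evidence snapshot wired to the generator's truth:
#' the first shared tumor DE gene is paired with a palbociclib-like drug and
#' an (overexpression, sensitivity) evidence record so the directed candidate
#' spans every tumor subclone; additional interactions cover subclone-private
#' DE genes with varied evidence, plus decoy interactions on background
#' (non-DE) genes that must never surface as candidates.
#'
#' @param sim result of [simulate_sample()].
#' @param dir_path optional directory to write `interactions.tsv` and
#'   `evidence.tsv`.
#' @return An `interaction_snapshot`.
#' @export
make_drug_fixture <- function(sim, dir_path = NULL) {
  shared <- sim$sets[["de:shared_tumor"]]
  # the pan-tumor sensitive pair goes on the best-expressed shared gene
  wts <- sim$gene_truth$baseline_weight[match(shared, sim$gene_truth$symbol)]
  shared <- shared[order(-wts)]
  sub1 <- sim$sets[["de:subclone1"]]
  sub2 <- sim$sets[["de:subclone2"]]
  bg <- sim$gene_truth$symbol[sim$gene_truth$role == "background"]
  inter <- rbind(
    data.frame(gene = shared[1], drug = "PALBOSYN", interaction_type = "inhibitor",
               source = "synthetic_dgidb", stringsAsFactors = FALSE),
    data.frame(gene = shared[2], drug = "SHAREDRUG2", interaction_type = "inhibitor",
               source = "synthetic_dgidb", stringsAsFactors = FALSE),
    data.frame(gene = sub1[1], drug = "CLONEDRUG1", interaction_type = "antagonist",
               source = "synthetic_dgidb", stringsAsFactors = FALSE),
    data.frame(gene = sub2[1], drug = "CLONEDRUG2", interaction_type = "inhibitor",
               source = "synthetic_dgidb", stringsAsFactors = FALSE),
    data.frame(gene = bg[1:5], drug = sprintf("DECOYDRUG%d", 1:5),
               interaction_type = "inhibitor", source = "synthetic_dgidb",
               stringsAsFactors = FALSE))
  evid <- rbind(
    data.frame(gene = shared[1], drug = "PALBOSYN",
               expression_direction = "overexpression",
               clinical_significance = "sensitivity",
               evidence_source = "synthetic_civic", stringsAsFactors = FALSE),
    data.frame(gene = sub1[1], drug = "CLONEDRUG1",
               expression_direction = "overexpression",
               clinical_significance = "resistance",
               evidence_source = "synthetic_civic", stringsAsFactors = FALSE),
    # direction-inconsistent evidence: an up-regulated gene with
    # underexpression evidence must never direct a candidate
    data.frame(gene = sub2[1], drug = "CLONEDRUG2",
               expression_direction = "underexpression",
               clinical_significance = "sensitivity",
               evidence_source = "synthetic_civic", stringsAsFactors = FALSE))
  if (!is.null(dir_path)) {
    dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
    write_tsv(inter, file.path(dir_path, "interactions.tsv"))
    write_tsv(evid, file.path(dir_path, "evidence.tsv"))
  }
  structure(list(interactions = inter, evidence = evid),
            class = "interaction_snapshot")
}
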