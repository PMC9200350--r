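#' Filter genes by biotype and ribosomal status
#'
#' Keeps genes whose biotype is in `keep_biotypes` (default protein coding
#' only) and, when `drop_ribo`, removes ribosomal-protein genes.
#' Mitochondrial genes passing the biotype filter are retained (still flagged)
#' so that the mitochondrial read fraction can be computed during cell QC;
#' they are dropped later by [filter_cells()]. After filtering, gene identity
#' collapses to the symbol: duplicate symbols keep the highest-total-count
#' copy and the drop is logged.
#'
#' @param m a [count_matrix()].
#' @param keep_biotypes character set of biotypes to retain.
#' @param drop_ribo drop ribosomal-protein genes?
#' @return A filtered [count_matrix()] with row order preserved.
#' @export
filter_genes <- function(m, keep_biotypes = "protein_coding", drop_ribo = TRUE) {
  if (!length(keep_biotypes))
    sc_stop("pipeline_error", "keep_biotypes is empty: zero genes would remain")
  keep <- m$genes$biotype %in% keep_biotypes
  if (drop_ribo) keep <- keep & !m$genes$is_ribo
  if (!any(keep)) sc_stop("pipeline_error", "no genes remain after biotype/ribo filter")
  counts <- m$counts[keep, , drop = FALSE]
  genes <- m$genes[keep, , drop = FALSE]
  # collapse to symbol identity: keep the highest-total-count duplicate
  if (anyDuplicated(genes$symbol)) {
    tot <- Matrix::rowSums(counts)
    ord <- order(genes$symbol, -tot)
    dup <- duplicated(genes$symbol[ord])
    drop_idx <- sort(ord[dup])
    sc_log("dropping %d duplicate gene symbol(s): %s", length(drop_idx),
           paste(unique(genes$symbol[drop_idx]), collapse = ", "))
    keep2 <- setdiff(seq_len(nrow(genes)), drop_idx)
    counts <- counts[keep2, , drop = FALSE]
    genes <- genes[keep2, , drop = FALSE]
  }
  rownames(genes) <- NULL
  count_matrix(counts, genes, m$barcodes)
}

#' Estimate the mitochondrial-fraction cutoff from the data
#'
#' Robust upper fence: median plus three normal-consistent MADs of the
#' per-cell mitochondrial UMI fraction, clamped to the interval
#' \[0.05, 0.6\]. Requires at least 20 cells; below that the caller must
#' supply a threshold.
#'
#' @param frac_mito numeric vector of per-cell mito fractions in \[0,1\].
#' @return A single threshold in \[0.05, 0.6\].
#' @export
estimate_mito_threshold <- function(frac_mito) {
  if (length(frac_mito) < 20)
    sc_stop("parameter_error",
            "need >= 20 cells to estimate the mito threshold; supply mito_threshold explicitly")
  thr <- stats::median(frac_mito) + 3 * stats::mad(frac_mito)
  min(max(thr, 0.05), 0.6)
}

#' Filter cells by expressed-gene count, mitochondrial fraction and doublets
#'
#' Each cell is assigned exactly one category with fixed precedence:
#' `low_genes` (fewer than `min_genes` genes with nonzero counts), else
#' `high_mito` (mito fraction above `mito_threshold`), else `doublet`
#' (external label), else `pass`. Only passing cells are retained, and
#' mitochondrial genes are dropped from the returned matrix (their job -- the
#' QC fraction -- is done).
#'
#' @param m a [count_matrix()] (gene-filtered, mito genes still present).
#' @param min_genes minimum number of expressed genes per cell.
#' @param mito_threshold maximum mitochondrial UMI fraction, in (0, 1];
#'   `"auto"` estimates it via [estimate_mito_threshold()].
#' @param doublet_labels optional logical vector (one per cell) from an
#'   external doublet caller; `NULL` means no doublet information.
#' @return List with `matrix` (passing cells, mito genes dropped) and `qc`
#'   (data.frame with barcode, n_counts, n_genes, frac_mito, is_doublet,
#'   filter_category for every input cell).
#' @export
filter_cells <- function(m, min_genes = 400, mito_threshold = "auto",
                         doublet_labels = NULL) {
  if (min_genes < 0) sc_stop("parameter_error", "min_genes must be >= 0")
  n_counts <- Matrix::colSums(m$counts)
  n_genes <- Matrix::colSums(m$counts > 0)
  mito_counts <- Matrix::colSums(m$counts[m$genes$is_mito, , drop = FALSE])
  frac_mito <- ifelse(n_counts > 0, mito_counts / n_counts, 0)
  if (identical(mito_threshold, "auto"))
    mito_threshold <- estimate_mito_threshold(frac_mito)
  if (!is.numeric(mito_threshold) || mito_threshold <= 0 || mito_threshold > 1)
    sc_stop("parameter_error", "mito_threshold must be in (0, 1]")
  if (is.null(doublet_labels)) doublet_labels <- rep(FALSE, ncol(m$counts))
  if (length(doublet_labels) != ncol(m$counts))
    sc_stop("parameter_error", "doublet_labels length != number of cells")
  category <- ifelse(n_genes < min_genes, "low_genes",
              ifelse(frac_mito > mito_threshold, "high_mito",
              ifelse(doublet_labels, "doublet", "pass")))
  qc <- data.frame(barcode = m$barcodes,
                   n_counts = as.numeric(n_counts),
                   n_genes = as.integer(n_genes),
                   frac_mito = as.numeric(frac_mito),
                   is_doublet = as.logical(doublet_labels),
                   filter_category = category,
                   stringsAsFactors = FALSE)
  pass <- category == "pass"
  if (!any(pass)) sc_stop("pipeline_error", "zero cells pass QC")
  keep_genes <- !m$genes$is_mito
  out <- count_matrix(m$counts[keep_genes, pass, drop = FALSE],
                      m$genes[keep_genes, , drop = FALSE],
                      m$barcodes[pass])
  list(matrix = out, qc = qc, mito_threshold = mito_threshold)
}
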