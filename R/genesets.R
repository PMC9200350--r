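#' Competitive gene-set test on differential-expression statistics
#'
#' For each gene set, asks whether its genes are more differentially
#' expressed than the genes outside it, accounting for inter-gene
#' correlation. The statistic is the difference between the mean t-statistic
#' of in-set genes and that of out-of-set genes, standardized by the pooled
#' t variance and inflated by a variance inflation factor
#' VIF = 1 + (m - 1) * rho, where rho is the mean pairwise correlation of
#' the in-set genes' residual expression across cells (floored at 0).
#' Two-sided p-values come from the normal approximation;
#' Benjamini-Hochberg correction is applied across sets.
#'
#' Direction is `up`/`down` by the sign of the in-set shift, or `mixed` when
#' the set contains both significantly over- and under-expressed genes at
#' the DE module's own cutoffs.
#'
#' @param de a `de_result`.
#' @param sets named list of gene symbol vectors.
#' @param residuals optional gene x cell residual matrix for the contrast's
#'   cells, used to estimate the inter-gene correlation; `NULL` assumes
#'   independence (VIF = 1).
#' @param min_set_size sets with fewer universe genes are skipped (default 5).
#' @return Object of class `geneset_result`: data.frame set, n_genes,
#'   direction, z, p_value, fdr.
#' @export
competitive_test <- function(de, sets, residuals = NULL, min_set_size = 5) {
  tab <- de$table
  universe <- tab$gene
  G <- length(universe)
  tstat <- tab$t
  s2_t <- stats::var(tstat)
  rows <- list()
  for (nm in names(sets)) {
    idx <- which(universe %in% sets[[nm]])
    m <- length(idx)
    if (m < min_set_size || m > G - 2) {
      sc_log("gene set '%s' skipped: %d universe gene(s)", nm, m)
      next
    }
    delta <- mean(tstat[idx]) - mean(tstat[-idx])
    rho <- 0
    if (!is.null(residuals) && m >= 2) {
      cr <- suppressWarnings(stats::cor(t(residuals[universe[idx], , drop = FALSE])))
      cr[is.na(cr)] <- 0
      rho <- max(0, mean(cr[upper.tri(cr)]))
    }
    vif <- 1 + (m - 1) * rho
    z <- delta / sqrt(vif * (1 / m + 1 / (G - m)) * s2_t)
    sig_up <- sum(tab$fdr[idx] < de$fdr_cut & tab$logFC[idx] > de$fc_cut)
    sig_dn <- sum(tab$fdr[idx] < de$fdr_cut & tab$logFC[idx] < -de$fc_cut)
    direction <- if (sig_up > 0 && sig_dn > 0) "mixed" else if (delta >= 0) "up" else "down"
    rows[[nm]] <- data.frame(set = nm, n_genes = m, direction = direction,
                             z = z, p_value = 2 * stats::pnorm(-abs(z)),
                             stringsAsFactors = FALSE)
  }
  res <- rbind_rows(rows)
  if (is.null(res)) res <- data.frame(set = character(), n_genes = integer(),
                                      direction = character(), z = numeric(),
                                      p_value = numeric())
  res$fdr <- stats::p.adjust(res$p_value, method = "BH")
  structure(list(table = res, contrast = de$contrast), class = "geneset_result")
}

#' @export
print.geneset_result <- function(x, ...) {
  cat(sprintf("geneset_result %s: %d sets tested, %d at FDR < 0.05\n",
              x$contrast, nrow(x$table), sum(x$table$fdr < 0.05)))
  invisible(x)
}

#' Reference-free per-cell gene-set score
#'
#' Within each cell, all genes are ranked by corrected counts (average ranks
#' for ties) and a set's score is its mean rank, centered and scaled to
#' \[-1, 1\]:
#'
#'   score = (mean rank of set genes - (G+1)/2) / ((G-1)/2).
#'
#' A random set scores 0 in expectation; +1/-1 require the set to occupy the
#' extreme ranks. Because ranks are computed within the cell, the score does
#' not depend on any other cell (no reference population needed).
#'
#' @param norm a `normalized_matrix`.
#' @param sets named list of gene symbol vectors.
#' @param min_set_size sets with fewer universe genes are skipped.
#' @return Numeric matrix, cells in rows (barcodes), sets in columns.
#' @export
per_cell_set_score <- function(norm, sets, min_set_size = 5) {
  ranks <- cell_ranks(norm$corrected_counts)
  G <- nrow(ranks)
  out <- matrix(NA_real_, ncol(ranks), length(sets),
                dimnames = list(colnames(ranks), names(sets)))
  for (nm in names(sets)) {
    hit <- rownames(ranks) %in% sets[[nm]]
    m <- sum(hit)
    if (m == 0) { sc_log("gene set '%s' has no universe genes; scores undefined", nm); next }
    if (m < min_set_size) { sc_log("gene set '%s' below min_set_size; skipped", nm); next }
    out[, nm] <- (colSums(ranks[hit, , drop = FALSE]) / m - (G + 1) / 2) / ((G - 1) / 2)
  }
  out
}

#' Per-cluster summary of per-cell gene-set scores
#'
#' Median and interquartile range of each set score within each named
#' cluster, the per-cluster pathway readout.
#'
#' @param scores cell x set matrix from [per_cell_set_score()].
#' @param clusters a `cluster_assignment`.
#' @return data.frame (cluster, set, median, iqr, n_cells).
#' @export
summarize_cluster_pathways <- function(scores, clusters) {
  a <- clusters$assignment
  named <- sort(unique(a$label[a$label != "unassigned_small"]))
  rows <- list()
  for (cl in named) {
    bc <- a$barcode[a$label == cl]
    sub <- scores[rownames(scores) %in% bc, , drop = FALSE]
    if (!nrow(sub)) next
    for (nm in colnames(scores)) {
      rows[[paste(cl, nm)]] <- data.frame(
        cluster = cl, set = nm,
        median = stats::median(sub[, nm]),
        iqr = stats::IQR(sub[, nm]),
        n_cells = nrow(sub), stringsAsFactors = FALSE)
    }
  }
  out <- rbind_rows(rows)
  if (is.null(out)) out <- data.frame(cluster = character(), set = character(),
                                      median = numeric(), iqr = numeric(),
                                      n_cells = integer())
  out
}
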