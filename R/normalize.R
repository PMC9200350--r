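#' Normalize a filtered count matrix
#'
#' Variance-stabilizing normalization by analytic Pearson residuals under a
#' negative binomial model with fixed dispersion: for gene j in cell i with
#' count x_ij, the expected value is mu_ij = n_i * p_j, where n_i is the
#' cell's total UMI depth and p_j the gene's global count fraction, and
#'
#'   r_ij = (x_ij - mu_ij) / sqrt(mu_ij + mu_ij^2 / theta).
#'
#' Residuals are clipped to +/- sqrt(number of cells). Cell-cycle S and G2M
#' scores are the mean clipped residual over the respective marker genes;
#' cell-cycle effect is then removed by per-gene least-squares regression of
#' the residuals on (S score, G2M score), keeping the residuals of that fit.
#' Depth-equalized "corrected counts" (counts rescaled to the median depth)
#' are carried alongside for fold-change and rank-based statistics.
#'
#' @param m a [count_matrix()] after gene and cell filtering.
#' @param theta negative binomial dispersion parameter (inverse overdispersion),
#'   default 100.
#' @param cc_genes optional list with elements `s` and `g2m`, character vectors
#'   of cycle marker symbols. `NULL` skips cell-cycle scoring and correction
#'   (all cells reported as G1).
#' @return Object of class `normalized_matrix`: `residuals` (gene x cell, dense,
#'   cycle-corrected), `corrected_counts` (sparse, depth-equalized),
#'   `cc_scores` (data.frame barcode, s_score, g2m_score, phase), `genes`,
#'   `barcodes`, `clip`.
#' @export
normalize_counts <- function(m, theta = 100, cc_genes = NULL) {
  if (theta <= 0) sc_stop("parameter_error", "theta must be > 0")
  counts <- m$counts
  tot <- Matrix::rowSums(counts)
  if (any(tot == 0)) {
    sc_log("dropping %d gene(s) with zero total count before normalization", sum(tot == 0))
    keep <- tot > 0
    counts <- counts[keep, , drop = FALSE]
    genes <- m$genes[keep, , drop = FALSE]
    tot <- tot[keep]
  } else genes <- m$genes
  n_cells <- ncol(counts)
  depth <- Matrix::colSums(counts)
  p <- tot / sum(tot)
  mu <- outer(p, as.numeric(depth))           # genes x cells
  x <- as.matrix(counts)
  resid <- (x - mu) / sqrt(mu + mu^2 / theta)
  clip <- sqrt(n_cells)
  resid[resid > clip] <- clip
  resid[resid < -clip] <- -clip
  rownames(resid) <- genes$symbol
  colnames(resid) <- m$barcodes

  s_score <- g2m_score <- rep(0, n_cells)
  if (!is.null(cc_genes)) {
    score_of <- function(set) {
      hit <- rownames(resid) %in% set
      if (!any(hit)) { sc_log("no cell-cycle marker genes found for one phase"); return(rep(0, n_cells)) }
      colMeans(resid[hit, , drop = FALSE])
    }
    s_score <- score_of(cc_genes$s)
    g2m_score <- score_of(cc_genes$g2m)
    if (stats::var(s_score) > 0 || stats::var(g2m_score) > 0) {
      X <- cbind(1, s_score, g2m_score)
      B <- tryCatch(solve(crossprod(X), crossprod(X, t(resid))),
                    error = function(e) qr.coef(qr(X), t(resid)))
      B[is.na(B)] <- 0
      resid <- resid - t(X %*% B)
      resid[resid > clip] <- clip
      resid[resid < -clip] <- -clip
    }
  }
  phase <- c("G1", "S", "G2M")[max.col(cbind(0, s_score, g2m_score), ties.method = "first")]

  corr <- counts
  corr@x <- corr@x * rep.int(stats::median(depth) / depth, diff(corr@p))
  rownames(corr) <- genes$symbol

  structure(list(
    residuals = resid,
    corrected_counts = corr,
    cc_scores = data.frame(barcode = m$barcodes, s_score = s_score,
                           g2m_score = g2m_score, phase = phase,
                           stringsAsFactors = FALSE),
    genes = genes, barcodes = m$barcodes, clip = clip, theta = theta),
    class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d genes x %d cells (theta = %g, clip = %.1f)\n",
              nrow(x$residuals), ncol(x$residuals), x$theta, x$clip))
  tab <- table(x$cc_scores$phase)
  cat("  cell-cycle phases:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
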