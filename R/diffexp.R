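#' Differential expression between two cell groups
#'
#' Per-gene ordinary least squares of the cycle-corrected residual expression
#' on a group-membership indicator, which for a single binary covariate is
#' the classic pooled-variance two-sample t-test. Fold changes are computed
#' on the depth-equalized corrected counts with a pseudocount of 1 (residuals
#' are not on a fold-change scale), p-values are two-sided from the t
#' distribution and corrected across genes by Benjamini-Hochberg.
#' A gene is called DE when |logFC| exceeds `fc_cut` and FDR falls below
#' `fdr_cut`.
#'
#' @param norm a `normalized_matrix`.
#' @param target,reference disjoint barcode vectors defining the two groups.
#' @param fc_cut absolute log2 fold-change cutoff (default 2).
#' @param fdr_cut FDR cutoff (default 0.01).
#' @param min_cells minimum group size; smaller contrasts are skipped
#'   (returns `NULL`) with a log entry.
#' @param contrast_name label stored on the result.
#' @return Object of class `de_result` (data.frame gene, logFC, t, p_value,
#'   fdr, is_de plus contrast metadata), or `NULL` when skipped.
#' @export
run_de <- function(norm, target, reference, fc_cut = 2, fdr_cut = 0.01,
                   min_cells = 20, contrast_name = "target_vs_reference") {
  if (length(intersect(target, reference)))
    sc_stop("parameter_error", "target and reference groups overlap")
  i1 <- match(target, norm$barcodes); i2 <- match(reference, norm$barcodes)
  if (anyNA(i1) || anyNA(i2))
    sc_stop("parameter_error", "group barcodes not all present in the matrix")
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < min_cells || n2 < min_cells) {
    sc_log("contrast %s skipped: group sizes %d/%d below %d", contrast_name, n1, n2, min_cells)
    return(NULL)
  }
  R <- norm$residuals
  x1 <- R[, i1, drop = FALSE]; x2 <- R[, i2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- matrixStats::rowVars(x1); v2 <- matrixStats::rowVars(x2)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tval <- (m1 - m2) / se
  tval[se == 0 & m1 == m2] <- 0
  p <- 2 * stats::pt(-abs(tval), df)
  cc <- norm$corrected_counts
  mu1 <- Matrix::rowSums(cc[, i1, drop = FALSE]) / n1
  mu2 <- Matrix::rowSums(cc[, i2, drop = FALSE]) / n2
  logFC <- log2((mu1 + 1) / (mu2 + 1))
  fdr <- stats::p.adjust(p, method = "BH")
  structure(list(
    table = data.frame(gene = rownames(R), logFC = logFC, t = tval,
                       p_value = p, fdr = fdr,
                       is_de = abs(logFC) > fc_cut & fdr < fdr_cut,
                       row.names = NULL, stringsAsFactors = FALSE),
    contrast = contrast_name, n_target = n1, n_reference = n2,
    fc_cut = fc_cut, fdr_cut = fdr_cut), class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("de_result %s: %d genes tested (%d vs %d cells), %d DE at |logFC|>%g & FDR<%g\n",
              x$contrast, nrow(x$table), x$n_target, x$n_reference,
              sum(x$table$is_de), x$fc_cut, x$fdr_cut))
  invisible(x)
}

# dominant major type per named cluster (ties excluded from malignancy)
cluster_dominant_types <- function(clusters, calls) {
  comp <- summarize_composition(calls, clusters)
  dom <- comp$dominant
  dom[dom$cluster != "unassigned_small", , drop = FALSE]
}

#' Run the two tumor contrasts across all clusters
#'
#' A named cluster is malignant when its dominant cell type belongs to
#' `malignant_types`. Emits one DE result per malignant cluster against the
#' pooled cells of all non-malignant clusters, and one per ordered pair of
#' distinct malignant clusters (each tumor cluster gets its own up-regulated
#' gene list). Contrasts with an empty or undersized reference are skipped
#' with a log entry.
#'
#' @param norm a `normalized_matrix`.
#' @param clusters a `cluster_assignment`.
#' @param calls a `cell_type_calls`.
#' @param malignant_types character set of tumor cell-type names.
#' @param fc_cut,fdr_cut,min_cells passed to [run_de()].
#' @return Named list of `de_result`s (possibly empty, with a warning, when
#'   no malignant cluster exists).
#' @export
tumor_contrasts <- function(norm, clusters, calls, malignant_types,
                            fc_cut = 2, fdr_cut = 0.01, min_cells = 20) {
  if (!length(malignant_types))
    sc_stop("parameter_error", "malignant_types must be non-empty")
  dom <- cluster_dominant_types(clusters, calls)
  mal <- dom$cluster[dom$dominant_type %in% malignant_types & !dom$tie]
  if (!length(mal)) {
    warning("no malignant cluster found; returning empty contrast list")
    return(list())
  }
  a <- clusters$assignment
  nonmal_clusters <- setdiff(dom$cluster, mal)
  ref <- a$barcode[a$label %in% nonmal_clusters]
  out <- list()
  for (cl in mal) {
    tgt <- a$barcode[a$label == cl]
    nm <- sprintf("cluster_%s_vs_nonmalignant", cl)
    if (!length(ref)) { sc_log("contrast %s skipped: no non-malignant cells", nm); next }
    r <- run_de(norm, tgt, ref, fc_cut, fdr_cut, min_cells, contrast_name = nm)
    if (!is.null(r)) { r$reference_kind <- "nonmalignant"; r$target_cluster <- cl; out[[nm]] <- r }
  }
  for (cl in mal) for (other in setdiff(mal, cl)) {
    nm <- sprintf("cluster_%s_vs_cluster_%s", cl, other)
    r <- run_de(norm, a$barcode[a$label == cl], a$barcode[a$label == other],
                fc_cut, fdr_cut, min_cells, contrast_name = nm)
    if (!is.null(r)) { r$reference_kind <- "tumor_cluster"; r$target_cluster <- cl; out[[nm]] <- r }
  }
  out
}
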