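#' Rank-AUC similarity of one cell to a marker gene set
#'
#' The score is the probability that a randomly chosen marker gene outranks a
#' randomly chosen non-marker gene within the cell (Mann-Whitney AUC on the
#' cell's expression ranks). It is scale-free and bounded in \[0, 1\]: 1 when
#' all markers occupy the top ranks, 0.5 for an uninformative (e.g. all-tied)
#' profile. Markers absent from the gene universe are ignored.
#'
#' @param expr_ranks named numeric vector: within-cell ranks of expression
#'   (average ranks for ties, higher expression = higher rank).
#' @param markers character vector of marker gene symbols.
#' @return AUC in \[0,1\], or `NA` if no marker is in the universe or the
#'   universe contains no non-marker gene.
#' @export
score_cell <- function(expr_ranks, markers) {
  hit <- names(expr_ranks) %in% markers
  m <- sum(hit)
  G <- length(expr_ranks)
  if (m == 0 || m == G) return(NA_real_)
  (sum(expr_ranks[hit]) - m * (m + 1) / 2) / (m * (G - m))
}

# rank genes within each cell (columns), average ranks for ties
cell_ranks <- function(corrected_counts) {
  x <- as.matrix(corrected_counts)
  r <- apply(x, 2, rank, ties.method = "average")
  dimnames(r) <- dimnames(x)
  r
}

# score every cell against a list of marker sets; rows = sets, cols = cells
score_matrix <- function(ranks, sets) {
  G <- nrow(ranks)
  out <- matrix(NA_real_, length(sets), ncol(ranks),
                dimnames = list(names(sets), colnames(ranks)))
  for (s in seq_along(sets)) {
    hit <- rownames(ranks) %in% sets[[s]]
    m <- sum(hit)
    missing <- setdiff(sets[[s]], rownames(ranks))
    if (length(missing))
      sc_log("marker set '%s': %d gene(s) not in universe, ignored", names(sets)[s], length(missing))
    if (m == 0 || m == G) next
    out[s, ] <- (colSums(ranks[hit, , drop = FALSE]) - m * (m + 1) / 2) / (m * (G - m))
  }
  out
}

# apply the unknown/uncertain decision rule to a score matrix column-wise
decide_labels <- function(scores, min_score, margin) {
  n <- ncol(scores)
  label <- character(n); best <- second <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    s <- scores[, i]
    s <- s[!is.na(s)]
    if (!length(s)) { label[i] <- "unknown"; next }
    ord <- order(-s)
    best[i] <- s[ord[1]]
    second[i] <- if (length(s) > 1) s[ord[2]] else NA_real_
    if (best[i] < min_score) label[i] <- "unknown"
    else if (!is.na(second[i]) && (best[i] - second[i]) < margin) label[i] <- "uncertain"
    else label[i] <- names(s)[ord[1]]
  }
  data.frame(label = label, best_score = best, second_score = second,
             stringsAsFactors = FALSE)
}

#' Hierarchical marker-based cell-type classification
#'
#' Two-step per-cell classification: every cell is first scored against all
#' major cell-type marker sets with [score_cell()] semantics; a cell whose
#' best score falls below `min_score` is `unknown`, and a cell whose best and
#' second-best scores differ by less than `margin` is `uncertain`. Cells with
#' a named major type whose type defines subtypes are then re-scored against
#' those subtype marker sets only, with the same decision rule.
#'
#' @param norm a `normalized_matrix` (ranks are taken on corrected counts).
#' @param hierarchy a [marker_hierarchy()].
#' @param min_score minimum similarity for a named call, in (0.5, 1).
#' @param margin minimum lead of best over second-best score.
#' @return Object of class `cell_type_calls`: data.frame `calls` (barcode,
#'   major_label, sub_label, best_score, second_score) and the major-level
#'   score matrix `scores` (types x cells).
#' @export
classify_cells <- function(norm, hierarchy, min_score = 0.6, margin = 0.05) {
  if (!inherits(hierarchy, "marker_hierarchy") || !length(hierarchy$major))
    sc_stop("parameter_error", "empty or invalid marker hierarchy")
  if (min_score <= 0.5 || min_score >= 1)
    sc_stop("parameter_error", "min_score must be in (0.5, 1)")
  if (margin <= 0) sc_stop("parameter_error", "margin must be > 0")
  ranks <- cell_ranks(norm$corrected_counts)
  maj_scores <- score_matrix(ranks, hierarchy$major)
  maj <- decide_labels(maj_scores, min_score, margin)
  sub_label <- rep(NA_character_, ncol(ranks))
  for (parent in names(hierarchy$sub)) {
    idx <- which(maj$label == parent)
    if (!length(idx)) next
    sub_scores <- score_matrix(ranks[, idx, drop = FALSE], hierarchy$sub[[parent]])
    sub_label[idx] <- decide_labels(sub_scores, min_score, margin)$label
  }
  structure(list(
    calls = data.frame(barcode = norm$barcodes,
                       major_label = maj$label,
                       sub_label = sub_label,
                       best_score = maj$best_score,
                       second_score = maj$second_score,
                       stringsAsFactors = FALSE),
    scores = maj_scores), class = "cell_type_calls")
}

#' @export
print.cell_type_calls <- function(x, ...) {
  cat("cell_type_calls:", nrow(x$calls), "cells\n")
  print(sort(table(x$calls$major_label), decreasing = TRUE))
  invisible(x)
}

#' Summarize sample composition by cell type and cluster
#'
#' Per-type cell counts and fractions, overall and within each cluster, and
#' the dominant type per cluster by majority vote (ties are reported
#' alphabetically, flagged).
#'
#' @param calls a `cell_type_calls`.
#' @param clusters a `cluster_assignment` over the same barcodes.
#' @return List with data.frames `overall` (type, n, fraction), `per_cluster`
#'   (cluster, type, n, fraction) and `dominant` (cluster, dominant_type,
#'   tie flag).
#' @export
summarize_composition <- function(calls, clusters) {
  a <- clusters$assignment
  if (!setequal(calls$calls$barcode, a$barcode))
    sc_stop("integrity_error", "cell-type calls and clusters cover different barcodes")
  lab <- calls$calls$major_label[match(a$barcode, calls$calls$barcode)]
  overall_tab <- table(calls$calls$major_label)
  overall <- data.frame(type = names(overall_tab),
                        n = as.integer(overall_tab),
                        fraction = as.numeric(overall_tab) / nrow(calls$calls),
                        stringsAsFactors = FALSE)
  overall <- overall[order(-overall$n, overall$type), ]
  rownames(overall) <- NULL
  per <- list(); dom <- list()
  for (cl in sort(unique(a$label))) {
    sel <- a$label == cl
    tab <- table(lab[sel])
    per[[cl]] <- data.frame(cluster = cl, type = names(tab),
                            n = as.integer(tab),
                            fraction = as.numeric(tab) / sum(sel),
                            stringsAsFactors = FALSE)
    top <- names(tab)[tab == max(tab)]
    dom[[cl]] <- data.frame(cluster = cl,
                            dominant_type = paste(sort(top), collapse = ";"),
                            tie = length(top) > 1, stringsAsFactors = FALSE)
  }
  list(overall = overall,
       per_cluster = rbind_rows(per),
       dominant = rbind_rows(dom))
}
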