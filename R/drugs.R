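#' Directed in-silico drug-candidate identification
#'
#' For each tumor cluster, joins its differentially expressed genes (from the
#' tumor-vs-nonmalignant contrast) against the offline drug-gene interaction
#' snapshot (case-insensitive symbol match). Each candidate carries the
#' expression direction (sign of logFC) and is directed by any matching
#' clinical-evidence record: up-regulation plus overexpression/sensitivity
#' evidence yields `directed_sensitivity`, up-regulation plus
#' overexpression/resistance yields `directed_resistance` (mirrored for
#' down-regulation and underexpression); with no direction-consistent
#' evidence the interaction stays `undirected`. When one (gene, drug) pair
#' has direction-consistent evidence for both sensitivity and resistance,
#' both rows are emitted, flagged as conflicting.
#'
#' @param de_list list of `de_result`s from the vs-nonmalignant contrasts
#'   (results of other contrast kinds are rejected).
#' @param snapshot an `interaction_snapshot`.
#' @return data.frame (cluster, gene, drug, interaction_type, de_direction,
#'   support, evidence_source, conflicting), sorted by cluster, support
#'   priority (sensitivity, resistance, undirected) and drug.
#' @export
identify_candidates <- function(de_list, snapshot) {
  for (de in de_list)
    if (!identical(de$reference_kind, "nonmalignant"))
      sc_stop("parameter_error",
              "identify_candidates requires vs-nonmalignant contrasts only (got %s)",
              de$contrast)
  inter <- snapshot$interactions
  evid <- snapshot$evidence
  rows <- list()
  for (de in de_list) {
    tab <- de$table[de$table$is_de, , drop = FALSE]
    if (!nrow(tab)) next
    for (gi in seq_len(nrow(tab))) {
      gene <- tab$gene[gi]
      dir <- if (tab$logFC[gi] > 0) "up" else "down"
      hits <- inter[toupper(inter$gene) == toupper(gene), , drop = FALSE]
      if (!nrow(hits)) next
      want_expr <- if (dir == "up") "overexpression" else "underexpression"
      for (hi in seq_len(nrow(hits))) {
        ev <- evid[toupper(evid$gene) == toupper(gene) &
                   toupper(evid$drug) == toupper(hits$drug[hi]) &
                   evid$expression_direction == want_expr, , drop = FALSE]
        sig <- unique(ev$clinical_significance)
        conflicting <- all(c("sensitivity", "resistance") %in% sig)
        mk <- function(support, src) data.frame(
          cluster = de$target_cluster, gene = gene, drug = hits$drug[hi],
          interaction_type = hits$interaction_type[hi], de_direction = dir,
          support = support, evidence_source = src,
          conflicting = conflicting, stringsAsFactors = FALSE)
        if (!nrow(ev)) {
          rows[[length(rows) + 1L]] <- mk("undirected", "")
        } else {
          for (s in sort(sig)) {
            src <- paste(sort(unique(ev$evidence_source[ev$clinical_significance == s])),
                         collapse = ";")
            rows[[length(rows) + 1L]] <- mk(paste0("directed_", s), src)
          }
        }
      }
    }
  }
  out <- rbind_rows(rows)
  if (is.null(out))
    out <- data.frame(cluster = character(), gene = character(), drug = character(),
                      interaction_type = character(), de_direction = character(),
                      support = character(), evidence_source = character(),
                      conflicting = logical(), stringsAsFactors = FALSE)
  prio <- c(directed_sensitivity = 1L, directed_resistance = 2L, undirected = 3L)
  out <- out[order(out$cluster, prio[out$support], out$drug, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-drug summary across tumor clusters
#'
#' For each candidate drug, the set of tumor clusters supporting it and the
#' fraction of tumor cells those clusters hold, plus a per-cell logical flag
#' (cell sits in a supporting cluster) for plotting on the embedding.
#'
#' @param cands candidate table from [identify_candidates()].
#' @param clusters a `cluster_assignment`.
#' @param tumor_clusters character vector of all tumor cluster labels
#'   (denominator of the coverage); defaults to the clusters present in
#'   `cands`.
#' @return List with `summary` (drug, clusters, n_clusters, coverage) sorted
#'   by decreasing coverage then drug, and `cell_flags` (cells x drugs
#'   logical matrix).
#' @export
per_cluster_drug_summary <- function(cands, clusters, tumor_clusters = NULL) {
  a <- clusters$assignment
  if (is.null(tumor_clusters)) tumor_clusters <- sort(unique(as.character(cands$cluster)))
  tumor_cells <- a$barcode[a$label %in% tumor_clusters]
  drugs <- sort(unique(cands$drug))
  flags <- matrix(FALSE, nrow(a), length(drugs),
                  dimnames = list(a$barcode, drugs))
  rows <- list()
  for (d in drugs) {
    supp <- sort(unique(as.character(cands$cluster[cands$drug == d])))
    covered <- a$barcode[a$label %in% supp]
    flags[a$barcode %in% covered, d] <- TRUE
    rows[[d]] <- data.frame(
      drug = d, clusters = paste(supp, collapse = ";"),
      n_clusters = length(supp),
      coverage = if (length(tumor_cells)) length(covered) / length(tumor_cells) else 0,
      stringsAsFactors = FALSE)
  }
  summary <- rbind_rows(rows)
  if (is.null(summary))
    summary <- data.frame(drug = character(), clusters = character(),
                          n_clusters = integer(), coverage = numeric())
  summary <- summary[order(-summary$coverage, summary$drug), , drop = FALSE]
  rownames(summary) <- NULL
  list(summary = summary, cell_flags = flags)
}
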