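# Independent brute-force oracles used to check the package's statistics.
# These deliberately use naive algorithms (pairwise loops, full enumeration)
# so they share no code path with the implementation under test.

# Mann-Whitney AUC by explicit pairwise comparison of marker vs non-marker
# expression values (0.5 credit for ties)
auc_pairwise <- function(values, is_marker) {
  mk <- values[is_marker]; bg <- values[!is_marker]
  wins <- 0
  for (a in mk) for (b in bg) wins <- wins + (a > b) + 0.5 * (a == b)
  wins / (length(mk) * length(bg))
}

# Benjamini-Hochberg by the literal step-up procedure
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# pooled-variance two-sample t statistic, closed form
pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# all set partitions of 1..n as restricted-growth strings
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxval) {
    k <- length(prefix)
    if (k == n) { out[[length(out) + 1L]] <<- prefix; return(invisible()) }
    for (v in seq_len(maxval + 1)) rec(c(prefix, v), max(maxval, v))
  }
  rec(integer(0), 0L)
  out
}

# weighted modularity of a membership vector, computed from the dense
# adjacency (independent of igraph's implementation)
modularity_dense <- function(W, memb) {
  m2 <- sum(W)                      # 2m for an undirected graph stored densely
  k <- rowSums(W)
  B <- W - outer(k, k) / m2
  sum(B[outer(memb, memb, "==")]) / m2
}

# maximum modularity over every partition of a small graph
best_modularity <- function(g) {
  W <- as.matrix(igraph::as_adjacency_matrix(g, attr = if ("weight" %in%
    igraph::edge_attr_names(g)) "weight" else NULL, sparse = FALSE))
  parts <- all_partitions(igraph::vcount(g))
  max(vapply(parts, function(p) modularity_dense(W, p), numeric(1)))
}

# adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  exp_idx <- sum_a * sum_b / choose(n, 2)
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}

# nested-loop reference join for drug-candidate identification: for every
# (cluster, DE gene, interaction, evidence) combination apply the direction
# rules literally
drug_join_oracle <- function(de_list, snapshot) {
  rows <- list()
  for (de in de_list) {
    tab <- de$table
    for (i in seq_len(nrow(tab))) {
      if (!tab$is_de[i]) next
      gene <- tab$gene[i]
      dir <- if (tab$logFC[i] > 0) "up" else "down"
      want <- if (dir == "up") "overexpression" else "underexpression"
      for (j in seq_len(nrow(snapshot$interactions))) {
        it <- snapshot$interactions[j, ]
        if (toupper(it$gene) != toupper(gene)) next
        sigs <- character(0)
        for (k in seq_len(nrow(snapshot$evidence))) {
          ev <- snapshot$evidence[k, ]
          if (toupper(ev$gene) == toupper(gene) &&
              toupper(ev$drug) == toupper(it$drug) &&
              ev$expression_direction == want)
            sigs <- c(sigs, ev$clinical_significance)
        }
        sigs <- unique(sigs)
        if (!length(sigs)) {
          rows[[length(rows) + 1L]] <- data.frame(
            cluster = de$target_cluster, gene = gene, drug = it$drug,
            support = "undirected", stringsAsFactors = FALSE)
        } else {
          for (s in sigs)
            rows[[length(rows) + 1L]] <- data.frame(
              cluster = de$target_cluster, gene = gene, drug = it$drug,
              support = paste0("directed_", s), stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) return(data.frame(cluster = character(), gene = character(),
                                       drug = character(), support = character()))
  out <- do.call(rbind, rows)
  out[order(out$cluster, out$gene, out$drug, out$support), , drop = FALSE]
}
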