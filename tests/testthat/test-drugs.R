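test_that("the canonical over-expression/sensitivity case is directed", {
  de <- fake_de(c("CCND1", "CDK4", "OTHER"), de_up = "CCND1")
  snap <- structure(list(
    interactions = data.frame(gene = "CCND1", drug = "PALBOCICLIB",
                              interaction_type = "inhibitor", source = "dgidb",
                              stringsAsFactors = FALSE),
    evidence = data.frame(gene = "CCND1", drug = "PALBOCICLIB",
                          expression_direction = "overexpression",
                          clinical_significance = "sensitivity",
                          evidence_source = "civic", stringsAsFactors = FALSE)),
    class = "interaction_snapshot")
  out <- identify_candidates(list(de), snap)
  expect_equal(nrow(out), 1)
  expect_equal(out$support, "directed_sensitivity")
  expect_equal(out$de_direction, "up")
})

test_that("empty DE lists and non-matching genes produce no candidates", {
  snap <- random_snapshot(paste0("g", 1:10))
  out <- identify_candidates(list(fake_de(paste0("g", 1:10))), snap)
  expect_equal(nrow(out), 0)
  # tumor-vs-tumor contrasts are rejected
  de_tt <- fake_de(paste0("g", 1:3), de_up = "g1")
  de_tt$reference_kind <- "tumor_cluster"
  expect_error(identify_candidates(list(de_tt), snap), class = "parameter_error")
})

test_that("direction-inconsistent evidence leaves the candidate undirected", {
  de <- fake_de(c("A", "B"), de_up = "A")
  snap <- structure(list(
    interactions = data.frame(gene = "A", drug = "D1", interaction_type = "x",
                              source = "s", stringsAsFactors = FALSE),
    evidence = data.frame(gene = "A", drug = "D1",
                          expression_direction = "underexpression",
                          clinical_significance = "sensitivity",
                          evidence_source = "e", stringsAsFactors = FALSE)),
    class = "interaction_snapshot")
  out <- identify_candidates(list(de), snap)
  expect_equal(out$support, "undirected")
})

test_that("conflicting evidence yields both rows, flagged", {
  de <- fake_de("A", de_up = "A")
  snap <- structure(list(
    interactions = data.frame(gene = "A", drug = "D1", interaction_type = "x",
                              source = "s", stringsAsFactors = FALSE),
    evidence = data.frame(gene = "A", drug = "D1",
                          expression_direction = "overexpression",
                          clinical_significance = c("sensitivity", "resistance"),
                          evidence_source = "e", stringsAsFactors = FALSE)),
    class = "interaction_snapshot")
  out <- identify_candidates(list(de), snap)
  expect_equal(nrow(out), 2)
  expect_setequal(out$support, c("directed_sensitivity", "directed_resistance"))
  expect_true(all(out$conflicting))
})

test_that("join output equals the nested-loop oracle on random fixtures", {
  set.seed(19)
  genes <- sprintf("G%02d", 1:15)
  for (i in 1:30) {
    snap <- random_snapshot(genes, n_inter = sample(3:12, 1), n_evid = sample(2:8, 1))
    de1 <- fake_de(genes, de_up = sample(genes, sample(0:5, 1)),
                   de_down = character(0), cluster = "0")
    down_pool <- setdiff(genes, de1$table$gene[de1$table$is_de])
    de2 <- fake_de(genes, de_up = character(0),
                   de_down = sample(down_pool, sample(0:3, 1)), cluster = "1")
    got <- identify_candidates(list(de1, de2), snap)
    want <- drug_join_oracle(list(de1, de2), snap)
    got_sorted <- got[order(got$cluster, got$gene, got$drug, got$support),
                      c("cluster", "gene", "drug", "support")]
    rownames(got_sorted) <- rownames(want) <- NULL
    expect_equal(got_sorted, want)
  }
})

test_that("direction soundness holds across many random fixtures", {
  set.seed(20)
  genes <- sprintf("G%02d", 1:12)
  for (i in 1:200) {
    snap <- random_snapshot(genes, n_inter = 6, n_evid = 6)
    de <- fake_de(genes, de_up = sample(genes, 3),
                  de_down = sample(setdiff(genes, genes[1:6]), 1))
    out <- identify_candidates(list(de), snap)
    if (!nrow(out)) next
    for (r in seq_len(nrow(out))) {
      if (!startsWith(out$support[r], "directed")) next
      want <- if (out$de_direction[r] == "up") "overexpression" else "underexpression"
      ev <- snap$evidence[toupper(snap$evidence$gene) == toupper(out$gene[r]) &
                          toupper(snap$evidence$drug) == toupper(out$drug[r]), ]
      expect_true(want %in% ev$expression_direction)
    }
    # join completeness: every output pair exists in the snapshot
    expect_true(all(paste(toupper(out$gene), toupper(out$drug)) %in%
                    paste(toupper(snap$interactions$gene), toupper(snap$interactions$drug))))
  }
})

test_that("candidate output is deterministic and ordered by support priority", {
  de <- fake_de(c("A", "B"), de_up = c("A", "B"))
  snap <- structure(list(
    interactions = data.frame(gene = c("A", "B"), drug = c("ZDRUG", "ADRUG"),
                              interaction_type = "x", source = "s",
                              stringsAsFactors = FALSE),
    evidence = data.frame(gene = "B", drug = "ADRUG",
                          expression_direction = "overexpression",
                          clinical_significance = "sensitivity",
                          evidence_source = "e", stringsAsFactors = FALSE)),
    class = "interaction_snapshot")
  o1 <- identify_candidates(list(de), snap)
  o2 <- identify_candidates(list(de), snap)
  expect_identical(o1, o2)
  expect_equal(o1$support, c("directed_sensitivity", "undirected"))
})

test_that("drug summary computes coverage over tumor cells", {
  clusters <- structure(list(assignment = data.frame(
    barcode = paste0("b", 1:100),
    cluster_id = rep(0:3, 25),
    label = as.character(rep(0:3, 25)), stringsAsFactors = FALSE),
    min_size = 20), class = "cluster_assignment")
  cands <- data.frame(cluster = c("0", "1", "2", "3", "1"),
                      gene = "G", drug = c(rep("PANDRUG", 4), "SOLODRUG"),
                      support = "undirected", stringsAsFactors = FALSE)
  s <- per_cluster_drug_summary(cands, clusters, tumor_clusters = c("0", "1", "2", "3"))
  expect_equal(s$summary$coverage[s$summary$drug == "PANDRUG"], 1.0)
  expect_equal(s$summary$coverage[s$summary$drug == "SOLODRUG"], 0.25)
  # coverage 0.3 case: supporting cluster holds 30 of 100 tumor cells
  clusters$assignment$label <- c(rep("0", 30), rep("1", 70))
  s2 <- per_cluster_drug_summary(data.frame(cluster = "0", gene = "G", drug = "D",
                                            support = "undirected"),
                                 clusters, tumor_clusters = c("0", "1"))
  expect_equal(s2$summary$coverage, 0.3)
  # alphabetical tie-break on equal coverage
  cands2 <- data.frame(cluster = "0", gene = "G", drug = c("BDRUG", "ADRUG"),
                       support = "undirected", stringsAsFactors = FALSE)
  s3 <- per_cluster_drug_summary(cands2, clusters, tumor_clusters = c("0", "1"))
  expect_equal(s3$summary$drug, c("ADRUG", "BDRUG"))
})
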