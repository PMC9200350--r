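fake_de_t <- function(tvals, genes = sprintf("g%04d", seq_along(tvals))) {
  structure(list(table = data.frame(gene = genes, logFC = 0, t = tvals,
                                    p_value = 2 * pnorm(-abs(tvals)),
                                    fdr = 1, is_de = FALSE,
                                    stringsAsFactors = FALSE),
                 contrast = "synthetic", reference_kind = "nonmalignant",
                 target_cluster = "0", fc_cut = 2, fdr_cut = 0.01),
            class = "de_result")
}

test_that("equal in-set and out-set t statistics give z = 0, p = 1", {
  tvals <- rep(c(-1, 0, 1), 20)
  de <- fake_de_t(tvals)
  # the set holds one gene of each value: in-set mean == out-set mean
  sets <- list(S = de$table$gene[c(1, 2, 3, 4, 5, 6)])
  res <- competitive_test(de, sets)
  expect_equal(res$table$z, 0)
  expect_equal(res$table$p_value, 1)
})

test_that("with rho = 0 the statistic is the standardized mean difference", {
  set.seed(10)
  tvals <- rnorm(100)
  de <- fake_de_t(tvals)
  idx <- 1:10
  sets <- list(S = de$table$gene[idx])
  res <- competitive_test(de, sets)
  m <- 10; G <- 100
  delta <- mean(tvals[idx]) - mean(tvals[-idx])
  z_manual <- delta / sqrt((1 / m + 1 / (G - m)) * var(tvals))
  expect_equal(res$table$z, z_manual, tolerance = 1e-12)
})

test_that("analytic p agrees with a permutation oracle of set membership", {
  set.seed(12)
  G <- 200; m <- 20
  tvals <- rnorm(G) + c(rep(0.5, m), rep(0, G - m))
  de <- fake_de_t(tvals)
  res <- competitive_test(de, list(S = de$table$gene[1:m]))
  # permutation oracle: re-draw the set uniformly, compare |delta|
  obs <- mean(tvals[1:m]) - mean(tvals[-(1:m)])
  perm <- replicate(10000, {
    idx <- sample(G, m)
    mean(tvals[idx]) - mean(tvals[-idx])
  })
  p_perm <- mean(abs(perm) >= abs(obs))
  expect_lt(abs(res$table$p_value - p_perm), 0.02)
})

test_that("null type-I error of the competitive test is calibrated", {
  set.seed(13)
  reps <- 1000
  hits <- 0
  for (i in seq_len(reps)) {
    tvals <- rnorm(150)
    de <- fake_de_t(tvals)
    res <- competitive_test(de, list(S = sample(de$table$gene, 15)))
    hits <- hits + (res$table$p_value < 0.05)
  }
  expect_lt(abs(hits / reps - 0.05), 0.02)
})

test_that("correlated in-set genes inflate the variance (smaller |z|)", {
  set.seed(14)
  n_cells <- 60; G <- 80; m <- 10
  shared <- rnorm(n_cells)
  resid <- matrix(rnorm(G * n_cells), G, n_cells)
  resid[1:m, ] <- resid[1:m, ] + 2 * rep(shared, each = m)
  rownames(resid) <- sprintf("g%04d", 1:G)
  tvals <- rnorm(G); tvals[1:m] <- tvals[1:m] + 1
  de <- fake_de_t(tvals)
  sets <- list(S = de$table$gene[1:m])
  z_indep <- competitive_test(de, sets)$table$z
  z_corr <- competitive_test(de, sets, residuals = resid)$table$z
  expect_lt(abs(z_corr), abs(z_indep))
})

test_that("adding a constant to in-set t strictly increases z", {
  set.seed(15)
  tvals <- rnorm(100)
  idx <- 1:12
  z <- sapply(c(0, 0.5, 1), function(shift) {
    tv <- tvals; tv[idx] <- tv[idx] + shift
    competitive_test(fake_de_t(tv), list(S = sprintf("g%04d", idx)))$table$z
  })
  expect_true(all(diff(z) > 0))
})

test_that("direction is up/down/mixed per the DE-cutoff rule", {
  de <- fake_de_t(c(rep(3, 5), rep(-3, 5), rnorm(90)))
  tab <- de$table
  tab$logFC[1:5] <- 3; tab$fdr[1:5] <- 1e-5
  tab$logFC[6:10] <- -3; tab$fdr[6:10] <- 1e-5
  de$table <- tab
  res <- competitive_test(de, list(M = tab$gene[1:10], U = tab$gene[c(1:5, 11:15)],
                                   D = tab$gene[c(6:10, 16:20)]))
  expect_equal(res$table$direction[res$table$set == "M"], "mixed")
  expect_equal(res$table$direction[res$table$set == "U"], "up")
  expect_equal(res$table$direction[res$table$set == "D"], "down")
})

test_that("undersized sets are skipped with a log entry", {
  de <- fake_de_t(rnorm(50))
  expect_message(res <- competitive_test(de, list(tiny = de$table$gene[1:2])),
                 "skipped")
  expect_equal(nrow(res$table), 0)
})

test_that("per-cell scores hit their exact extremes and null mean", {
  cc <- Matrix::Matrix(matrix(c(9, 1, 1, 1,   2, 2, 2, 2), 4, 2), sparse = TRUE)
  rownames(cc) <- paste0("g", 1:4); colnames(cc) <- c("c1", "c2")
  norm <- fake_norm(cc)
  s <- per_cell_set_score(norm, list(top = "g1"), min_set_size = 1)
  expect_equal(s["c1", "top"], 1)     # the single top-ranked gene
  expect_equal(s["c2", "top"], 0)     # all-tied cell scores 0
  # random sets have mean score ~0
  set.seed(16)
  cc2 <- Matrix::Matrix(matrix(rpois(1000 * 200, 5), 1000, 200), sparse = TRUE)
  rownames(cc2) <- sprintf("g%04d", 1:1000)
  colnames(cc2) <- sprintf("c%03d", 1:200)
  norm2 <- fake_norm(cc2)
  sets <- lapply(stats::setNames(1:10, paste0("R", 1:10)),
                 function(i) sample(rownames(cc2), 20))
  sc <- per_cell_set_score(norm2, sets)
  expect_lt(abs(mean(sc)), 0.02)            # pooled null mean
  expect_lt(max(abs(colMeans(sc))), 0.035)  # per-set, within MC error
  expect_true(all(sc >= -1 & sc <= 1))
})

test_that("a cell's score depends only on that cell (column independence)", {
  set.seed(17)
  cc <- Matrix::Matrix(matrix(rpois(200 * 30, 4), 200, 30), sparse = TRUE)
  rownames(cc) <- sprintf("g%03d", 1:200); colnames(cc) <- sprintf("c%02d", 1:30)
  sets <- list(S = sample(rownames(cc), 15))
  s_all <- per_cell_set_score(fake_norm(cc), sets)
  s_some <- per_cell_set_score(fake_norm(cc[, 1:5]), sets)
  expect_equal(s_all[1:5, , drop = FALSE], s_some)
})

test_that("planted pathway suppression orders cluster medians as planted", {
  sd <- small_de()
  sim <- sd$sim
  scores <- per_cell_set_score(sd$norm, sim$gene_sets)
  med <- summarize_cluster_pathways(scores, sd$cl)
  mapk <- med[med$set == "SYNTH_MAPK", ]
  # map clusters to subclones via truth
  a <- sd$cl$assignment
  clu_sub <- sapply(mapk$cluster, function(cl) {
    sel <- a$label == cl
    s <- sd$truth$subclone[sel]
    if (all(is.na(s))) NA_integer_ else as.integer(names(which.max(table(s))))
  })
  suppressed <- mapk$median[!is.na(clu_sub) & clu_sub > 1]
  unsuppressed <- mapk$median[is.na(clu_sub) | clu_sub == 1]
  expect_equal(length(suppressed), 3)
  expect_lt(max(suppressed), min(unsuppressed))
})
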