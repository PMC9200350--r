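make_de_norm <- function(resid, corrected = NULL) {
  if (is.null(corrected)) corrected <- Matrix::Matrix(pmax(resid + 5, 0), sparse = TRUE)
  rownames(corrected) <- rownames(resid)
  structure(list(residuals = resid,
                 corrected_counts = corrected,
                 barcodes = colnames(resid)), class = "normalized_matrix")
}

test_that("a gene identical in both groups is a perfect null", {
  resid <- matrix(1.5, 3, 40, dimnames = list(paste0("g", 1:3), paste0("c", 1:40)))
  resid[2, ] <- rnorm(40)
  norm <- make_de_norm(resid)
  de <- run_de(norm, paste0("c", 1:20), paste0("c", 21:40), min_cells = 5)
  expect_equal(de$table$t[1], 0)
  expect_equal(de$table$p_value[1], 1)
  expect_equal(de$table$logFC[1], 0)
  expect_false(de$table$is_de[1])
})

test_that("regression t equals the closed-form pooled two-sample t", {
  set.seed(5)
  resid <- matrix(rnorm(20 * 50), 20, 50,
                  dimnames = list(paste0("g", 1:20), paste0("c", 1:50)))
  norm <- make_de_norm(resid)
  g1 <- paste0("c", 1:22); g2 <- paste0("c", 23:50)
  de <- run_de(norm, g1, g2, min_cells = 5)
  for (j in 1:20) {
    x <- resid[j, 1:22]; y <- resid[j, 23:50]
    expect_lt(abs(de$table$t[j] - pooled_t(x, y)), 1e-10)
    # and the OLS route: t of the group coefficient
    fit <- summary(lm(c(x, y) ~ rep(c(1, 0), c(22, 28))))
    expect_lt(abs(de$table$t[j] - fit$coefficients[2, "t value"]), 1e-10)
  }
})

test_that("DE calls apply both cutoffs jointly", {
  sd <- small_de()
  for (de in sd$des[1:2]) {
    tab <- de$table
    expect_equal(tab$is_de, abs(tab$logFC) > 2 & tab$fdr < 0.01)
  }
  # a strong fold change with mediocre FDR is not DE, and vice versa
  expect_false(any(sd$des[[1]]$table$is_de[sd$des[[1]]$table$fdr >= 0.01]))
})

test_that("swapping groups flips logFC and t, keeps p and fdr", {
  set.seed(6)
  resid <- matrix(rnorm(30 * 60, sd = 1) + rep(c(2, 0), c(15, 15)), 30, 60,
                  dimnames = list(paste0("g", 1:30), paste0("c", 1:60)))
  norm <- make_de_norm(resid)
  a <- paste0("c", 1:25); b <- paste0("c", 26:60)
  de1 <- run_de(norm, a, b, min_cells = 5)
  de2 <- run_de(norm, b, a, min_cells = 5)
  expect_equal(de1$table$t, -de2$table$t)
  expect_equal(de1$table$logFC, -de2$table$logFC)
  expect_equal(de1$table$p_value, de2$table$p_value)
  expect_equal(de1$table$fdr, de2$table$fdr)
})

test_that("overlapping or undersized groups are rejected/skipped", {
  resid <- matrix(rnorm(5 * 30), 5, 30,
                  dimnames = list(paste0("g", 1:5), paste0("c", 1:30)))
  norm <- make_de_norm(resid)
  expect_error(run_de(norm, paste0("c", 1:10), paste0("c", 10:20)),
               class = "parameter_error")
  expect_message(r <- run_de(norm, paste0("c", 1:5), paste0("c", 6:30)),
                 "skipped")
  expect_null(r)
})

test_that("null simulation has calibrated type-I error and BH yields ~0 calls", {
  set.seed(8)
  n_genes <- 2000
  resid <- matrix(rnorm(n_genes * 80), n_genes, 80,
                  dimnames = list(paste0("g", 1:n_genes), paste0("c", 1:80)))
  norm <- make_de_norm(resid)
  de <- run_de(norm, paste0("c", 1:40), paste0("c", 41:80), min_cells = 5)
  expect_lt(abs(mean(de$table$p_value < 0.05) - 0.05), 0.02)
  expect_lte(sum(de$table$fdr < 0.01), 2)
})

test_that("BH adjustment equals the brute-force step-up procedure", {
  set.seed(9)
  for (i in 1:10) {
    p <- runif(sample(5:200, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, "BH"), bh_stepup(p), tolerance = 1e-12)
  }
  # and the package's fdr column is BH of its p column
  sd <- small_de()
  tab <- sd$des[[1]]$table
  expect_equal(tab$fdr, bh_stepup(tab$p_value), tolerance = 1e-12)
})

test_that("contrast structure: 4 malignant clusters give 4 + 12 contrasts", {
  sd <- small_de()
  kinds <- vapply(sd$des, function(d) d$reference_kind, character(1))
  expect_equal(sum(kinds == "nonmalignant"), 4)
  expect_equal(sum(kinds == "tumor_cluster"), 12)
  expect_error(tumor_contrasts(sd$norm, sd$cl, sd$calls, character(0)),
               class = "parameter_error")
  expect_warning(out <- tumor_contrasts(sd$norm, sd$cl, sd$calls, "Hepatocyte"),
                 "no malignant cluster")
  expect_length(out, 0)
})

test_that("planted DE genes are recovered with controlled empirical FDR", {
  sd <- small_de()
  sim <- sd$sim
  truth_roles <- sim$gene_truth$role
  names(truth_roles) <- sim$gene_truth$symbol
  for (nm in names(sd$des)) {
    de <- sd$des[[nm]]
    if (!identical(de$reference_kind, "nonmalignant")) next
    cl_cells <- sd$cl$assignment$label == de$target_cluster
    sub <- names(which.max(table(sd$truth$subclone[cl_cells])))
    planted <- sim$sets[[paste0("de:subclone", sub)]]
    called <- de$table$gene[de$table$is_de]
    expect_gte(sum(planted %in% called) / length(planted), 0.9)
    # false discoveries: called genes with no planted effect in this contrast
    expected_de <- c(planted, sim$sets[["de:shared_tumor"]],
                     sim$sets[["marker:Melanoma"]],
                     sim$sets[["pathway:SYNTH_MAPK"]],
                     unlist(sim$sets[paste0("marker:", c("T.cell", "T.mem", "T.reg",
                                                         "Macrophage", "B.cell",
                                                         "NK", "Endothelial"))]))
    fdr_emp <- mean(!called %in% expected_de)
    expect_lte(fdr_emp, 0.05)
  }
})
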