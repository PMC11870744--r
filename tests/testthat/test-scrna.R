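small_cm <- function(seed = 5) {
  gen_expression(expr_sim_spec(n_cells = c(INT = 10, PY1 = 10, PY2 = 10,
                                           PY3 = 10),
                               n_genes = 300, n_ercc = 10, seed = seed))
}

test_that("QC gates apply the stated thresholds strictly", {
  counts <- matrix(5L, 20, 4,
                   dimnames = list(c(sprintf("G%02d", 1:18), "ERCC-1", "ERCC-2"),
                                   paste0("c", 1:4)))
  meta <- data.frame(cell = paste0("c", 1:4),
                     cdna_yield_ng = c(2, 1.0, 2, 2),     # c2: exactly 1 -> fails
                     cdna_peak_bp = c(2000, 2000, 999, 5000))  # c3 fails, c4 passes
  cm <- count_matrix(counts, meta)
  r <- qc_filter(cm, min_genes = 0, max_ercc_frac = 1)
  expect_setequal(r$report$failed_cells, c("c2", "c3"))
  expect_equal(r$report$n_kept, 2)

  # thresholds wide open: identity
  r2 <- qc_filter(cm, min_yield_ng = -Inf, peak_range_bp = c(-Inf, Inf),
                  min_genes = 0, max_ercc_frac = 1)
  expect_equal(ncol(r2$kept$counts), 4)

  # everything removed errors with a report
  expect_error(qc_filter(cm, min_yield_ng = Inf), "all 4 cells")
})

test_that("normalization is scale-invariant and keeps zero cells zero", {
  cm <- small_cm()
  norm <- normalize_log(cm)
  # doubling one cell's counts leaves its normalized profile unchanged
  c2 <- cm$counts; c2[, 3] <- c2[, 3] * 2L
  cm2 <- count_matrix(c2, cm$meta)
  expect_equal(normalize_log(cm2)[, 3], norm[, 3], tolerance = 1e-12)

  # an all-zero cell stays all-zero
  c3 <- cm$counts; c3[, 1] <- 0L
  expect_true(all(normalize_log(count_matrix(c3, cm$meta))[, 1] == 0))
})

test_that("spike-ins are excluded from the scaling denominator", {
  genes <- c("G1", "G2", "ERCC-1")
  counts <- matrix(c(10L, 30L, 5L,
                     10L, 30L, 500L), 3, 2,
                   dimnames = list(genes, c("a", "b")))
  meta <- data.frame(cell = c("a", "b"), cdna_yield_ng = 2, cdna_peak_bp = 2000)
  norm <- normalize_log(count_matrix(counts, meta))
  # biological rows identical across cells despite wildly different ERCC load
  expect_equal(norm["G1", "a"], norm["G1", "b"], tolerance = 1e-12)
  expect_equal(norm["G2", "a"], norm["G2", "b"], tolerance = 1e-12)
})

test_that("clustering separates well-separated groups and is reproducible", {
  cm <- small_cm(7)
  norm <- normalize_log(cm)
  lab <- cluster_cells(norm, k = 4, seed = 1)
  expect_gte(ari(lab, cm$meta$cluster_true), 0.9)
  expect_identical(cluster_cells(norm, k = 4, seed = 1), lab)

  # permuting cell order only permutes the labelling
  ord <- sample(ncol(norm))
  norm_p <- norm[, ord]
  attr(norm_p, "is_ercc") <- attr(norm, "is_ercc")
  lab_p <- cluster_cells(norm_p, k = 4, seed = 1)
  expect_equal(ari(lab_p, lab[ord]), 1)

  expect_error(cluster_cells(norm, k = 100, seed = 1), "exceeds")
})

test_that("two synthetic blobs are perfectly recovered with k = 2", {
  set.seed(11)
  x <- cbind(matrix(rnorm(50 * 10), 50), matrix(rnorm(50 * 10, 6), 50))
  rownames(x) <- paste0("g", 1:50)
  colnames(x) <- paste0("c", 1:20)
  lab <- cluster_cells(x, k = 2, seed = 2, n_hvg = 50, n_pcs = 5)
  expect_equal(ari(lab, rep(1:2, each = 10)), 1)
})

test_that("planted markers pass the padj < 0.05 & FC > 1.5 rule", {
  cm <- gen_expression(expr_sim_spec(seed = 13))
  norm <- normalize_log(cm)
  truth <- cm$meta$cluster_true
  mk <- find_markers(norm, truth)
  planted <- names(attr(cm, "truth")$markers$PY2)
  got <- mk$gene[mk$cluster == "PY2" & mk$is_marker]
  expect_true(all(planted %in% got))
  # marker sets are exactly reproducible
  mk2 <- find_markers(norm, truth)
  expect_identical(mk2$is_marker, mk$is_marker)
  # BH monotonicity: adjusted never below raw
  expect_true(all(mk$p_adj >= mk$p - 1e-12))
})

test_that("BH adjustment in the marker table matches the step-up definition", {
  cm <- small_cm(3)
  norm <- normalize_log(cm)
  mk <- find_markers(norm, cm$meta$cluster_true)
  for (cl in unique(mk$cluster)) {
    sub <- mk[mk$cluster == cl, ]
    expect_equal(sub$p_adj, bh_oracle(sub$p), tolerance = 1e-12)
  }
})

test_that("rank-sum p on a 6-cell instance equals exact enumeration", {
  set.seed(17)
  x <- matrix(rnorm(5 * 6), 5, 6,
              dimnames = list(paste0("g", 1:5), paste0("c", 1:6)))
  lab <- rep(c("a", "b"), each = 3)
  mk <- find_markers(x, lab, min_cells = 3)
  for (g in rownames(x)) {
    p_oracle <- mw_oracle(x[g, 1:3], x[g, 4:6])
    expect_equal(mk$p[mk$gene == g & mk$cluster == "a"], p_oracle,
                 tolerance = 1e-12)
  }
})

test_that("constant genes get p = 1 by convention", {
  x <- matrix(rnorm(3 * 30), 3, 30,
              dimnames = list(c("g1", "g2", "flat"), paste0("c", 1:30)))
  x["flat", ] <- 2.5
  mk <- find_markers(x, rep(c("a", "b"), 15))
  expect_true(all(mk$p[mk$gene == "flat"] == 1))
})

test_that("null data produce few markers", {
  set.seed(19)
  x <- matrix(rpois(400 * 60, 5), 400, 60,
              dimnames = list(paste0("g", 1:400), paste0("c", 1:60)))
  norm <- log1p(x / rep(colSums(x), each = 400) * 1e4)
  mk <- find_markers(norm, rep(c("a", "b"), each = 30))
  expect_lt(mean(mk$is_marker), 0.02)
})

test_that("cluster annotation votes by panel overlap; ties are ambiguous", {
  mk <- data.frame(
    gene = c("GAD1", "GAD2", "XYZ", "SATB2", "CUX2", "SLC17A7", "AAA", "BBB"),
    cluster = c("c1", "c1", "c1", "c2", "c2", "c2", "c3", "c3"),
    is_marker = TRUE
  )
  ann <- annotate_clusters(mk)
  expect_equal(unname(ann[c("c1", "c2", "c3")]), c("INT", "PY", "ambiguous"))
  # panel order irrelevant
  ann2 <- annotate_clusters(mk, panels = list(INT = rev(interneuron_panel()),
                                              PY = rev(pyramidal_panel())))
  expect_identical(ann, ann2)
})
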