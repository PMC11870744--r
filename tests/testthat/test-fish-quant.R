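small_volume_sample <- function(seed = 3, n_cells = 5, density = 0.02) {
  m <- matrix(density, 6, 2,
              dimnames = list(c("NFKBIA", "CDKN1A", "CCL2", "CUX2", "NEFM",
                                "NEFH"), c("PY1", "PY2")))
  sp <- fish_sim_spec(n_cells = n_cells,
                      radius_meanlog = c(PY1 = log(2.4), PY2 = log(2.8)),
                      radius_sdlog = 0.05, densities = m, seed = seed)
  gen_fish(sp, mode = "volume")
}

test_that("spot detection needs a voxel size and handles empty volumes", {
  vol <- array(0, c(20, 20, 10))
  expect_error(detect_spots(vol), "voxel_size_um")
  expect_error(detect_spots(vol, c(0.23, -1, 0.4)), "positive")
  expect_equal(nrow(detect_spots(vol, c(0.23, 0.23, 0.4))), 0)
  # infinite threshold: nothing survives
  vol[10, 10, 5] <- 1
  expect_equal(nrow(detect_spots(vol, c(0.23, 0.23, 0.4), threshold = Inf)), 0)
})

test_that("rendered synthetic spots are detected within one voxel", {
  fv <- small_volume_sample(seed = 31)
  for (g in c("NFKBIA", "CUX2")) {
    truth_sp <- fv$spots[fv$spots$gene == g, ]
    det <- detect_spots(fv$channels[[g]], fv$voxel_size_um, threshold = 0.1)
    expect_equal(nrow(det), nrow(truth_sp))
    if (nrow(det) > 0) {
      dd <- vapply(seq_len(nrow(truth_sp)), function(i) {
        min(sqrt((det$x - truth_sp$x[i])^2 + (det$y - truth_sp$y[i])^2 +
                 (det$z - truth_sp$z[i])^2))
      }, numeric(1))
      expect_lt(max(dd), max(fv$voxel_size_um))
    }
  }
})

test_that("soma segmentation recovers disjoint ellipsoids within 10%", {
  fv <- small_volume_sample(seed = 32, n_cells = 5)
  seg <- segment_somas(fv$dapi, fv$voxel_size_um, min_volume_um3 = 10)
  vols <- attr(seg, "volumes_um3")
  expect_equal(length(vols), 5)
  expect_true(all(abs(sort(vols) - sort(fv$cells$volume_post_um3)) /
                  sort(fv$cells$volume_post_um3) < 0.1))
})

test_that("segmentation of an empty volume gives no labels; bypass is identity", {
  empty <- array(0, c(15, 15, 8))
  seg <- segment_somas(empty, c(0.23, 0.23, 0.4))
  expect_equal(max(seg), 0)

  lab <- array(0L, c(10, 10, 5)); lab[2:4, 2:4, 2:3] <- 3L
  out <- segment_somas(lab, c(0.5, 0.5, 0.5), bypass = TRUE)
  expect_true(all(out == lab))
  expect_equal(unname(attr(out, "volumes_um3")[["3"]]), 18 * 0.125)
})

test_that("expansion correction is a strict cube law", {
  expect_equal(correct_expansion(800, 2), 100)
  expect_equal(correct_expansion(123.4, 1), 123.4)
  expect_error(correct_expansion(100, 0.8), ">= 1")
  v <- 640
  expect_equal(correct_expansion(v, 4), correct_expansion(v, 2) / 8)
})

test_that("spot assignment conserves every spot", {
  fs <- gen_fish(fish_sim_spec(n_cells = 40, seed = 7))
  asg <- assign_spots(fs$spots, fs$cells)
  expect_equal(sum(asg$counts) + sum(asg$unassigned), nrow(fs$spots))
  # spots far outside any soma are unassigned
  far <- data.frame(gene = "CUX2", x = 1e5, y = 1e5, z = 1e5, quality = 1)
  asg2 <- assign_spots(rbind(fs$spots, far), fs$cells)
  expect_equal(sum(asg2$unassigned), 1)
})

test_that("label-array assignment uses the containing-voxel rule", {
  lab <- array(0L, c(10, 10, 4))
  lab[1:5, , ] <- 1L; lab[6:10, , ] <- 2L
  vx <- c(1, 1, 1)
  # x = 5 is exactly on the 5|6 voxel boundary: half-open bounds put it in
  # voxel 6, i.e. label 2
  sp <- data.frame(gene = "g", x = c(4.9, 5.0), y = 1.5, z = 1.5, quality = 1)
  asg <- assign_spots(sp, lab, voxel_size_um = vx)
  expect_equal(asg$assignment, c(1L, 2L))
})

test_that("molecular classification recovers the two planted classes", {
  fs <- gen_fish(fish_sim_spec(seed = 21), make_spots = FALSE)
  tr <- fs$truth
  cl <- classify_cells(tr$counts, tr$volume_pre_um3, seed = 1)
  expect_gte(ari(cl, tr$class), 0.9)
  # the PY2 name goes to the anchor-high cluster
  d <- attr(cl, "densities")
  expect_gt(mean(d[cl == "PY2", c("CDKN1A", "NFKBIA")]),
            mean(d[cl == "PY1", c("CDKN1A", "NFKBIA")]))
  # invariant to cell order up to the same relabelling
  ord <- sample(nrow(tr$counts))
  cl2 <- classify_cells(tr$counts[ord, ], tr$volume_pre_um3[ord], seed = 1)
  expect_gte(ari(cl2, cl[ord]), 0.999)
})

test_that("single-class input triggers the no-split warning", {
  sp <- fish_sim_spec(n_cells = 120, fraction_py2 = 0.5,
                      radius_meanlog = c(PY1 = log(6), PY2 = log(6)),
                      densities = {
                        m <- matrix(0.05, 6, 2,
                                    dimnames = list(c("NFKBIA", "CDKN1A",
                                                      "CCL2", "CUX2", "NEFM",
                                                      "NEFH"),
                                                    c("PY1", "PY2")))
                        m
                      }, seed = 22)
  fs <- gen_fish(sp, make_spots = FALSE)
  expect_warning(classify_cells(fs$truth$counts, fs$truth$volume_pre_um3,
                                seed = 1),
                 "no-split")
})

test_that("degenerate all-equal profiles return unassigned labels", {
  cnt <- matrix(5L, 20, 6,
                dimnames = list(NULL, c("NFKBIA", "CDKN1A", "CCL2", "CUX2",
                                        "NEFM", "NEFH")))
  cl <- classify_cells(cnt, rep(100, 20), seed = 1)
  expect_true(all(cl == "unassigned"))
})

test_that("density slope is exact on noiseless proportional data", {
  v <- c(10, 20, 30, 40)
  expect_equal(density_slope(0.5 * v, v), 0.5, tolerance = 1e-12)
  expect_equal(density_slope(rep(0, 4), v), 0)
  expect_error(density_slope(1:2, 1:2), ">= 3")
  # ordinary fit differs when an intercept is present in the data
  expect_gt(abs(density_slope(0.5 * v + 3, v, intercept = TRUE) -
                density_slope(0.5 * v + 3, v)), 1e-6)
})

test_that("rendered stacks round-trip through multi-page TIFF up to scale", {
  skip_if_not_installed("tiff")
  fv <- small_volume_sample(seed = 33, n_cells = 2)
  f <- file.path(withr::local_tempdir(), "dapi.tif")
  mx <- write_stack(fv$dapi, f)
  back <- read_stack(f)
  expect_equal(dim(back), dim(fv$dapi))
  expect_equal(back * mx, fv$dapi, tolerance = 1e-5)
})

test_that("paired comparison gates on normality and reports its branch", {
  # identical pairs: p = 1 regardless of branch
  r0 <- per_sample_paired_compare(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_equal(r0$p.value, 1)
  expect_identical(r0$test, "degenerate")

  # clean Gaussian shift: t branch fires and detects it
  set.seed(41)
  x <- rnorm(8); y <- x + 3 / sqrt(8) + rnorm(8, 0, 0.3)
  r1 <- per_sample_paired_compare(x, y)
  expect_identical(r1$test, "paired t")
  expect_lt(r1$p.value, 0.05)

  # heavily skewed differences: signed-rank branch
  set.seed(42)
  d <- rexp(12)^3
  r2 <- per_sample_paired_compare(rep(0, 12), d)
  expect_identical(r2$test, "signed-rank")

  expect_error(per_sample_paired_compare(1:3, 2:4), ">= 4")
})
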