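test_that("Fisher exact p matches enumeration on random small tables", {
  set.seed(101)
  for (i in 1:150) {
    tab <- matrix(rpois(4, sample(2:8, 1)), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0) || sum(tab) > 40) next
    expect_equal(fisher_exact_2x2(tab)$p.value, fisher_oracle(tab),
                 tolerance = 1e-10)
  }
})

test_that("Fisher exact handles extreme and symmetric tables", {
  r <- fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2))
  expect_equal(r$p.value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_true(attr(r$estimate, "haldane"))

  r2 <- fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))
  expect_equal(as.numeric(r2$estimate), 1)
  expect_equal(r2$p.value, 1)
  expect_false(attr(r2$estimate, "haldane"))

  expect_error(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margins")
  expect_error(fisher_exact_2x2(matrix(c(1.5, 2, 3, 4), 2)), "integer")
})

test_that("Mann-Whitney exact branch equals full enumeration", {
  set.seed(102)
  for (i in 1:40) {
    x <- rnorm(4); y <- rnorm(4)
    r <- mann_whitney(x, y)
    expect_identical(r$branch, "exact")
    expect_equal(r$p.value, mw_oracle(x, y), tolerance = 1e-12)
  }
  # unequal sizes too
  x <- rnorm(3); y <- rnorm(7)
  expect_equal(mann_whitney(x, y)$p.value, mw_oracle(x, y), tolerance = 1e-12)
})

test_that("Mann-Whitney degenerate and large-sample behaviour", {
  expect_equal(mann_whitney(rep(2, 5), rep(2, 6))$p.value, 1)
  r <- mann_whitney(rnorm(20), rnorm(20))
  expect_identical(r$branch, "normal")
  # power is monotone in the shift (Monte-Carlo)
  set.seed(103)
  rej <- vapply(c(0, 1, 2), function(shift) {
    mean(replicate(150, mann_whitney(rnorm(10), rnorm(10) + shift)$p.value < 0.05))
  }, numeric(1))
  expect_true(rej[1] < rej[2] && rej[2] < rej[3])
})

test_that("signed-rank exact branch equals enumeration over sign assignments", {
  set.seed(104)
  for (i in 1:25) {
    d <- rnorm(6)
    r <- wilcoxon_signed_rank(d)
    expect_identical(r$branch, "exact")
    expect_equal(r$p.value, signrank_oracle(d), tolerance = 1e-12)
  }
  expect_equal(wilcoxon_signed_rank(rep(0, 6))$p.value, 1)
  expect_identical(wilcoxon_signed_rank(rep(0, 6))$branch, "degenerate")
})

test_that("Kruskal-Wallis H matches the independent statistic on tied data", {
  set.seed(105)
  for (i in 1:25) {
    g <- list(a = sample(1:6, 8, TRUE), b = sample(1:6, 6, TRUE),
              c = sample(1:6, 7, TRUE))
    kd <- kruskal_dunn(g)
    expect_equal(kd$H, kw_stat_oracle(g), tolerance = 1e-10)
  }
})

test_that("Kruskal-Wallis exact branch equals full rank enumeration", {
  set.seed(106)
  for (i in 1:5) {
    g <- list(a = rnorm(3), b = rnorm(3), c = rnorm(3))
    kd <- kruskal_dunn(g)
    expect_identical(kd$branch, "exact")
    # oracle: every distinct assignment of the 9 values into groups of 3,
    # scored with the independent statistic
    x <- unlist(g)
    hs <- c()
    for (s1 in combn(9, 3, simplify = FALSE)) {
      rest <- setdiff(1:9, s1)
      for (s2 in combn(rest, 3, simplify = FALSE)) {
        s3 <- setdiff(rest, s2)
        hs <- c(hs, kw_stat_oracle(list(x[s1], x[s2], x[s3])))
      }
    }
    expect_equal(kd$p.value, mean(hs >= kd$H - 1e-9), tolerance = 1e-10)
  }
})

test_that("identical groups give H near zero and Dunn adjustment is sane", {
  v <- c(3, 1, 4, 1, 5)
  kd <- kruskal_dunn(list(a = v, b = v, c = v), exact_max = 0)
  expect_lt(kd$H, 1e-10)
  expect_true(all(kd$dunn$p_adj >= kd$dunn$p - 1e-12))

  # splitting one group into two identical copies leaves H unchanged; the
  # merged (lower-df) test can only be more significant
  set.seed(107)
  x <- rnorm(8); y <- rnorm(6) + 1
  split3 <- kruskal_dunn(list(a = x, b = y, c = y), exact_max = 0)
  merged <- kruskal_dunn(list(a = x, b = c(y, y)), exact_max = 0)
  expect_equal(split3$H, merged$H, tolerance = 1e-10)
  expect_lte(merged$p.value, split3$p.value + 1e-12)
})

test_that("log-rank matches survival::survdiff and handles edge cases", {
  skip_if_not_installed("survival")
  set.seed(108)
  for (i in 1:10) {
    d <- gen_survival(survival_sim_spec(hazard = c(vehicle = 0.3,
                                                   treated = 0.3 / (i %% 3 + 1)),
                                        seed = 200 + i))
    a1 <- d[d$arm == "vehicle", ]; a2 <- d[d$arm == "treated", ]
    lr <- logrank(a1, a2)
    sd <- survival::survdiff(survival::Surv(time, event) ~ arm, data = d)
    expect_equal(lr$chisq, unname(sd$chisq), tolerance = 1e-8)
  }
  # identical arms: observed = expected
  a <- data.frame(time = c(1, 2, 3, 4), event = c(1, 1, 0, 1))
  lr0 <- logrank(a, a)
  expect_lt(lr0$chisq, 1e-10)
  # censoring-only arm runs without error
  cens <- data.frame(time = rep(5, 6), event = rep(0, 6))
  expect_no_error(logrank(a, cens))
})

test_that("complete separation of arms is strongly significant", {
  a <- data.frame(time = 1:10, event = 1)
  b <- data.frame(time = 1:10 + 20, event = 1)
  expect_lt(logrank(a, b)$p.value, 0.01)
})

test_that("Kaplan-Meier curve matches survival::survfit", {
  skip_if_not_installed("survival")
  set.seed(109)
  tm <- rexp(25); ev <- rbinom(25, 1, 0.8)
  km <- km_curve(tm, ev)
  sf <- survival::survfit(survival::Surv(tm, ev) ~ 1)
  expect_equal(km$surv[-1], sf$surv[sf$n.event > 0], tolerance = 1e-10)
})

test_that("marker fraction report computes per-sample percentages and SEM", {
  cells <- rbind(
    data.frame(sample = "s1", group = "FCD", neun = TRUE,
               marker = rep(c(TRUE, FALSE), c(27, 170))),
    data.frame(sample = "s2", group = "FCD", neun = TRUE, marker = TRUE),
    data.frame(sample = "s3", group = "Control", neun = FALSE, marker = FALSE)
  )
  rep_ <- marker_fraction_report(cells)
  expect_equal(rep_$per_sample$percent[rep_$per_sample$sample == "s1"],
               100 * 27 / 197, tolerance = 1e-12)
  expect_equal(rep_$per_sample$percent[rep_$per_sample$sample == "s2"], 100)
  expect_true(rep_$per_sample$excluded[rep_$per_sample$sample == "s3"])
  expect_false("Control" %in% rep_$summary$group)  # only the empty sample
})
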