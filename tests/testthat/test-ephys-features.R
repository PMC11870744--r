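# build a bare synthetic sweep with template APs injected at known times,
# independent of the generator's LIF machinery
template_sweep <- function(ap_times, dt = 2e-5, dur = 1, base = -60,
                           amp = 80, ahp = 8, hw = 1.2) {
  tt <- seq(0, dur, by = dt)
  v <- rep(base, length(tt))
  tmpl_fun <- episen:::ap_template
  for (t0 in ap_times) {
    idx <- which(tt >= t0 & tt <= t0 + 0.01)
    tm <- tmpl_fun(tt[idx] - t0, amp, ahp, hw)
    dur_t <- attr(tm, "dur")
    sel <- tt[idx] - t0 <= dur_t
    v[idx][sel] <- base + tm[sel]
  }
  list(time = tt, v = v)
}

test_that("flat traces yield no APs and non-uniform grids error", {
  tt <- seq(0, 1, by = 1e-4)
  expect_equal(nrow(detect_aps(tt, rep(-65, length(tt)))), 0)
  bad_t <- c(tt[1:50], tt[52:100])
  expect_error(detect_aps(bad_t, rnorm(99)), "non-uniform")
})

test_that("injected template APs are recovered with accurate parameters", {
  sw <- template_sweep(ap_times = c(0.1, 0.25, 0.4, 0.6, 0.8))
  aps <- detect_aps(sw$time, sw$v)
  expect_equal(nrow(aps), 5)
  expect_true(all(abs(aps$amplitude_mV - 80) < 1))
  expect_true(all(abs(aps$threshold_mV - (-60)) < 1))
  expect_true(all(abs(aps$halfwidth_ms - 1.2) < 0.1))
  expect_true(all(abs(aps$ahp_mV - 8) < 1))
  expect_true(all(abs(sort(aps$peak_time_s) -
                      (c(0.1, 0.25, 0.4, 0.6, 0.8) + 0.6e-3)) < 5e-4))
})

test_that("AP detection is invariant to a constant voltage offset", {
  sw <- template_sweep(ap_times = c(0.2, 0.5))
  a0 <- detect_aps(sw$time, sw$v)
  a1 <- detect_aps(sw$time, sw$v + 17.3)
  expect_equal(a1$amplitude_mV, a0$amplitude_mV, tolerance = 1e-9)
  expect_equal(a1$halfwidth_ms, a0$halfwidth_ms, tolerance = 1e-9)
  expect_equal(a1$threshold_mV, a0$threshold_mV + 17.3, tolerance = 1e-9)
  expect_equal(a1$peak_mV, a0$peak_mV + 17.3, tolerance = 1e-9)
})

test_that("events closer than the refractory window merge into one", {
  sw <- template_sweep(ap_times = c(0.3, 0.301))  # 1 ms apart
  aps <- detect_aps(sw$time, sw$v, refractory_ms = 2)
  expect_equal(nrow(aps), 1)
})

test_that("passive properties are exact on noiseless RC sweeps", {
  spec <- ephys_sim_spec(rin_MOhm = 100, cm_pF = 100, noise_sd_mV = 0)
  ss <- gen_ephys(spec, c(-50, -30, -10))
  pp <- passive_properties(ss)
  expect_equal(pp$rin_MOhm, 100, tolerance = 1e-3)
  expect_equal(pp$tau_ms, 10, tolerance = 0.05)
  expect_equal(pp$cm_pF, 100, tolerance = 0.5)
  expect_equal(pp$rmp_mV, spec$rmp_mV, tolerance = 1e-6)
})

test_that("missing hyperpolarizing sweeps flag the passive features", {
  ss <- gen_ephys(ephys_sim_spec(noise_sd_mV = 0), c(0, 100))
  pp <- passive_properties(ss)
  expect_true(all(c("rin_MOhm", "cm_pF") %in% pp$missing))
  expect_true(is.na(pp$rin_MOhm))
})

test_that("rheobase is the smallest spiking step; boundary is left-censored", {
  spec <- ephys_sim_spec(rheobase_pA = 80, noise_sd_mV = 0)
  ss <- gen_ephys(spec, c(50, 100, 150))
  rb <- find_rheobase(ss)
  expect_equal(rb$rheobase_pA, 100)
  expect_false(rb$left_censored)
  expect_gt(rb$latency_ms, 0)

  ss2 <- gen_ephys(spec, c(120, 150))
  rb2 <- find_rheobase(ss2)
  expect_equal(rb2$rheobase_pA, 120)
  expect_true(rb2$left_censored)

  ss3 <- gen_ephys(spec, c(-50, 20))   # no sweep spikes
  expect_true(is.na(find_rheobase(ss3)$rheobase_pA))
})

test_that("the 13-feature record recovers generator truth", {
  spec <- ephys_sim_spec(noise_sd_mV = 0)
  ss <- gen_ephys(spec, c(-70, -50, -30, 0, 100, 160))
  f <- extract_features(ss)
  expect_length(unclass(f), 13)
  expect_equal(f[["rin_MOhm"]], spec$rin_MOhm, tolerance = 1e-3)
  expect_equal(f[["cm_pF"]], spec$cm_pF, tolerance = 0.01 * spec$cm_pF)
  expect_equal(f[["ap_amplitude_mV"]], spec$ap_amp_mV, tolerance = 1)
  expect_equal(f[["ap_halfwidth_ms"]], spec$ap_halfwidth_ms, tolerance = 0.1)
  expect_equal(f[["ahp_mV"]], spec$ahp_mV, tolerance = 1)
  expect_equal(f[["rheobase_pA"]], 100)  # grid step above the true 80 pA
  # rate features agree with the truth spike times of the largest step
  st <- attr(ss, "truth")$spike_times[[6]]
  isi <- diff(st)
  expect_equal(f[["f_inst_Hz"]], 1 / isi[1], tolerance = 0.05 / isi[1])
  expect_equal(f[["adaptation_index"]], isi[length(isi)] / isi[1],
               tolerance = 0.05)
  # determinism
  expect_identical(unclass(extract_features(ss)), unclass(f))
})

test_that("fast-spiking cells fire faster than regular-spiking at 2x rheobase", {
  fs_spec <- ephys_sim_spec("fast_spiking", noise_sd_mV = 0)
  rs_spec <- ephys_sim_spec("regular_spiking", noise_sd_mV = 0)
  f_fs <- extract_features(gen_ephys(fs_spec, c(-50, 0, 2 * fs_spec$rheobase_pA)))
  f_rs <- extract_features(gen_ephys(rs_spec, c(-50, 0, 2 * rs_spec$rheobase_pA)))
  expect_gt(f_fs[["f_ss_Hz"]], f_rs[["f_ss_Hz"]])
  expect_gt(f_fs[["ahp_mV"]], f_rs[["ahp_mV"]])
  expect_lt(f_fs[["cm_pF"]], f_rs[["cm_pF"]])
})

test_that("sweep sets without suprathreshold steps flag the rate features", {
  ss <- gen_ephys(ephys_sim_spec(noise_sd_mV = 0), c(-50, -20, 0))
  f <- extract_features(ss)
  expect_true(is.na(f[["f_inst_Hz"]]))
  expect_true(all(c("f_inst_Hz", "f_ss_Hz") %in% attr(f, "missing")))
})

test_that("Welch ANOVA matches the textbook two-sample formula", {
  x <- c(27.5, 21.0, 19.0, 23.6, 17.0)
  y <- c(27.1, 22.0, 20.8, 23.4, 23.4)
  df <- data.frame(feat = c(x, y))
  res <- compare_feature_groups(df, rep(c("a", "b"), each = 5))
  expect_equal(res$welch$p, welch_oracle(x, y), tolerance = 1e-10)
})

test_that("group comparison flags features with insufficient data", {
  df <- data.frame(f1 = rnorm(12), f2 = c(rnorm(9), NA, NA, NA))
  g <- rep(c("a", "b", "c"), each = 4)
  res <- compare_feature_groups(df, g, min_per_group = 3)
  expect_true("f2" %in% res$flagged)
  expect_false("f1" %in% res$flagged)
  expect_true(all(c("a-b" , "b-c", "a-c") %in% res$tukey$pair) ||
              all(c("b-a", "c-b", "c-a") %in% res$tukey$pair))
})

test_that("well-separated groups are detected, identical groups are not", {
  set.seed(31)
  x <- rnorm(30); y <- rnorm(30) + 5   # 5 sigma shift
  res <- compare_feature_groups(data.frame(f = c(x, y)),
                                rep(c("a", "b"), each = 30))
  expect_lt(res$welch$p, 1e-6)
  # permuting labels on homogeneous data gives uniform-ish p-values
  z <- rnorm(40)
  ps <- replicate(200, {
    compare_feature_groups(data.frame(f = z),
                           sample(rep(c("a", "b"), each = 20)))$welch$p
  })
  expect_gt(mean(ps), 0.42)
  expect_lt(mean(ps), 0.58)
})
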