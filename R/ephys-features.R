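## Feature extraction from current-clamp sweep sets: action-potential
## detection on the dV/dt criterion, passive membrane properties from
## hyperpolarizing steps, rheobase, and the 13-parameter per-cell summary.

#' Detect action potentials in a single sweep
#'
#' An AP starts where dV/dt first crosses `dvdt_threshold` (mV/ms) on the way
#' up. For each event the threshold voltage is the voltage at that crossing,
#' the peak is the maximum within `peak_window_ms`, the afterhyperpolarization
#' is threshold minus the minimum within `ahp_window_ms` after the peak, and
#' the half-width is measured at threshold + amplitude/2 with linear
#' interpolation. Crossings within `refractory_ms` of a previous event are
#' merged into it, and candidate events with amplitude below `min_amp_mV` are
#' discarded as noise.
#'
#' Detection depends only on voltage differences, so adding a constant offset
#' to the sweep shifts threshold and peak equally and leaves amplitude,
#' half-width and AHP unchanged.
#'
#' @param time uniform time grid (s).
#' @param voltage membrane voltage (mV).
#' @param dvdt_threshold upstroke detection threshold, mV/ms (default 20, the
#'   standard patch-clamp convention).
#' @param refractory_ms minimum separation between events (default 2 ms).
#' @param ahp_window_ms window after the peak searched for the AHP trough.
#' @param peak_window_ms window after the threshold crossing searched for the
#'   peak.
#' @param min_amp_mV minimum accepted amplitude (default 20 mV).
#' @return data frame with one row per AP: `peak_time_s`, `threshold_mV`,
#'   `peak_mV`, `amplitude_mV`, `halfwidth_ms`, `ahp_mV`.
#' @export
detect_aps <- function(time, voltage, dvdt_threshold = 20,
                       refractory_ms = 2, ahp_window_ms = 50,
                       peak_window_ms = 5, min_amp_mV = 20) {
  stopifnot(length(time) == length(voltage))
  dts <- diff(time)
  if (max(abs(dts - dts[1])) > 1e-9 * dts[1])
    stop("non-uniform time grid")
  dt <- dts[1]
  dvdt <- c(NA, diff(voltage)) / (dt * 1000)  # mV/ms
  up <- which(dvdt[-1] >= dvdt_threshold & dvdt[-length(dvdt)] < dvdt_threshold) + 1L
  if (length(up) == 0)
    return(empty_ap_table())
  # merge crossings closer than the refractory period (keep the first;
  # distances re-checked against the last kept event)
  sel <- integer(0); last_t <- -Inf
  for (i in seq_along(up)) {
    if ((time[up[i]] - last_t) * 1000 >= refractory_ms) {
      sel <- c(sel, up[i]); last_t <- time[up[i]]
    }
  }
  up <- sel
  n <- length(voltage)
  events <- lapply(up, function(i0) {
    # threshold = last sample before the dV/dt criterion is exceeded; taking
    # the crossing sample itself would already sit up the steep upstroke
    thr <- voltage[max(i0 - 1L, 1L)]
    i1 <- min(n, i0 + ceiling(peak_window_ms / 1000 / dt))
    ipk <- i0 - 1L + which.max(voltage[i0:i1])
    peak <- voltage[ipk]
    amp <- peak - thr
    if (amp < min_amp_mV) return(NULL)
    # half-width at thr + amp/2, interpolated
    lev <- thr + amp / 2
    t_up <- interp_crossing(time, voltage, from = i0, to = ipk, level = lev,
                            rising = TRUE)
    i2 <- min(n, ipk + ceiling(peak_window_ms * 2 / 1000 / dt))
    t_dn <- interp_crossing(time, voltage, from = ipk, to = i2, level = lev,
                            rising = FALSE)
    hw <- if (is.na(t_up) || is.na(t_dn)) NA_real_ else (t_dn - t_up) * 1000
    i3 <- min(n, ipk + ceiling(ahp_window_ms / 1000 / dt))
    ahp <- if (i3 > ipk) thr - min(voltage[(ipk + 1):i3]) else NA_real_
    data.frame(peak_time_s = time[ipk], threshold_mV = thr, peak_mV = peak,
               amplitude_mV = amp, halfwidth_ms = hw, ahp_mV = ahp)
  })
  events <- do.call(rbind, events)
  if (is.null(events)) empty_ap_table() else events[order(events$peak_time_s), ]
}

empty_ap_table <- function() {
  data.frame(peak_time_s = numeric(0), threshold_mV = numeric(0),
             peak_mV = numeric(0), amplitude_mV = numeric(0),
             halfwidth_ms = numeric(0), ahp_mV = numeric(0))
}

# first crossing of `level` between indices from..to, linearly interpolated
interp_crossing <- function(time, v, from, to, level, rising = TRUE) {
  if (to <= from) return(NA_real_)
  seg <- v[from:to]
  idx <- if (rising) which(seg[-1] >= level & seg[-length(seg)] < level)
         else which(seg[-1] <= level & seg[-length(seg)] > level)
  if (length(idx) == 0) return(NA_real_)
  i <- from + idx[1] - 1L
  f <- (level - v[i]) / (v[i + 1] - v[i])
  time[i] + f * (time[i + 1] - time[i])
}

#' Passive membrane properties from hyperpolarizing steps
#'
#' Resting potential is the median pre-step voltage across all sweeps; input
#' resistance is the through-origin slope of steady-state deflection versus
#' injected current across the hyperpolarizing sweeps; the membrane time
#' constant comes from a single-exponential fit of the step-onset transient of
#' the most hyperpolarized sweep; capacitance is `tau / Rin`.
#'
#' @param ss a `"sweep_set"`.
#' @param ss_frac final fraction of the step window treated as steady state
#'   (default 0.25).
#' @return list with `rmp_mV`, `rin_MOhm`, `tau_ms`, `cm_pF` and a character
#'   vector `missing` naming any feature that could not be computed (e.g. when
#'   no hyperpolarizing sweep exists).
#' @export
passive_properties <- function(ss, ss_frac = 0.25) {
  stopifnot(inherits(ss, "sweep_set"))
  pre <- ss$time < ss$step_window[1]
  rmp <- median(ss$voltage[pre, , drop = FALSE])
  hyp <- which(ss$current_pA < 0)
  if (length(hyp) == 0) {
    return(list(rmp_mV = rmp, rin_MOhm = NA_real_, tau_ms = NA_real_,
                cm_pF = NA_real_, missing = c("rin_MOhm", "tau_ms", "cm_pF")))
  }
  on <- ss$step_window[1]; off <- ss$step_window[2]
  ss_win <- ss$time >= off - (off - on) * ss_frac & ss$time < off
  dv <- vapply(hyp, function(s) {
    mean(ss$voltage[ss_win, s]) - mean(ss$voltage[pre, s])
  }, numeric(1))
  i <- ss$current_pA[hyp]
  rin <- sum(dv * i) / sum(i * i) * 1000   # mV/pA -> MOhm (through origin)

  # tau from the onset transient of the most hyperpolarized sweep
  s_fit <- hyp[which.min(ss$current_pA[hyp])]
  fit_i <- ss$time >= on & ss$time < off
  tt <- ss$time[fit_i] - on
  vv <- ss$voltage[fit_i, s_fit]
  v0 <- mean(ss$voltage[pre, s_fit])
  dv_fit <- dv[match(s_fit, hyp)]
  tau <- fit_exp_tau(tt, vv, v0, dv_fit)
  cm <- if (is.na(tau) || rin <= 0) NA_real_ else 1000 * tau / rin  # pF
  missing <- character(0)
  if (is.na(tau)) missing <- c(missing, "tau_ms", "cm_pF")
  list(rmp_mV = rmp, rin_MOhm = rin, tau_ms = tau, cm_pF = cm,
       missing = missing)
}

# Single-exponential fit v(t) = v0 + dv (1 - exp(-t/tau)); nls seeded from the
# 63% crossing, falling back to the log-linear estimate if nls fails.
fit_exp_tau <- function(tt, vv, v0, dv) {
  if (abs(dv) < 1e-9) return(NA_real_)
  i63 <- which(abs(vv - v0) >= 0.632 * abs(dv))[1]
  tau0 <- if (is.na(i63) || tt[i63] <= 0) max(tt) / 5 else tt[i63]
  fit <- tryCatch(
    suppressWarnings(nls(vv ~ v0f + dvf * (1 - exp(-tt / tau)),
                         start = list(v0f = v0, dvf = dv, tau = tau0),
                         control = list(maxiter = 200, warnOnly = TRUE))),
    error = function(e) NULL)
  if (!is.null(fit)) {
    tau <- coef(fit)[["tau"]]
    if (is.finite(tau) && tau > 0) return(tau * 1000)  # ms
  }
  # log-linear fallback on the residual decay
  resid <- (v0 + dv) - vv
  ok <- resid / dv > 1e-3 & tt > 0
  if (sum(ok) < 3) return(NA_real_)
  sl <- coef(lm(log(resid[ok] / dv) ~ tt[ok]))[2]
  if (sl >= 0) NA_real_ else -1000 / sl
}

#' Find the rheobase sweep
#'
#' The rheobase is the smallest step current whose sweep contains at least one
#' action potential inside the step window. If the lowest tested current
#' already spikes, the value is returned but flagged left-censored.
#'
#' @param ss a `"sweep_set"`.
#' @param ... passed to [detect_aps()].
#' @return list with `rheobase_pA` (NA if no sweep spikes), `aps` (the AP
#'   table of the rheobase sweep), `latency_ms` (step onset to first AP peak)
#'   and `left_censored`.
#' @export
find_rheobase <- function(ss, ...) {
  stopifnot(inherits(ss, "sweep_set"))
  ord <- order(ss$current_pA)
  for (s in ord) {
    if (ss$current_pA[s] <= 0) next
    aps <- detect_aps(ss$time, ss$voltage[, s], ...)
    aps <- aps[aps$peak_time_s >= ss$step_window[1] &
               aps$peak_time_s <= ss$step_window[2] + 0.01, , drop = FALSE]
    if (nrow(aps) > 0) {
      pos <- ss$current_pA[ss$current_pA > 0]
      return(list(rheobase_pA = ss$current_pA[s], aps = aps,
                  latency_ms = (aps$peak_time_s[1] - ss$step_window[1]) * 1000,
                  left_censored = ss$current_pA[s] == min(pos)))
    }
  }
  list(rheobase_pA = NA_real_, aps = empty_ap_table(),
       latency_ms = NA_real_, left_censored = FALSE)
}

#' The 13 electrophysiological parameters of a cell
#'
#' Composes [passive_properties()], [find_rheobase()] and [detect_aps()] into
#' the standard per-cell feature vector: resting potential, input resistance,
#' capacitance, membrane time constant, rheobase, AP threshold / amplitude /
#' half-width / AHP (first AP of the rheobase sweep), rheobase AP latency,
#' instantaneous firing frequency (reciprocal first inter-spike interval at
#' the largest suprathreshold step), steady-state firing frequency
#' (reciprocal mean of the last three intervals) and the adaptation index
#' (last / first interval). Features that cannot be computed are `NA` and
#' listed in the `missing` attribute.
#'
#' @param ss a `"sweep_set"`.
#' @param dvdt_threshold upstroke criterion passed to [detect_aps()].
#' @return named numeric vector of length 13 with class `"ephys_features"`;
#'   attributes `missing` (character) and `left_censored` (logical).
#' @export
extract_features <- function(ss, dvdt_threshold = 20) {
  stopifnot(inherits(ss, "sweep_set"))
  pp <- passive_properties(ss)
  rb <- find_rheobase(ss, dvdt_threshold = dvdt_threshold)
  missing <- pp$missing

  ap_thr <- ap_amp <- ap_hw <- ap_ahp <- lat <- NA_real_
  if (nrow(rb$aps) > 0) {
    ap_thr <- rb$aps$threshold_mV[1]; ap_amp <- rb$aps$amplitude_mV[1]
    ap_hw <- rb$aps$halfwidth_ms[1]; ap_ahp <- rb$aps$ahp_mV[1]
    lat <- rb$latency_ms
  } else {
    missing <- c(missing, "rheobase_pA", "ap_threshold_mV", "ap_amplitude_mV",
                 "ap_halfwidth_ms", "ahp_mV", "ap_latency_ms")
  }

  f_inst <- f_ss <- adapt <- NA_real_
  supra <- which(ss$current_pA > 0)
  if (length(supra) > 0 && !is.na(rb$rheobase_pA)) {
    s_max <- supra[which.max(ss$current_pA[supra])]
    aps <- detect_aps(ss$time, ss$voltage[, s_max],
                      dvdt_threshold = dvdt_threshold)
    aps <- aps[aps$peak_time_s >= ss$step_window[1] &
               aps$peak_time_s <= ss$step_window[2] + 0.01, , drop = FALSE]
    if (nrow(aps) >= 2) {
      isi <- diff(aps$peak_time_s)
      f_inst <- 1 / isi[1]
      f_ss <- 1 / mean(utils::tail(isi, 3))
      if (length(isi) >= 2) adapt <- isi[length(isi)] / isi[1]
    }
  }
  if (is.na(f_inst)) missing <- c(missing, "f_inst_Hz", "f_ss_Hz")
  if (is.na(adapt)) missing <- c(missing, "adaptation_index")

  out <- c(rmp_mV = pp$rmp_mV, rin_MOhm = pp$rin_MOhm, cm_pF = pp$cm_pF,
           tau_ms = pp$tau_ms, rheobase_pA = rb$rheobase_pA,
           ap_threshold_mV = ap_thr, ap_amplitude_mV = ap_amp,
           ap_halfwidth_ms = ap_hw, ahp_mV = ap_ahp, ap_latency_ms = lat,
           f_inst_Hz = f_inst, f_ss_Hz = f_ss, adaptation_index = adapt)
  structure(out, class = "ephys_features", missing = unique(missing),
            left_censored = rb$left_censored, cell_id = ss$cell_id)
}

#' @export
print.ephys_features <- function(x, ...) {
  cat(sprintf("ephys features for '%s':\n", attr(x, "cell_id")))
  print(unclass(x)[seq_along(x)], ...)
  if (length(attr(x, "missing")))
    cat("missing:", paste(attr(x, "missing"), collapse = ", "), "\n")
  invisible(x)
}

#' Feature table for a list of cells
#'
#' @param sweep_sets list of `"sweep_set"` objects.
#' @param ... passed to [extract_features()].
#' @return data frame, one row per cell (rownames = cell ids), 13 feature
#'   columns.
#' @export
extract_features_table <- function(sweep_sets, ...) {
  rows <- lapply(sweep_sets, function(ss) {
    f <- extract_features(ss, ...)
    as.data.frame(as.list(unclass(f)[seq_along(f)]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- vapply(sweep_sets, function(s) s$cell_id, character(1))
  out
}

#' Compare extracted features across clusters
#'
#' For every feature column: Welch's (unequal-variance) one-way ANOVA across
#' groups, followed by Tukey's honestly-significant-difference test on all
#' pairs. Missing values are dropped per feature; a feature is flagged (and
#' reported with NA statistics) if fewer than two groups retain at least
#' `min_per_group` non-missing values.
#'
#' @param features data frame of numeric features (cells x features).
#' @param labels group label per cell.
#' @param min_per_group minimum non-missing values per group (default 3).
#' @return list with `welch` (feature, F, df1, df2, p) and `tukey` (feature,
#'   pair, diff, lwr, upr, p_adj), plus `flagged` feature names.
#' @export
compare_feature_groups <- function(features, labels, min_per_group = 3) {
  stopifnot(nrow(features) == length(labels))
  g_all <- factor(labels)
  if (nlevels(g_all) < 2) stop("need >= 2 groups")
  welch <- list(); tukey <- list(); flagged <- character(0)
  for (f in names(features)) {
    x <- features[[f]]
    ok <- is.finite(x)
    g <- droplevels(g_all[ok]); xv <- x[ok]
    sizes <- table(g)
    if (sum(sizes >= min_per_group) < 2 || nlevels(g) < 2 ||
        all(tapply(xv, g, function(v) var(v) == 0 || length(v) < 2))) {
      flagged <- c(flagged, f)
      welch[[f]] <- data.frame(feature = f, F = NA, df1 = NA, df2 = NA, p = NA)
      next
    }
    wt <- tryCatch(oneway.test(xv ~ g, var.equal = FALSE),
                   error = function(e) NULL)
    if (is.null(wt)) {
      flagged <- c(flagged, f)
      welch[[f]] <- data.frame(feature = f, F = NA, df1 = NA, df2 = NA, p = NA)
      next
    }
    welch[[f]] <- data.frame(feature = f,
                             F = unname(wt$statistic),
                             df1 = unname(wt$parameter[1]),
                             df2 = unname(wt$parameter[2]),
                             p = wt$p.value)
    th <- TukeyHSD(aov(xv ~ g))$g
    tukey[[f]] <- data.frame(feature = f, pair = rownames(th),
                             diff = th[, "diff"], lwr = th[, "lwr"],
                             upr = th[, "upr"], p_adj = th[, "p adj"],
                             row.names = NULL)
  }
  list(welch = do.call(rbind, c(welch, list(make.row.names = FALSE))),
       tukey = do.call(rbind, c(tukey, list(make.row.names = FALSE))),
       flagged = flagged)
}
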