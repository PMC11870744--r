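## Current-clamp sweep simulator: single-compartment RC subthreshold response
## plus an adapting-threshold leaky-integrator spike generator that injects a
## stereotyped action-potential template. The goal is parameter *recovery* by
## the feature extractor, not biophysical realism, so every generating
## parameter (and every realized spike time) is stored in a truth record.

#' Specification for a simulated patch-clamp cell
#'
#' Defaults describe either a regular-spiking pyramidal neuron or a
#' fast-spiking interneuron: interneurons get higher input resistance, smaller
#' capacitance, larger afterhyperpolarization, narrower spikes and weaker
#' spike-frequency adaptation.
#'
#' @param cell_class `"regular_spiking"` or `"fast_spiking"`.
#' @param rmp_mV resting membrane potential (mV).
#' @param rin_MOhm input resistance (MOhm), > 0.
#' @param cm_pF membrane capacitance (pF), > 0; the membrane time constant is
#'   `rin_MOhm * cm_pF / 1000` ms.
#' @param ap_amp_mV spike amplitude from threshold to peak (mV).
#' @param ahp_mV afterhyperpolarization depth below threshold (mV).
#' @param ap_halfwidth_ms spike width at half amplitude (ms).
#' @param rheobase_pA minimum step current that can elicit a spike (pA), > 0.
#'   The spike threshold voltage is `rmp_mV + rheobase_pA * rin_MOhm / 1000`.
#' @param adaptation_ratio target ratio of last to first inter-spike interval
#'   at the reference drive (2x rheobase); 1 = no adaptation.
#' @param noise_sd_mV standard deviation of additive Gaussian voltage noise.
#' @param seed integer RNG seed.
#' @return list of class `"ephys_sim_spec"`.
#' @export
ephys_sim_spec <- function(cell_class = c("regular_spiking", "fast_spiking"),
                           rmp_mV = NULL, rin_MOhm = NULL, cm_pF = NULL,
                           ap_amp_mV = NULL, ahp_mV = NULL,
                           ap_halfwidth_ms = NULL, rheobase_pA = NULL,
                           adaptation_ratio = NULL, noise_sd_mV = 0.2,
                           seed = 1L) {
  cell_class <- match.arg(cell_class)
  def <- if (cell_class == "regular_spiking") {
    list(rmp_mV = -65, rin_MOhm = 150, cm_pF = 150, ap_amp_mV = 80,
         ahp_mV = 8, ap_halfwidth_ms = 1.2, rheobase_pA = 80,
         adaptation_ratio = 1.8)
  } else {
    list(rmp_mV = -67, rin_MOhm = 250, cm_pF = 60, ap_amp_mV = 70,
         ahp_mV = 16, ap_halfwidth_ms = 0.5, rheobase_pA = 60,
         adaptation_ratio = 1.1)
  }
  spec <- list(cell_class = cell_class,
               rmp_mV = rmp_mV %||% def$rmp_mV,
               rin_MOhm = rin_MOhm %||% def$rin_MOhm,
               cm_pF = cm_pF %||% def$cm_pF,
               ap_amp_mV = ap_amp_mV %||% def$ap_amp_mV,
               ahp_mV = ahp_mV %||% def$ahp_mV,
               ap_halfwidth_ms = ap_halfwidth_ms %||% def$ap_halfwidth_ms,
               rheobase_pA = rheobase_pA %||% def$rheobase_pA,
               adaptation_ratio = adaptation_ratio %||% def$adaptation_ratio,
               noise_sd_mV = noise_sd_mV, seed = as.integer(seed))
  with(spec, {
    if (rin_MOhm <= 0 || cm_pF <= 0 || rheobase_pA <= 0 || noise_sd_mV < 0 ||
        ap_amp_mV <= 0 || ahp_mV < 0 || ap_halfwidth_ms <= 0 ||
        adaptation_ratio < 1)
      stop("invalid ephys_sim_spec: rin, cm, rheobase, amp, half-width must be > 0; ",
           "noise_sd >= 0; adaptation_ratio >= 1")
  })
  structure(spec, class = "ephys_sim_spec")
}

# Spike times of the adapting-threshold integrator during a step of I pA,
# starting at step onset, within a window of `dur` s. Closed-form segments:
# the first crossing starts from rest; after each spike the trajectory
# restarts from the AHP trough (threshold - ahp) and relaxes toward
# rmp + I*Rin with the membrane time constant, while the threshold rises by
# theta_inc per emitted spike. The rendered trace uses the same segments, so
# recorded spike times and the trace agree exactly.
lif_spike_times <- function(spec, i_pA, dur, theta_inc, dead_s) {
  tau <- spec$rin_MOhm * spec$cm_pF * 1e-6          # seconds
  target <- spec$rmp_mV + i_pA * spec$rin_MOhm / 1000
  theta0 <- spec$rmp_mV + spec$rheobase_pA * spec$rin_MOhm / 1000
  times <- numeric(0)
  t <- 0; k <- 0
  v0 <- spec$rmp_mV
  repeat {
    theta_k <- theta0 + k * theta_inc
    if (target <= theta_k) break
    dt_cross <- -tau * log((target - theta_k) / (target - v0))
    t <- t + dt_cross
    if (t > dur) break
    times <- c(times, t)
    k <- k + 1
    v0 <- theta_k - spec$ahp_mV
    t <- t + dead_s
    if (t > dur) break
  }
  times
}

# Piecewise-linear AP template sampled on `tt` seconds relative to threshold
# crossing; rises over `tr` to the peak, holds a short plateau `tp` (so the
# sampled maximum equals the true peak regardless of grid phase), then falls
# over `tf` to -ahp (relative to threshold). tr, tp and tf are solved so the
# width at half amplitude equals the requested half-width.
ap_template <- function(tt, amp, ahp, halfwidth_ms) {
  hw <- halfwidth_ms / 1000
  tr <- hw / 2
  tp <- min(2e-4, 0.5 * (hw - tr / 2))
  tf <- (hw - tr / 2 - tp) * (amp + ahp) / (amp / 2)
  tq <- 2e-4                       # sampled trough plateau, same idea as tp
  v <- numeric(length(tt))
  up <- tt >= 0 & tt < tr
  v[up] <- amp * tt[up] / tr
  v[tt >= tr & tt < tr + tp] <- amp
  down <- tt >= tr + tp & tt < tr + tp + tf
  v[down] <- amp - (amp + ahp) * (tt[down] - tr - tp) / tf
  v[tt >= tr + tp + tf & tt <= tr + tp + tf + tq] <- -ahp
  attr(v, "dur") <- tr + tp + tf + tq
  v
}

#' Simulate a current-clamp sweep set
#'
#' Generates one voltage sweep per entry of `step_currents`. Subthreshold
#' responses follow the single-exponential RC law with time constant
#' `rin * cm`; suprathreshold steps fire stereotyped spikes at times given by
#' an adapting-threshold leaky integrator. The per-spike threshold increment
#' is solved so the last/first inter-spike-interval ratio at twice rheobase
#' matches `spec$adaptation_ratio`.
#'
#' @param spec an [ephys_sim_spec()].
#' @param step_currents numeric vector of step amplitudes (pA); must be
#'   non-empty and should span sub- and suprathreshold values for full
#'   feature extraction.
#' @param dt sample interval (s); default 1e-4 (10 kHz).
#' @param sweep_dur total sweep duration (s).
#' @param step_onset,step_offset step window (s).
#' @param cell_id identifier stored in the sweep set.
#' @return a `"sweep_set"` (see [sweep_set()]) with a `truth` attribute:
#'   the spec, the membrane time constant, the solved threshold increment and
#'   the realized spike times per sweep.
#' @examples
#' ss <- gen_ephys(ephys_sim_spec(noise_sd_mV = 0), step_currents = c(-50, 0, 200))
#' range(ss$voltage[, 1])
#' @export
gen_ephys <- function(spec, step_currents, dt = 1e-4, sweep_dur = 1.2,
                      step_onset = 0.1, step_offset = 0.7,
                      cell_id = "cell") {
  stopifnot(inherits(spec, "ephys_sim_spec"))
  if (length(step_currents) == 0) stop("'step_currents' must be non-empty")
  stopifnot(step_onset > 0, step_offset > step_onset, step_offset < sweep_dur)
  tau <- spec$rin_MOhm * spec$cm_pF * 1e-6
  tgrid <- seq(0, sweep_dur, by = dt)
  nt <- length(tgrid)
  dur <- step_offset - step_onset
  tmpl0 <- ap_template(0, spec$ap_amp_mV, spec$ahp_mV, spec$ap_halfwidth_ms)
  dead_s <- attr(tmpl0, "dur")

  # threshold increment that realizes the requested adaptation ratio at 2x
  # rheobase; ratio is monotone increasing in the increment
  theta_inc <- 0
  if (spec$adaptation_ratio > 1) {
    ratio_at <- function(inc) {
      st <- lif_spike_times(spec, 2 * spec$rheobase_pA, dur, inc, dead_s)
      if (length(st) < 3) return(NA_real_)
      isi <- diff(st)
      isi[length(isi)] / isi[1]
    }
    lo <- 0; hi <- 0.05
    while (!is.na(ratio_at(hi)) && ratio_at(hi) < spec$adaptation_ratio &&
           hi < 20) hi <- hi * 2
    if (!is.na(ratio_at(hi))) {
      theta_inc <- tryCatch(
        stats::uniroot(function(i) ratio_at(i) - spec$adaptation_ratio,
                       c(lo, hi))$root,
        error = function(e) hi)
    }
  }

  theta_abs <- spec$rmp_mV + spec$rheobase_pA * spec$rin_MOhm / 1000
  volts <- matrix(NA_real_, nt, length(step_currents))
  spike_times <- vector("list", length(step_currents))
  with_seed(spec$seed, {
    for (s in seq_along(step_currents)) {
      i_pA <- step_currents[s]
      dv_inf <- i_pA * spec$rin_MOhm / 1000
      v <- rep(spec$rmp_mV, nt)
      on_i <- tgrid >= step_onset & tgrid < step_offset
      v[on_i] <- spec$rmp_mV + dv_inf * (1 - exp(-(tgrid[on_i] - step_onset) / tau))
      v_off <- spec$rmp_mV + dv_inf * (1 - exp(-dur / tau))
      post <- tgrid >= step_offset
      v[post] <- spec$rmp_mV + (v_off - spec$rmp_mV) * exp(-(tgrid[post] - step_offset) / tau)

      st <- lif_spike_times(spec, i_pA, dur, theta_inc, dead_s) + step_onset
      if (length(st) > 0) {
        # between spikes the trajectory restarts from the AHP trough toward
        # the step steady state; the template overwrites the spike window
        target <- spec$rmp_mV + dv_inf
        for (k in seq_along(st)) {
          t0 <- st[k]
          thr_k <- theta_abs + (k - 1) * theta_inc
          idx <- which(tgrid >= t0 & tgrid <= t0 + dead_s)
          tmpl <- ap_template(tgrid[idx] - t0, spec$ap_amp_mV, spec$ahp_mV,
                              spec$ap_halfwidth_ms)
          v[idx] <- thr_k + tmpl
          # relaxation from the trough until the next spike (or step end)
          t_rel0 <- t0 + dead_s
          t_rel1 <- if (k < length(st)) st[k + 1] else step_offset
          ridx <- which(tgrid > t_rel0 & tgrid < t_rel1)
          if (length(ridx) > 0) {
            v0 <- thr_k - spec$ahp_mV
            v[ridx] <- target + (v0 - target) * exp(-(tgrid[ridx] - t_rel0) / tau)
          }
        }
        # after step offset, relax from wherever we are back to rest
        last_i <- max(which(tgrid < step_offset))
        post <- tgrid >= step_offset
        v[post] <- spec$rmp_mV +
          (v[last_i] - spec$rmp_mV) * exp(-(tgrid[post] - step_offset) / tau)
      }
      if (spec$noise_sd_mV > 0) v <- v + rnorm(nt, 0, spec$noise_sd_mV)
      volts[, s] <- v
      spike_times[[s]] <- st
    }
  })
  ss <- sweep_set(time = tgrid, voltage = volts, current_pA = step_currents,
                  step_window = c(step_onset, step_offset), cell_id = cell_id)
  attr(ss, "truth") <- list(spec = spec, tau_ms = tau * 1000,
                            theta_inc_mV = theta_inc,
                            theta_mV = theta_abs,
                            spike_times = spike_times)
  ss
}

#' Construct a current-clamp sweep set
#'
#' Container for one cell's current-clamp recording: a shared uniform time
#' grid, one voltage column per sweep, the step current of each sweep and the
#' common step window.
#'
#' @param time uniform time grid (s).
#' @param voltage matrix (time x sweeps) of membrane voltage (mV).
#' @param current_pA step current per sweep (pA).
#' @param step_window length-2 numeric, step onset/offset (s).
#' @param cell_id character id.
#' @return list of class `"sweep_set"`.
#' @export
sweep_set <- function(time, voltage, current_pA, step_window, cell_id = "cell") {
  voltage <- as.matrix(voltage)
  stopifnot(length(time) == nrow(voltage),
            length(current_pA) == ncol(voltage),
            length(step_window) == 2, step_window[1] < step_window[2])
  dts <- diff(time)
  if (max(abs(dts - dts[1])) > 1e-9 * dts[1])
    stop("time grid must be uniform")
  if (step_window[1] < time[1] || step_window[2] > time[length(time)])
    stop("step window must lie within the recorded interval")
  structure(list(time = time, voltage = voltage,
                 current_pA = as.numeric(current_pA),
                 step_window = as.numeric(step_window),
                 cell_id = cell_id, dt = dts[1]),
            class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("sweep_set '%s': %d sweeps, %.3g s at %.0f kHz, steps %g..%g pA\n",
              x$cell_id, ncol(x$voltage), max(x$time), 1e-3 / x$dt,
              min(x$current_pA), max(x$current_pA)))
  invisible(x)
}

#' Write / read a sweep set as plain text
#'
#' The voltage traces go to `<prefix>_sweeps.tsv` (column `time_s` then one
#' `mV` column per sweep) and the stimulus descriptor to `<prefix>_stim.tsv`
#' (sweep, current_pA, onset_s, offset_s, cell_id).
#'
#' @param x a `"sweep_set"`.
#' @param prefix path prefix for the two files.
#' @return `write_sweeps` returns the two file paths invisibly; `read_sweeps`
#'   returns the reconstructed `"sweep_set"`.
#' @export
write_sweeps <- function(x, prefix) {
  stopifnot(inherits(x, "sweep_set"))
  sw <- data.frame(time_s = x$time, x$voltage)
  names(sw) <- c("time_s", paste0("sweep", seq_len(ncol(x$voltage))))
  f1 <- paste0(prefix, "_sweeps.tsv"); f2 <- paste0(prefix, "_stim.tsv")
  write.table(sw, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  stim <- data.frame(sweep = seq_along(x$current_pA),
                     current_pA = x$current_pA,
                     onset_s = x$step_window[1], offset_s = x$step_window[2],
                     cell_id = x$cell_id)
  write.table(stim, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(f1, f2))
}

#' @rdname write_sweeps
#' @export
read_sweeps <- function(prefix) {
  sw <- read.delim(paste0(prefix, "_sweeps.tsv"))
  stim <- read.delim(paste0(prefix, "_stim.tsv"))
  sweep_set(time = sw$time_s,
            voltage = as.matrix(sw[, -1, drop = FALSE]),
            current_pA = stim$current_pA,
            step_window = c(stim$onset_s[1], stim$offset_s[1]),
            cell_id = as.character(stim$cell_id[1]))
}
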