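## Generators for the histology contingency counts and the two-arm survival
## records, with recorded ground truth.

#' Specification for simulated marker-positivity counts
#'
#' Emulates per-sample immunostaining counts: each sample contributes SMI+
#' (dysmorphic) and SMI- neurons, and every neuron is marker-positive with a
#' class-specific probability.
#'
#' @param n_samples number of tissue samples (default 5).
#' @param n_smi_pos,n_smi_neg neurons counted per sample in each class.
#' @param p_marker named numeric, marker-positivity probability for
#'   `smi_pos` and `smi_neg` (both in `[0, 1]`).
#' @param seed integer RNG seed.
#' @return list of class `"histo_sim_spec"`.
#' @export
histo_sim_spec <- function(n_samples = 5, n_smi_pos = 60, n_smi_neg = 200,
                           p_marker = c(smi_pos = 0.6, smi_neg = 0.08),
                           seed = 1L) {
  if (any(p_marker < 0) || any(p_marker > 1))
    stop("marker probabilities must be in [0, 1]")
  stopifnot(all(c("smi_pos", "smi_neg") %in% names(p_marker)),
            n_samples >= 1, n_smi_pos >= 1, n_smi_neg >= 1)
  structure(list(n_samples = as.integer(n_samples),
                 n_smi_pos = as.integer(n_smi_pos),
                 n_smi_neg = as.integer(n_smi_neg),
                 p_marker = p_marker, seed = as.integer(seed)),
            class = "histo_sim_spec")
}

#' Simulate per-sample 2x2 marker-by-class contingency tables
#'
#' @param spec a [histo_sim_spec()].
#' @return list of 2x2 matrices (rows SMI+/SMI-, columns marker+/marker-),
#'   one per sample, with a `truth` attribute recording the spec. The pooled
#'   table is available via `Reduce("+", tables)`.
#' @export
gen_histo <- function(spec) {
  stopifnot(inherits(spec, "histo_sim_spec"))
  with_seed(spec$seed, {
    tabs <- lapply(seq_len(spec$n_samples), function(s) {
      kp <- rbinom(1, spec$n_smi_pos, spec$p_marker[["smi_pos"]])
      kn <- rbinom(1, spec$n_smi_neg, spec$p_marker[["smi_neg"]])
      m <- matrix(c(kp, spec$n_smi_pos - kp, kn, spec$n_smi_neg - kn),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(c("SMI+", "SMI-"),
                                  c("marker+", "marker-")))
      m
    })
    names(tabs) <- sprintf("sample%02d", seq_len(spec$n_samples))
    attr(tabs, "truth") <- list(spec = spec)
    tabs
  })
}

#' Specification for a two-arm survival simulation
#'
#' Exponential event times per arm with administrative (right) censoring at a
#' fixed time. Defaults emulate the mouse lifespan experiment: 18 vehicle vs
#' 10 treated animals, with treatment reducing the hazard.
#'
#' @param n named integer vector, subjects per arm.
#' @param hazard named numeric vector, exponential hazard per arm (> 0),
#'   in 1/week.
#' @param censor_time administrative censoring time (weeks).
#' @param seed integer RNG seed.
#' @return list of class `"survival_sim_spec"`.
#' @export
survival_sim_spec <- function(n = c(vehicle = 18, treated = 10),
                              hazard = c(vehicle = 0.33, treated = 0.08),
                              censor_time = 20, seed = 1L) {
  if (any(hazard <= 0)) stop("hazards must be > 0")
  stopifnot(identical(names(n), names(hazard)), length(n) == 2,
            censor_time > 0)
  structure(list(n = n, hazard = hazard, censor_time = censor_time,
                 seed = as.integer(seed)), class = "survival_sim_spec")
}

#' Simulate two-arm survival records
#'
#' @param spec a [survival_sim_spec()].
#' @return data frame with `arm`, `time`, `event` (1 = death observed,
#'   0 = administratively censored) and a `truth` attribute.
#' @export
gen_survival <- function(spec) {
  stopifnot(inherits(spec, "survival_sim_spec"))
  with_seed(spec$seed, {
    rows <- lapply(names(spec$n), function(a) {
      t_raw <- rexp(spec$n[[a]], rate = spec$hazard[[a]])
      data.frame(arm = a,
                 time = pmin(t_raw, spec$censor_time),
                 event = as.integer(t_raw <= spec$censor_time),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    attr(out, "truth") <- list(spec = spec)
    out
  })
}
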