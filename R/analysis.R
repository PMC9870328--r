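#' @title Spike-train analysis
#'
#' @description
#' The evaluation toolbox for simulated traces: threshold spike detection
#' with sub-grid interpolation, interspike-interval (ISI) sequences and
#' their coefficient of variation (CV) and local variation (LV), burst
#' segmentation, phase-resetting curves (PRC), graded-response curves, the
#' ISI-transition experiment, and mean-square-error comparison of matched
#' point sets.  A seeded Poisson spike-train generator provides the
#' calibration fixture for the LV statistic (whose Poisson expectation is
#' one by construction).
#'
#' @name analysis
NULL

# run expr with a private, restored RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Construct a spike train
#'
#' @param times Strictly increasing, non-negative spike times in seconds.
#' @param source Provenance note (free text).
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(times, source = "unspecified") {
  times <- as.numeric(times)
  if (length(times)) {
    if (any(times < 0))
      .pqn_stop("spike times must be non-negative", "pqn_domain_error")
    if (any(diff(times) <= 0))
      .pqn_stop("spike times must be strictly increasing", "pqn_domain_error")
  }
  structure(list(times = times, source = source), class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("spike train: %d spikes (%s)\n", length(x$times), x$source))
  invisible(x)
}

#' @export
length.spike_train <- function(x) length(x$times)

#' Interspike-interval sequence
#'
#' @param x A `spike_train`, or a numeric vector of intervals in seconds.
#' @return An object of class `isi_sequence` with fields `intervals`,
#'   `mean` and `m` (the interval count).
#' @export
isi_sequence <- function(x) {
  intervals <- if (inherits(x, "spike_train")) diff(x$times)
  else as.numeric(x)
  if (any(intervals <= 0))
    .pqn_stop("ISIs must be positive", "pqn_domain_error")
  structure(list(intervals = intervals,
                 mean = if (length(intervals)) mean(intervals) else NaN,
                 m = length(intervals)),
            class = "isi_sequence")
}

.as_isis <- function(x) {
  if (inherits(x, "isi_sequence")) x else isi_sequence(x)
}

#' Detect spikes in a simulated trace
#'
#' A spike is recorded at each upward threshold crossing
#' (`v[j-1] < threshold <= v[j]`), with the sub-grid time obtained by
#' linear interpolation between the two samples.  Crossings within
#' `min_separation` of the previous accepted spike are suppressed
#' (debounce).  The PQN model has no stereotyped spike event, so the
#' default threshold is `v = 0`, the junction of the `f` nullcline.
#'
#' @param trace A `pqn_trace` (or any data frame with `time` and `v`).
#' @param threshold Crossing threshold on `v` (default 0).
#' @param min_separation Debounce interval in seconds; defaults to twice
#'   the trace's grid spacing.
#' @return A `spike_train` of interpolated crossing times.
#' @export
detect_spikes <- function(trace, threshold = 0, min_separation = NULL) {
  stopifnot(is.data.frame(trace), nrow(trace) >= 1L,
            all(c("time", "v") %in% names(trace)))
  tt <- trace$time; v <- trace$v
  if (is.null(min_separation)) {
    dt <- if (nrow(trace) > 1L) tt[2] - tt[1] else 0
    min_separation <- 2 * dt
  }
  j <- which(v[-1] >= threshold & v[-length(v)] < threshold) + 1L
  if (!length(j))
    return(spike_train(numeric(0), source = "detect_spikes"))
  frac <- (threshold - v[j - 1L]) / (v[j] - v[j - 1L])
  cand <- tt[j - 1L] + frac * (tt[j] - tt[j - 1L])
  keep <- numeric(0)
  last <- -Inf
  for (tc in cand) {
    if (tc - last >= min_separation) {
      keep <- c(keep, tc)
      last <- tc
    }
  }
  spike_train(keep, source = "detect_spikes")
}

#' Coefficient of variation of ISIs
#'
#' `CV = sd(T) / mean(T)` with the sample (m-1 denominator) standard
#' deviation; zero for constant ISIs and one in expectation for a Poisson
#' train.
#'
#' @param isis An `isi_sequence`, `spike_train` or numeric interval vector
#'   with at least two intervals.
#' @return The CV (dimensionless).
#' @export
cv_stat <- function(isis) {
  isis <- .as_isis(isis)
  if (isis$m < 2L)
    .pqn_stop("CV is undefined for fewer than two ISIs", "pqn_stat_error")
  stats::sd(isis$intervals) / isis$mean
}

#' Local variation of ISIs
#'
#' `LV = (1/(m-1)) * sum_{i=1}^{m-1} 3 (T_i - T_{i+1})^2 / (T_i + T_{i+1})^2`
#' where `m` is the number of intervals.  The factor 3 normalises the
#' Poisson expectation to one; constant ISIs give exactly zero.  Unlike the
#' CV, the LV is sensitive to the ordering of intervals and captures local
#' (adjacent-interval) fluctuation, which is what makes it large for
#' bursting trains.
#'
#' @inheritParams cv_stat
#' @return The LV (dimensionless).
#' @export
lv_stat <- function(isis) {
  isis <- .as_isis(isis)
  if (isis$m < 2L)
    .pqn_stop("LV is undefined for fewer than two ISIs", "pqn_stat_error")
  Ti <- isis$intervals[-isis$m]
  Tj <- isis$intervals[-1L]
  sum(3 * (Ti - Tj)^2 / (Ti + Tj)^2) / (isis$m - 1L)
}

#' Seeded Poisson spike train
#'
#' Spike times are cumulative sums of `n_intervals + 1` i.i.d.
#' exponential(rate) draws, so the train carries exactly `n_intervals`
#' ISIs.  The global RNG state is left untouched.
#'
#' @param rate Event rate in events/second.
#' @param n_intervals Number of ISIs (`>= 1`).
#' @param seed Integer seed; identical seeds give identical trains.
#' @return A `spike_train`.
#' @export
poisson_spike_train <- function(rate, n_intervals, seed) {
  stopifnot(rate > 0, n_intervals >= 1)
  times <- .with_seed(seed, cumsum(stats::rexp(n_intervals + 1L, rate)))
  spike_train(times, source = sprintf("poisson(rate=%g, seed=%d)",
                                      rate, as.integer(seed)))
}

#' Phase-resetting curve of an oscillating PQN neuron
#'
#' Drives the model with the constant stimulus `I_base`, requires a stable
#' oscillation (at least 10 post-transient ISIs, each within `2 dt` of
#' their mean), and measures the first-order phase shift produced by a
#' brief pulse.  With `T` the unperturbed period and `t_s` a
#' post-transient spike time, a pulse of amplitude `pulse_amp` and
#' duration `pulse_dur` is applied at `t_i = t_s + theta * T` for each
#' phase `theta = j/n_phases`; the perturbed cycle length `T_i` is the
#' interval from the spike at `t_s` to the next spike, and the shift is
#' `Delta(theta) = (T - T_i)/T` (positive = advanced).
#'
#' @inheritParams pqn_simulate
#' @param I_base Constant stimulus driving periodic spiking.
#' @param pulse_amp Pulse amplitude (added on top of `I_base`).
#' @param pulse_dur Pulse duration in seconds.
#' @param n_phases Number of equally spaced phases in `[0, 1)`.
#' @param t_max Duration of each simulation (default 2 s).
#' @param transient_frac Fraction of the record discarded as transient
#'   (default 0.2).
#' @return An object of class `pqn_prc`: a list with the baseline period
#'   `T`, vectors `theta` and `delta`, and the pulse parameters.
#' @export
compute_prc <- function(p, I_base, pulse_amp, pulse_dur, n_phases = 20L,
                        t_max = 2, transient_frac = 0.2, backend = "float",
                        qfmt = NULL) {
  stopifnot(inherits(p, "pqn_params"), n_phases >= 1L, pulse_dur > 0)
  base <- pqn_simulate(p, stim_const(I_base), t_max, backend = backend,
                       qfmt = qfmt)
  dt <- attr(base, "dt")
  sp <- detect_spikes(base)
  t_cut <- transient_frac * t_max
  st <- sp$times[sp$times >= t_cut]
  if (length(st) < 12L)
    .pqn_stop("no stable oscillation: too few post-transient spikes",
              "pqn_precondition_error")
  isis <- diff(st)
  # require >= 10 consecutive stable ISIs, leaving >= 2 cycles after t_s
  if (sum(abs(isis - mean(isis)) <= 2 * dt) < 10L)
    .pqn_stop("no stable oscillation: post-transient ISIs not periodic",
              "pqn_precondition_error")
  T_per <- mean(isis)
  t_s <- st[1L]
  if (t_s + 2 * T_per > t_max)
    .pqn_stop("t_max too short to measure a perturbed cycle",
              "pqn_precondition_error")
  theta <- (seq_len(n_phases) - 1L) / n_phases
  delta <- vapply(theta, function(th) {
    t_i <- t_s + th * T_per
    stim <- stimulus_program(c(0, t_i, t_i + pulse_dur),
                             c(I_base, I_base + pulse_amp, I_base))
    tr <- pqn_simulate(p, stim, t_max, backend = backend, qfmt = qfmt)
    ps <- detect_spikes(tr)$times
    idx <- which.min(abs(ps - t_s))
    if (idx >= length(ps))
      .pqn_stop("perturbed cycle has no terminating spike",
                "pqn_precondition_error")
    T_i <- ps[idx + 1L] - ps[idx]
    (T_per - T_i) / T_per
  }, numeric(1))
  structure(list(T = T_per, theta = theta, delta = delta,
                 pulse_amp = pulse_amp, pulse_dur = pulse_dur,
                 I_base = I_base),
            class = "pqn_prc")
}

#' @export
print.pqn_prc <- function(x, ...) {
  cat(sprintf(
    "PRC: period %.5g s, pulse amp %g for %g s, %d phases, delta in [%.4g, %.4g]\n",
    x$T, x$pulse_amp, x$pulse_dur, length(x$theta),
    min(x$delta), max(x$delta)))
  invisible(x)
}

#' Graded-response curve
#'
#' Simulates the model from rest and records the peak membrane potential
#' after a brief pulse, for each pulse amplitude.  Class II neurons show a
#' graded response: the spike peak grows continuously with the pulse
#' magnitude instead of being stereotyped.
#'
#' @inheritParams pqn_simulate
#' @param amplitudes Pulse amplitudes to test.
#' @param pulse_t0 Pulse onset in seconds (default 0.1).
#' @param pulse_dur Pulse duration in seconds (default 0.002).
#' @param t_max Simulation length (default `pulse_t0 + 0.15`).
#' @return A data frame with columns `amplitude` and `peak_v`.
#' @export
graded_response_curve <- function(p, amplitudes, pulse_t0 = 0.1,
                                  pulse_dur = 0.002,
                                  t_max = pulse_t0 + 0.15,
                                  backend = "float", qfmt = NULL) {
  stopifnot(inherits(p, "pqn_params"), length(amplitudes) >= 1L)
  peaks <- vapply(amplitudes, function(a) {
    stim <- if (a == 0) stim_const(0) else stim_pulse(pulse_t0, pulse_dur, a)
    tr <- pqn_simulate(p, stim, t_max, backend = backend, qfmt = qfmt)
    max(tr$v[tr$time >= pulse_t0])
  }, numeric(1))
  data.frame(amplitude = as.numeric(amplitudes), peak_v = peaks)
}

#' ISI-transition experiment
#'
#' For each step amplitude, applies a step input from `t_on` and returns
#' the ordered list of ISIs (index versus length).  This is the standard
#' readout of spike-frequency adaptation (ISIs grow with index) and of
#' initial bursting (first ISIs much shorter than the asymptotic ISI).
#'
#' @inheritParams pqn_simulate
#' @param step_amps Step amplitudes (non-empty).
#' @param t_on Step onset in seconds.
#' @param t_max Simulation length in seconds.
#' @return A named list (one entry per amplitude) of numeric ISI vectors;
#'   an amplitude below rheobase yields a zero-length vector.
#' @export
isi_transition_experiment <- function(p, step_amps, t_on, t_max,
                                      backend = "float", qfmt = NULL) {
  stopifnot(inherits(p, "pqn_params"), length(step_amps) >= 1L)
  out <- lapply(step_amps, function(a) {
    tr <- pqn_simulate(p, stim_step(t_on, a), t_max, backend = backend,
                       qfmt = qfmt)
    st <- detect_spikes(tr)$times
    st <- st[st >= t_on]
    if (length(st) < 2L) numeric(0) else diff(st)
  })
  names(out) <- as.character(step_amps)
  out
}

#' Mean square error over matched data points
#'
#' For scalar points, the mean of squared componentwise differences; for
#' two-column matrices (e.g. points on the CV-LV plane), the mean over
#' points of the squared Euclidean distance.
#'
#' @param a,b Numeric vectors or matrices of equal dimensions.
#' @return A scalar MSE.
#' @export
mse_points <- function(a, b) {
  if (is.matrix(a) || is.matrix(b)) {
    a <- as.matrix(a); b <- as.matrix(b)
    if (!all(dim(a) == dim(b)))
      .pqn_stop("mse_points requires matched dimensions", "pqn_config_error")
    stopifnot(all(is.finite(a)), all(is.finite(b)))
    return(mean(rowSums((a - b)^2)))
  }
  if (length(a) != length(b))
    .pqn_stop("mse_points requires equal lengths", "pqn_config_error")
  stopifnot(all(is.finite(a)), all(is.finite(b)))
  mean((a - b)^2)
}

#' Segment a spike train into bursts
#'
#' A new burst starts whenever an ISI exceeds `gap_threshold`.  The
#' default threshold is five times the median ISI, which is scale-free
#' across the bursting classes.  Leading and trailing bursts may be
#' truncated by the recording window; they are flagged (`edge`), not
#' dropped.
#'
#' @param train A `spike_train` with at least one spike.
#' @param gap_threshold Burst-separating ISI in seconds (default
#'   `5 * median(ISI)`).
#' @return An object of class `burst_summary`: `spikes_per_burst`
#'   (integer), `interburst_intervals` (last spike of one burst to first
#'   of the next, seconds), `edge` (logical flag per burst) and the
#'   threshold used.
#' @export
segment_bursts <- function(train, gap_threshold = NULL) {
  stopifnot(inherits(train, "spike_train"), length(train$times) >= 1L)
  tt <- train$times
  isis <- diff(tt)
  if (is.null(gap_threshold)) {
    if (!length(isis))
      .pqn_stop("gap_threshold required for a single-spike train",
                "pqn_config_error")
    gap_threshold <- 5 * stats::median(isis)
  }
  stopifnot(gap_threshold > 0)
  breaks <- which(isis > gap_threshold)        # burst ends at index `breaks`
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(tt))
  counts <- ends - starts + 1L
  inter <- if (length(breaks)) tt[breaks + 1L] - tt[breaks] else numeric(0)
  edge <- rep(FALSE, length(counts))
  edge[1L] <- TRUE
  edge[length(edge)] <- TRUE
  structure(list(spikes_per_burst = as.integer(counts),
                 interburst_intervals = inter,
                 edge = edge,
                 gap_threshold = gap_threshold),
            class = "burst_summary")
}

#' @export
print.burst_summary <- function(x, ...) {
  cat(sprintf(
    "bursts: %d (spikes per burst %s), %d interburst interval(s), gap > %.4g s\n",
    length(x$spikes_per_burst),
    paste(x$spikes_per_burst, collapse = ","),
    length(x$interburst_intervals), x$gap_threshold))
  invisible(x)
}
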