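#' @title Hardware-planning arithmetic
#'
#' @description
#' In the FPGA implementation of the PQN model, every multiplication of a
#' state variable by a constant coefficient is realised as a network of
#' shifters and adders: one arithmetic right shift per set bit of the
#' coefficient's fixed-point binary representation.  The number of set bits
#' is therefore a direct proxy for circuit resources.  The only true
#' multiplier is the one computing `v^2`, which maps onto DSP slices; the
#' number of slices follows from tiling the operand width onto the DSP's
#' native 25 x 18-bit multiplier.  Finally, a single shared update engine
#' serves many neurons per time step, so the real-time neuron capacity is a
#' simple cycle budget: clock cycles per step minus pipeline and FIFO
#' latency.
#'
#' @name hardware
NULL

#' Decompose a constant coefficient into a shift-add plan
#'
#' Quantizes the magnitude of `c` to `fraction_bits` fractional bits and
#' returns the set of one-bit positions of the plain binary representation.
#' Position `p` contributes `2^-p`, so fractional bits have `p > 0` and
#' integer-part bits have `p <= 0` (e.g. `c = 1` gives the single position
#' `0`).  Plain binary (not canonical signed digit) is used because the
#' resource proxy counts ones in the binary representation; negative
#' coefficients are decomposed by magnitude with the sign carried alongside.
#'
#' @param c Coefficient (single finite numeric; zero yields an empty plan).
#' @param fraction_bits Number of fractional bits to quantize to.
#' @param rounding `"nearest"` (default) or `"truncate"` (toward zero on the
#'   magnitude).
#' @return An object of class `shift_add_plan` with fields `sign` (+1/-1),
#'   `shifts` (sorted bit positions), `reconstructed_value` (the quantized
#'   coefficient, reconstructed exactly as `sign * sum(2^-shifts)`),
#'   `ones_count`, `fraction_bits` and the requested `coefficient`.
#' @export
#' @examples
#' decompose_coefficient(0.037109375, 10)  # binary 0.000010011 -> {5, 8, 9}
decompose_coefficient <- function(c, fraction_bits,
                                  rounding = c("nearest", "truncate")) {
  stopifnot(is.numeric(c), length(c) == 1L, is.finite(c))
  rounding <- match.arg(rounding)
  fraction_bits <- as.integer(fraction_bits)
  stopifnot(fraction_bits >= 0L)
  scaled <- abs(c) * 2^fraction_bits
  m <- if (rounding == "truncate") floor(scaled) else round(scaled)
  if (m > 2^52)
    .pqn_stop("coefficient magnitude too large for exact decomposition",
              "pqn_domain_error")
  shifts <- integer(0)
  j <- 0L
  mm <- m
  while (mm > 0) {
    if (mm %% 2 == 1) shifts <- c(shifts, fraction_bits - j)
    mm <- mm %/% 2
    j <- j + 1L
  }
  shifts <- sort(shifts)
  sgn <- if (c < 0) -1 else 1
  structure(list(
    sign = sgn,
    shifts = shifts,
    reconstructed_value = sgn * m / 2^fraction_bits,
    ones_count = length(shifts),
    fraction_bits = fraction_bits,
    coefficient = c
  ), class = "shift_add_plan")
}

#' @export
print.shift_add_plan <- function(x, ...) {
  cat(sprintf("shift-add plan for %.17g (%d fraction bits):\n",
              x$coefficient, x$fraction_bits))
  cat(sprintf("  sign %+d, shifts {%s}, %d adder stage(s), value %.17g\n",
              x$sign, paste(x$shifts, collapse = ", "),
              x$ones_count, x$reconstructed_value))
  invisible(x)
}

#' DSP slices required for a squared operand
#'
#' A hard DSP slice multiplies `dsp_a`-bit by `dsp_b`-bit operands (25 x 18
#' on the target device).  A full `operand_bits x operand_bits` product is
#' tiled onto `ceiling(n/dsp_a) * ceiling(n/dsp_b)` slices.
#'
#' @param operand_bits Width of the squared state variable, in bits.
#' @param dsp_a,dsp_b Native DSP operand widths (defaults 25 and 18).
#' @return Integer slice count: 1 for 18-bit operands, 4 for 28-bit.
#' @export
dsp_tiles <- function(operand_bits, dsp_a = 25L, dsp_b = 18L) {
  stopifnot(operand_bits >= 1, dsp_a >= 1, dsp_b >= 1)
  as.integer(ceiling(operand_bits / dsp_a) * ceiling(operand_bits / dsp_b))
}

#' Real-time cycle budget and neuron capacity
#'
#' One shared update engine computes all neurons of a unit each time step.
#' At a clock of `clock_hz` the step `dt` offers `round(clock_hz * dt)`
#' cycles; the engine pipeline occupies `engine_latency_cycles` and FIFO
#' reads/writes `fifo_cycles`, so the remaining cycles bound the number of
#' neurons `N` the unit can serve in real time.
#'
#' @param clock_hz Clock frequency in Hz.
#' @param dt Simulation time step in seconds.
#' @param engine_latency_cycles Pipeline depth of the update engine
#'   (default 4).
#' @param fifo_cycles FIFO read/write latency (default 3).
#' @return An object of class `cycle_budget` with integer fields
#'   `clock_hz`, `dt`, `cycles_per_step`, `engine_latency_cycles`,
#'   `fifo_cycles` and `capacity` (`N`).
#' @export
#' @examples
#' cycle_budget(100e6, 1e-4)$capacity  # 9993 neurons at 0.1 ms steps
#' cycle_budget(100e6, 1e-3)$capacity  # 99993 at 1 ms steps
cycle_budget <- function(clock_hz, dt, engine_latency_cycles = 4L,
                         fifo_cycles = 3L) {
  stopifnot(clock_hz > 0, dt > 0,
            engine_latency_cycles >= 0, fifo_cycles >= 0)
  cycles <- round(clock_hz * dt)
  capacity <- cycles - engine_latency_cycles - fifo_cycles
  if (capacity < 0)
    .pqn_stop("cycle budget is negative: dt too short for the latencies",
              "pqn_domain_error")
  structure(list(
    clock_hz = clock_hz,
    dt = dt,
    cycles_per_step = cycles,
    engine_latency_cycles = as.integer(engine_latency_cycles),
    fifo_cycles = as.integer(fifo_cycles),
    capacity = capacity
  ), class = "cycle_budget")
}

#' @export
print.cycle_budget <- function(x, ...) {
  cat(sprintf(
    "cycle budget: %g Hz clock, dt %g s -> %g cycles/step; engine %d + FIFO %d -> N = %g neurons\n",
    x$clock_hz, x$dt, x$cycles_per_step, x$engine_latency_cycles,
    x$fifo_cycles, x$capacity))
  invisible(x)
}
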