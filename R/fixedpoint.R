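#' @title Fixed-point (Q-format) arithmetic emulation
#'
#' @description
#' Bit-exact emulation of the two's-complement fixed-point arithmetic used
#' by the hardware implementation of the PQN model.  A Q-format is written
#' `q<total>.<integer>` (e.g. `q18.8`, `q28.8`); the integer part INCLUDES
#' the sign bit, so `q18.8` has 10 fraction bits and `q28.8` has 20.  A
#' fixed value stores a signed integer `raw`; its real value is
#' `raw * 2^-fraction_bits`.
#'
#' Raw integers are carried in doubles.  Products of wide formats can exceed
#' the 53-bit exact-integer range of a double, so multiplication is
#' performed on base-2^20 limbs with an exact long division by the
#' fraction-bit power of two; results are therefore bit-exact for any
#' supported format (total width up to 40 bits, fraction bits up to 32).
#'
#' @name fixedpoint
NULL

.pqn_fx_state <- new.env(parent = emptyenv())
.pqn_fx_state$overflows <- 0L

#' Fixed-point format
#'
#' @param total_bits Total word width in bits.
#' @param integer_bits Width of the integer part, including the sign bit.
#' @return An object of class `qformat` with fields `total_bits`,
#'   `integer_bits` and `fraction_bits`.
#' @export
#' @examples
#' qformat(18, 8)     # 10 fraction bits, resolution 2^-10
#' qformat("q28.8")   # spec-string form
qformat <- function(total_bits, integer_bits = NULL) {
  if (is.character(total_bits)) {
    m <- regmatches(total_bits,
                    regexec("^q([0-9]+)\\.([0-9]+)$", total_bits))[[1]]
    if (length(m) != 3L)
      .pqn_stop(paste0("cannot parse Q-format spec: ", total_bits),
                "pqn_config_error")
    integer_bits <- as.integer(m[3]); total_bits <- as.integer(m[2])
  }
  total_bits <- as.integer(total_bits); integer_bits <- as.integer(integer_bits)
  if (integer_bits < 1L || integer_bits > total_bits)
    .pqn_stop("need 1 <= integer_bits <= total_bits", "pqn_config_error")
  if (total_bits > 40L || total_bits - integer_bits > 32L)
    .pqn_stop("formats wider than 40 bits (32 fraction bits) not supported",
              "pqn_config_error")
  structure(list(total_bits = total_bits, integer_bits = integer_bits,
                 fraction_bits = total_bits - integer_bits),
            class = "qformat")
}

#' @export
print.qformat <- function(x, ...) {
  cat(sprintf("q%d.%d: %d fraction bits, range [%g, %g], resolution %g\n",
              x$total_bits, x$integer_bits, x$fraction_bits,
              -2^(x$integer_bits - 1),
              2^(x$integer_bits - 1) - 2^-x$fraction_bits,
              2^-x$fraction_bits))
  invisible(x)
}

.fx_raw_min <- function(fmt) -2^(fmt$total_bits - 1)
.fx_raw_max <- function(fmt) 2^(fmt$total_bits - 1) - 1

#' Construct a fixed-point value from raw integers
#'
#' @param raw Signed integer raw value(s) (vectorised).
#' @param fmt A [qformat()].
#' @return An object of class `fixed_value`.
#' @export
fixed_value <- function(raw, fmt) {
  stopifnot(inherits(fmt, "qformat"))
  raw <- as.numeric(raw)
  if (any(raw != trunc(raw)))
    .pqn_stop("raw values must be integers", "pqn_domain_error")
  if (any(raw < .fx_raw_min(fmt) | raw > .fx_raw_max(fmt)))
    .pqn_stop("raw value outside the format's range", "pqn_overflow_error")
  structure(list(raw = raw, fmt = fmt), class = "fixed_value")
}

#' @export
print.fixed_value <- function(x, ...) {
  cat(sprintf("fixed q%d.%d:", x$fmt$total_bits, x$fmt$integer_bits),
      format(as.numeric(x), digits = 12), "\n")
  invisible(x)
}

#' @export
as.double.fixed_value <- function(x, ...) x$raw * 2^-x$fmt$fraction_bits

#' @export
length.fixed_value <- function(x) length(x$raw)

# Apply the overflow policy to raw values that may lie outside the format.
.fx_overflow <- function(raw, fmt, policy = c("wrap", "saturate", "error")) {
  policy <- match.arg(policy)
  lo <- .fx_raw_min(fmt); hi <- .fx_raw_max(fmt)
  out <- raw < lo | raw > hi
  if (any(out)) {
    .pqn_fx_state$overflows <- .pqn_fx_state$overflows + sum(out)
    if (policy == "error")
      .pqn_stop("fixed-point overflow", "pqn_overflow_error")
    if (policy == "saturate") {
      raw <- pmin(pmax(raw, lo), hi)
    } else {
      span <- 2^fmt$total_bits
      raw <- ((raw - lo) %% span) + lo
    }
  }
  raw
}

#' Fixed-point overflow counter
#'
#' Overflows under the `wrap` and `saturate` policies are silent (as in the
#' hardware) but counted; this reports and optionally resets the counter.
#'
#' @param reset If `TRUE`, reset the counter to zero after reading.
#' @return The number of overflowed operations since the last reset.
#' @export
fx_overflow_count <- function(reset = FALSE) {
  n <- .pqn_fx_state$overflows
  if (reset) .pqn_fx_state$overflows <- 0L
  n
}

#' Quantize real numbers into a Q-format
#'
#' @param x Finite numeric vector.
#' @param fmt A [qformat()].
#' @param rounding `"nearest"` (round half to even, the default) or
#'   `"truncate"` (floor toward minus infinity of `x * 2^fraction_bits`).
#' @param overflow Out-of-range policy: `"wrap"` (two's-complement
#'   wrap-around, the hardware default), `"saturate"`, or `"error"`.
#' @return A `fixed_value`.
#' @export
#' @examples
#' quantize(0.037109375, qformat(18, 8))$raw  # 38, i.e. 38/1024 exactly
quantize <- function(x, fmt, rounding = c("nearest", "truncate"),
                     overflow = c("wrap", "saturate", "error")) {
  stopifnot(inherits(fmt, "qformat"), all(is.finite(x)))
  rounding <- match.arg(rounding)
  scaled <- x * 2^fmt$fraction_bits
  raw <- if (rounding == "truncate") floor(scaled) else round(scaled)
  fixed_value(.fx_overflow(raw, fmt, overflow), fmt)
}

#' Convert a fixed-point value back to real numbers
#'
#' Exact on every representable value, so `dequantize(quantize(x))` is the
#' identity whenever `x` is representable in the format.
#'
#' @param x A `fixed_value`.
#' @return Numeric vector.
#' @export
dequantize <- function(x) {
  stopifnot(inherits(x, "fixed_value"))
  as.numeric(x)
}

# Exact floor((a * b) / 2^f) for integer-valued doubles |a|,|b| < 2^60,
# f <= 32, truncating toward -Inf.  Operands are split into base-2^20 limbs
# so every intermediate stays below 2^53.  Vectorised over a and b.
.mul_shift_floor <- function(a, b, f) {
  s <- sign(a) * sign(b)
  A <- abs(a); B <- abs(b)
  base <- 2^20; D <- 2^f
  a0 <- A %% base; t <- A %/% base; a1 <- t %% base; a2 <- t %/% base
  b0 <- B %% base; t <- B %/% base; b1 <- t %% base; b2 <- t %/% base
  # convolution of limbs, each term < 2^40, at most 3 terms per column
  p0 <- a0 * b0
  p1 <- a0 * b1 + a1 * b0
  p2 <- a0 * b2 + a1 * b1 + a2 * b0
  p3 <- a1 * b2 + a2 * b1
  p4 <- a2 * b2
  # carry-normalise into base-2^20 limbs c0..c5 (c5 collects the residue)
  c0 <- p0 %% base; p1 <- p1 + p0 %/% base
  c1 <- p1 %% base; p2 <- p2 + p1 %/% base
  c2 <- p2 %% base; p3 <- p3 + p2 %/% base
  c3 <- p3 %% base; p4 <- p4 + p3 %/% base
  c4 <- p4 %% base; c5 <- p4 %/% base
  # long division of (c5..c0)_base by D = 2^f, top limb first
  q <- 0; r <- 0
  for (limb in list(c5, c4, c3, c2, c1, c0)) {
    acc <- r * base + limb          # r < 2^32, base 2^20 -> acc < 2^52
    q <- q * base + acc %/% D
    r <- acc %% D
  }
  if (any(q > 2^52))
    .pqn_stop("fixed-point product quotient exceeds exact double range",
              "pqn_overflow_error")
  neg <- s < 0
  q[neg] <- -q[neg] - (r[neg] > 0)
  q
}

#' Fixed-point multiplication
#'
#' Emulates the hardware multiplier: the full-precision integer product of
#' the raw values is arithmetically right-shifted by the fraction-bit count
#' (truncation toward minus infinity), then the overflow policy is applied.
#'
#' @param a,b `fixed_value`s in the same format (recycled elementwise).
#' @param overflow Out-of-range policy, as in [quantize()].
#' @return A `fixed_value` in the common format.
#' @export
#' @examples
#' f <- qformat(18, 8)
#' as.numeric(fx_mul(quantize(-0.5, f), quantize(2^-9, f)))  # -2^-10, not 0
fx_mul <- function(a, b, overflow = c("wrap", "saturate", "error")) {
  stopifnot(inherits(a, "fixed_value"), inherits(b, "fixed_value"))
  if (!identical(unclass(a$fmt), unclass(b$fmt)))
    .pqn_stop("fx_mul operands must share a format", "pqn_config_error")
  raw <- .mul_shift_floor(a$raw, b$raw, a$fmt$fraction_bits)
  fixed_value(.fx_overflow(raw, a$fmt, match.arg(overflow)), a$fmt)
}

#' Fixed-point addition
#'
#' @inheritParams fx_mul
#' @return A `fixed_value` in the common format.
#' @export
fx_add <- function(a, b, overflow = c("wrap", "saturate", "error")) {
  stopifnot(inherits(a, "fixed_value"), inherits(b, "fixed_value"))
  if (!identical(unclass(a$fmt), unclass(b$fmt)))
    .pqn_stop("fx_add operands must share a format", "pqn_config_error")
  fixed_value(.fx_overflow(a$raw + b$raw, a$fmt, match.arg(overflow)), a$fmt)
}

# Arithmetic right shift of integer-valued doubles (floor division by 2^p);
# negative p shifts left (exact).
.ashift <- function(raw, p) {
  if (p >= 0) raw %/% 2^p else raw * 2^(-p)
}

#' Multiply a fixed-point value by a constant via its shift-add plan
#'
#' Reproduces the FPGA's shifter/adder network: each set bit of the constant
#' contributes one arithmetic right shift of `x`'s raw value, and the shifted
#' copies are summed.  Each shift truncates independently, so the result may
#' differ from [fx_mul()] with the quantized constant by up to one raw unit
#' per set bit; the two agree exactly whenever no shift discards set bits.
#'
#' @param x A `fixed_value`.
#' @param plan A [decompose_coefficient()] plan.
#' @param overflow Out-of-range policy, as in [quantize()].
#' @return A `fixed_value` in `x`'s format.
#' @export
shift_add_mul <- function(x, plan, overflow = c("wrap", "saturate", "error")) {
  stopifnot(inherits(x, "fixed_value"), inherits(plan, "shift_add_plan"))
  raw <- numeric(length(x$raw))
  for (p in plan$shifts) raw <- raw + .ashift(x$raw, p)
  raw <- plan$sign * raw
  fixed_value(.fx_overflow(raw, x$fmt, match.arg(overflow)), x$fmt)
}
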