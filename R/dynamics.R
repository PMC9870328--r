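#' @title PQN model dynamics
#'
#' @description
#' Right-hand sides, Euler integration and equilibrium location for the
#' PQN model family.  The state of one neuron is a named numeric vector
#' `c(v, n)` / `c(v, n, q)` / `c(v, n, q, u)` matching the variant.  The
#' float backend integrates in double precision; the fixed backend emulates
#' the FPGA pipeline: coefficients are folded per state-variable update
#' (e.g. the contribution of `v^2` to `v_next`), quantized once into the
#' active Q-format, and every product is a truncating fixed-point multiply.
#' Updates are synchronous: all derivatives are evaluated from the time-t
#' state before any assignment, and in the extended four-variable model the
#' `eta(u)` switch reads the time-t value of `u`.
#'
#' @name dynamics
NULL

.state_names <- function(variant) {
  switch(variant,
    two_var = c("v", "n"),
    three_var = c("v", "n", "q"),
    four_var = c("v", "n", "q", "u"),
    four_var_ext = c("v", "n", "q", "u"))
}

.check_state <- function(s, p) {
  want <- .state_names(p$variant)
  if (!is.numeric(s) || length(s) != length(want) ||
      !identical(names(s), want))
    .pqn_stop(paste0("state must be a named numeric vector (",
                     paste(want, collapse = ", "), ") for variant ",
                     p$variant), "pqn_config_error")
  invisible(s)
}

#' Evaluate a piecewise-quadratic branch function
#'
#' The nullcline building block of the PQN model:
#' `a_n (v - b_n)^2 + c_n` for `v < r`, `a_p (v - b_p)^2 + c_p` for
#' `v >= r` (the right branch applies at the junction itself).
#'
#' @param v Membrane-potential values (vectorised).
#' @param branch Coefficients `c(a_n, b_n, c_n, a_p, b_p, c_p)`.
#' @param r Junction position (0 for `f`, `r_g` for `g`, `r_h` for `h`).
#' @return Numeric vector of function values.
#' @export
eval_piecewise_quadratic <- function(v, branch, r) {
  stopifnot(length(branch) == 6L, all(is.finite(branch)))
  neg <- branch[1] * (v - branch[2])^2 + branch[3]
  pos <- branch[4] * (v - branch[5])^2 + branch[6]
  ifelse(v < r, neg, pos)
}

.f_branch <- function(p) c(p$a_fn, p$b_fn, p$c_fn, p$a_fp, p$b_fp, p$c_fp)
.g_branch <- function(p) c(p$a_gn, p$b_gn, p$c_gn, p$a_gp, p$b_gp, p$c_gp)
.h_branch <- function(p) c(p$a_hn, p$b_hn, p$c_hn, p$a_hp, p$b_hp, p$c_hp)

.f_of_v <- function(v, p) eval_piecewise_quadratic(v, .f_branch(p), 0)
.g_of_v <- function(v, p) eval_piecewise_quadratic(v, .g_branch(p), p$r_g)
.h_of_v <- function(v, p) eval_piecewise_quadratic(v, .h_branch(p), p$r_h)

#' Evaluate the eta(u) time-constant switch
#'
#' In the extended four-variable model the rate of the recovery variable
#' `n` is `eta(u)/tau` with `eta(u) = eta0` for `u < r_u` and `eta1` for
#' `u >= r_u`.  The step is genuinely discontinuous, so the branch taken at
#' the threshold matters: the `>=` branch is normative.
#'
#' @param u Slow-variable values (vectorised).
#' @param p A completed `pqn_params` of variant `four_var_ext`.
#' @return Numeric vector of eta values.
#' @export
eval_eta <- function(u, p) {
  stopifnot(inherits(p, "pqn_params"))
  if (!identical(p$variant, "four_var_ext"))
    .pqn_stop("eval_eta applies only to the extended four-variable variant",
              "pqn_usage_error")
  ifelse(u < p$r_u, p$eta0, p$eta1)
}

#' State derivatives of the PQN model
#'
#' Evaluates the right-hand side of the model ODEs from the current state
#' only (synchronous semantics).  For the two-variable variant
#' `dv/dt = (phi/tau) (f(v) - n + I0 + k I_stim)` and
#' `dn/dt = (1/tau) (g(v) - n)`; the three-variable variant subtracts the
#' slow variable `q` from `dv/dt` and adds
#' `dq/dt = (eps_q/tau) (h(v) - q)`; the four-variable variant further adds
#' `+u` to `dv/dt` with `du/dt = (eps_u/tau) (v + v0 - alpha_u u)`; the
#' extended four-variable variant omits `u` from `dv/dt` and instead uses
#' `dn/dt = (eta(u)/tau) (g(v) - n)`.
#'
#' @param s Named state vector matching the variant.
#' @param I_stim Stimulus value (scalar, dimensionless).
#' @param p A completed `pqn_params`.
#' @return Named vector of time derivatives (per second).
#' @export
derivatives <- function(s, I_stim, p) {
  stopifnot(inherits(p, "pqn_params"))
  .check_state(s, p)
  v <- s[["v"]]; n <- s[["n"]]
  fv <- .f_of_v(v, p); gv <- .g_of_v(v, p)
  drive <- I_stim * p$k + p$I0
  switch(p$variant,
    two_var = {
      c(v = (p$phi / p$tau) * (fv - n + drive),
        n = (1 / p$tau) * (gv - n))
    },
    three_var = {
      q <- s[["q"]]
      c(v = (p$phi / p$tau) * (fv - n - q + drive),
        n = (1 / p$tau) * (gv - n),
        q = (p$eps_q / p$tau) * (.h_of_v(v, p) - q))
    },
    four_var = {
      q <- s[["q"]]; u <- s[["u"]]
      c(v = (p$phi / p$tau) * (fv - n - q + u + drive),
        n = (1 / p$tau) * (gv - n),
        q = (p$eps_q / p$tau) * (.h_of_v(v, p) - q),
        u = (p$eps_u / p$tau) * (v + p$v0 - p$alpha_u * u))
    },
    four_var_ext = {
      q <- s[["q"]]; u <- s[["u"]]
      c(v = (p$phi / p$tau) * (fv - n - q + drive),
        n = (eval_eta(u, p) / p$tau) * (gv - n),
        q = (p$eps_q / p$tau) * (.h_of_v(v, p) - q),
        u = (p$eps_u / p$tau) * (v + p$v0 - p$alpha_u * u))
    })
}

#' PLS-framework core functions
#'
#' The polynomial/piecewise-linear/step framework expresses qualitative
#' neuron models through three core functions:
#' `P1(x, x0) = x0 - x`, `L1(x, x0, x1, x2) = x1 + x2 (x - x0)` and the
#' step `S1(x, x0, x1, x2) = x1` for `x < x0`, `x2` for `x >= x0`.
#'
#' @param kind One of `"P1"`, `"L1"`, `"S1"`.
#' @param ... Arguments of the core function, in the order above.
#' @return Numeric scalar (vectorised over the first argument).
#' @export
pls_core <- function(kind, ...) {
  args <- list(...)
  switch(match.arg(kind, c("P1", "L1", "S1")),
    P1 = {
      stopifnot(length(args) == 2L)
      args[[2]] - args[[1]]
    },
    L1 = {
      stopifnot(length(args) == 4L)
      args[[3]] + args[[4]] * (args[[1]] - args[[2]])
    },
    S1 = {
      stopifnot(length(args) == 4L)
      ifelse(args[[1]] < args[[2]], args[[3]], args[[4]])
    })
}

#' PLS-framework assembly of the PQN right-hand sides
#'
#' Rebuilds [derivatives()] purely from [pls_core()] calls, using the
#' reformulated time scales (the `v` equation carries `tau * theta` with
#' `theta = 1/phi`; the `u` equation carries `tau / (eps_u alpha_u)` and a
#' piecewise-linear nullcline `L1(v, 0, v0/alpha_u, 1/alpha_u)`).  The
#' reformulation omits the bias `I0`, so agreement with [derivatives()]
#' requires `I0 = 0`; this path exists as an independent formulation for
#' equivalence testing.
#'
#' @inheritParams derivatives
#' @return Named vector of time derivatives.
#' @export
derivatives_pls <- function(s, I_stim, p) {
  stopifnot(inherits(p, "pqn_params"))
  .check_state(s, p)
  v <- s[["v"]]; n <- s[["n"]]
  theta <- 1 / p$phi
  S1 <- function(...) pls_core("S1", ...)
  P1 <- function(...) pls_core("P1", ...)
  L1 <- function(...) pls_core("L1", ...)
  fv <- S1(v, 0,
           p$a_fn * P1(v, p$b_fn)^2 + p$c_fn,
           p$a_fp * P1(v, p$b_fp)^2 + p$c_fp)
  gv <- S1(v, p$r_g,
           p$a_gn * P1(v, p$b_gn)^2 + p$c_gn,
           p$a_gp * P1(v, p$b_gp)^2 + p$c_gp)
  hv <- if (p$variant != "two_var")
    S1(v, p$r_h,
       p$a_hn * P1(v, p$b_hn)^2 + p$c_hn,
       p$a_hp * P1(v, p$b_hp)^2 + p$c_hp)
  switch(p$variant,
    two_var = c(
      v = (fv - n + p$k * I_stim) / (p$tau * theta),
      n = (gv - n) / p$tau),
    three_var = c(
      v = (fv - n - s[["q"]] + p$k * I_stim) / (p$tau * theta),
      n = (gv - n) / p$tau,
      q = (hv - s[["q"]]) / (p$tau / p$eps_q)),
    four_var = c(
      v = (fv - n - s[["q"]] + s[["u"]] + p$k * I_stim) / (p$tau * theta),
      n = (gv - n) / p$tau,
      q = (hv - s[["q"]]) / (p$tau / p$eps_q),
      u = (L1(v, 0, p$v0 / p$alpha_u, 1 / p$alpha_u) - s[["u"]]) /
        (p$tau / (p$eps_u * p$alpha_u))),
    four_var_ext = c(
      v = (fv - n - s[["q"]] + p$k * I_stim) / (p$tau * theta),
      n = (gv - n) / S1(s[["u"]], p$r_u, p$tau / p$eta0, p$tau / p$eta1),
      q = (hv - s[["q"]]) / (p$tau / p$eps_q),
      u = (L1(v, 0, p$v0 / p$alpha_u, 1 / p$alpha_u) - s[["u"]]) /
        (p$tau / (p$eps_u * p$alpha_u))))
}

# ---------------------------------------------------------------------------
# fixed-point update engine
#
# Folds the Euler update of each state variable into per-signal constants
# (the multiplications the hardware performs with shifters/adders), quantizes
# them once and returns closures that advance raw integer states.  With
# alpha = dt*phi/tau, beta = dt/tau, gamma = dt*eps_q/tau, delta =
# dt*eps_u/tau, and writing a,b,c for the branch picked by the comparator:
#   v' = v + alpha*a*v^2 + (-2 alpha a b) v - alpha n [- alpha q] [+ alpha u]
#          + alpha k I + alpha (a b^2 + c + I0)
# and analogously for n, q (with their own branches) and the linear u update.
.fx_engine <- function(p, dt, qfmt, overflow = "wrap") {
  stopifnot(inherits(qfmt, "qformat"))
  f <- qfmt$fraction_bits
  Q <- function(x) quantize(x, qfmt, rounding = "nearest",
                            overflow = "error")$raw
  alpha <- dt * p$phi / p$tau
  beta <- dt / p$tau
  gamma <- if (p$variant != "two_var") dt * p$eps_q / p$tau
  delta <- if (p$variant %in% c("four_var", "four_var_ext"))
    dt * p$eps_u / p$tau

  quad_coefs <- function(rate, a, b, c, extra = 0) list(
    vv = Q(rate * a),
    v = Q(-2 * rate * a * b),
    c = Q(rate * (a * b^2 + c + extra)))
  co <- list(
    fS = quad_coefs(alpha, p$a_fn, p$b_fn, p$c_fn, p$I0),
    fL = quad_coefs(alpha, p$a_fp, p$b_fp, p$c_fp, p$I0),
    v_one = Q(1), v_n = Q(-alpha), v_I = Q(alpha * p$k),
    gS = quad_coefs(beta, p$a_gn, p$b_gn, p$c_gn),
    gL = quad_coefs(beta, p$a_gp, p$b_gp, p$c_gp),
    n_n = Q(1 - beta),
    r_g = Q(p$r_g))
  if (p$variant != "two_var") {
    co$hS <- quad_coefs(gamma, p$a_hn, p$b_hn, p$c_hn)
    co$hL <- quad_coefs(gamma, p$a_hp, p$b_hp, p$c_hp)
    co$q_q <- Q(1 - gamma)
    co$v_q <- Q(-alpha)
    co$r_h <- Q(p$r_h)
  }
  if (p$variant %in% c("four_var", "four_var_ext")) {
    co$u_v <- Q(delta)
    co$u_u <- Q(1 - delta * p$alpha_u)
    co$u_c <- Q(delta * p$v0)
    if (p$variant == "four_var") co$v_u <- Q(alpha)
  }
  if (p$variant == "four_var_ext") {
    # eta switches the whole n update: two pre-folded coefficient sets
    beta0 <- dt * p$eta0 / p$tau; beta1 <- dt * p$eta1 / p$tau
    co$gS0 <- quad_coefs(beta0, p$a_gn, p$b_gn, p$c_gn)
    co$gL0 <- quad_coefs(beta0, p$a_gp, p$b_gp, p$c_gp)
    co$gS1 <- quad_coefs(beta1, p$a_gn, p$b_gn, p$c_gn)
    co$gL1 <- quad_coefs(beta1, p$a_gp, p$b_gp, p$c_gp)
    co$n_n0 <- Q(1 - beta0); co$n_n1 <- Q(1 - beta1)
    co$r_u <- Q(p$r_u)
  }

  mul <- function(a, b) .mul_shift_floor(a, b, f)
  wrap <- function(raw) .fx_overflow(raw, qfmt, overflow)
  vnames <- .state_names(p$variant)

  step <- function(raw, I_raw) {
    v <- raw[[1]]; n <- raw[[2]]
    vv <- wrap(mul(v, v))
    fb <- if (v < 0) co$fS else co$fL                  # f junction is v = 0
    vnew <- v + mul(fb$vv, vv) + mul(fb$v, v) + mul(co$v_n, n) +
      mul(co$v_I, I_raw) + fb$c
    if (p$variant == "two_var") {
      gb <- if (v < co$r_g) co$gS else co$gL
      nnew <- mul(gb$vv, vv) + mul(gb$v, v) + mul(co$n_n, n) + gb$c
      return(c(wrap(vnew), wrap(nnew)))
    }
    q <- raw[[3]]
    vnew <- vnew + mul(co$v_q, q)
    hb <- if (v < co$r_h) co$hS else co$hL
    qnew <- mul(hb$vv, vv) + mul(hb$v, v) + mul(co$q_q, q) + hb$c
    if (p$variant == "three_var") {
      gb <- if (v < co$r_g) co$gS else co$gL
      nnew <- mul(gb$vv, vv) + mul(gb$v, v) + mul(co$n_n, n) + gb$c
      return(c(wrap(vnew), wrap(nnew), wrap(qnew)))
    }
    u <- raw[[4]]
    unew <- mul(co$u_v, v) + mul(co$u_u, u) + co$u_c
    if (p$variant == "four_var") {
      vnew <- vnew + mul(co$v_u, u)
      gb <- if (v < co$r_g) co$gS else co$gL
      nnew <- mul(gb$vv, vv) + mul(gb$v, v) + mul(co$n_n, n) + gb$c
    } else {
      # eta reads the time-t u (fourth pipeline stage)
      slow <- u < co$r_u
      gb <- if (slow) { if (v < co$r_g) co$gS0 else co$gL0 } else {
        if (v < co$r_g) co$gS1 else co$gL1 }
      nn <- if (slow) co$n_n0 else co$n_n1
      nnew <- mul(gb$vv, vv) + mul(gb$v, v) + mul(nn, n) + gb$c
    }
    c(wrap(vnew), wrap(nnew), wrap(qnew), wrap(unew))
  }
  list(step = step, fmt = qfmt, names = vnames, quantize_raw = Q)
}

#' Advance the state by one Euler step
#'
#' `s' = s + dt * derivatives(s, I_stim, p)`.  Under the fixed backend
#' every multiply runs in the Q-format with truncation and the folded
#' update coefficients are quantized on entry (for repeated stepping use
#' [pqn_simulate()], which quantizes them once).
#'
#' @inheritParams derivatives
#' @param dt Step size in seconds (defaults to the parameter set's `dt`).
#' @param backend `"float"` or `"fixed"`.
#' @param qfmt A [qformat()]; required for the fixed backend.
#' @param overflow Fixed-backend overflow policy (see [quantize()]).
#' @return The next state, as a named numeric vector.
#' @export
euler_step <- function(s, I_stim, p, dt = p$dt,
                       backend = c("float", "fixed"), qfmt = NULL,
                       overflow = "wrap") {
  backend <- match.arg(backend)
  stopifnot(dt >= 0)
  if (backend == "float")
    return(s + dt * derivatives(s, I_stim, p))
  if (is.null(qfmt))
    .pqn_stop("fixed backend requires a qfmt", "pqn_config_error")
  eng <- .fx_engine(p, dt, qfmt, overflow)
  raw <- vapply(s, function(x) quantize(x, qfmt)$raw, numeric(1))
  out <- eng$step(raw, quantize(I_stim, qfmt)$raw)
  stats::setNames(out * 2^-qfmt$fraction_bits, eng$names)
}

#' Locate a resting equilibrium
#'
#' Solves the nullcline intersection for the given constant stimulus by
#' scanning the bracket (1000 intervals) for a sign change of the `v`
#' residual and refining with [stats::uniroot()].  The slow variables are
#' substituted at their own equilibria (`n = g(v)`, `q = h(v)`,
#' `u = (v + v0)/alpha_u`); the `eta` switch does not affect equilibrium
#' values.  The LEFTMOST root in the bracket is returned.
#'
#' @inheritParams derivatives
#' @param I_stim Constant stimulus value.
#' @param bracket Finite `v` interval to search, `c(lo, hi)`.
#' @return A named state vector, or `NULL` when no sign change is found.
#' @export
find_equilibrium <- function(p, I_stim = 0, bracket = c(-8, 8)) {
  stopifnot(inherits(p, "pqn_params"),
            length(bracket) == 2L, all(is.finite(bracket)),
            bracket[1] < bracket[2])
  resid <- function(v) {
    r <- .f_of_v(v, p) - .g_of_v(v, p) + p$I0 + p$k * I_stim
    if (p$variant != "two_var") r <- r - .h_of_v(v, p)
    if (p$variant == "four_var") r <- r + (v + p$v0) / p$alpha_u
    r
  }
  vs <- seq(bracket[1], bracket[2], length.out = 1001L)
  rs <- resid(vs)
  hit <- which(rs == 0)
  if (length(hit)) {
    v_star <- vs[hit[1]]
  } else {
    sc <- which(rs[-length(rs)] * rs[-1] < 0)
    if (!length(sc)) return(NULL)
    v_star <- stats::uniroot(resid, c(vs[sc[1]], vs[sc[1] + 1L]),
                             tol = 1e-14)$root
  }
  s <- c(v = v_star, n = .g_of_v(v_star, p))
  if (p$variant != "two_var") s <- c(s, q = .h_of_v(v_star, p))
  if (p$variant %in% c("four_var", "four_var_ext"))
    s <- c(s, u = (v_star + p$v0) / p$alpha_u)
  s
}

#' Simulate a PQN neuron
#'
#' Forward-Euler integration on the uniform grid `t_j = j dt`,
#' `j = 0..round(t_max/dt)`.  The initial state defaults to the resting
#' equilibrium at zero stimulus when one is found in `[-8, 8]`, else the
#' zero state (recorded in the trace metadata).  Simulation is fully
#' deterministic given identical inputs.
#'
#' @inheritParams euler_step
#' @param stim A [stimulus_program()].
#' @param t_max Duration in seconds (`>= dt`).
#' @param init Optional initial state (named vector for the variant).
#' @return A `pqn_trace`: a data frame with columns `time`, the state
#'   variables of the variant, and `I_stim`, plus attributes `mode`,
#'   `variant`, `backend`, `dt`, `qfmt` and `init_kind`.
#' @export
#' @examples
#' p <- load_mode_params("toy2var_osc")
#' tr <- pqn_simulate(p, stim_const(0.6), t_max = 0.2)
#' range(tr$v)
pqn_simulate <- function(p, stim, t_max, init = NULL,
                         backend = c("float", "fixed"), qfmt = NULL,
                         dt = p$dt, overflow = "wrap") {
  stopifnot(inherits(p, "pqn_params"), inherits(stim, "stimulus_program"))
  backend <- match.arg(backend)
  if (t_max < dt)
    .pqn_stop("t_max must be at least one step dt", "pqn_config_error")
  n_steps <- round(t_max / dt)
  times <- (0:n_steps) * dt
  I <- stim_eval(stim, times)
  init_kind <- "user"
  if (is.null(init)) {
    init <- find_equilibrium(p, 0)
    init_kind <- "equilibrium"
    if (is.null(init)) {
      init <- stats::setNames(numeric(length(.state_names(p$variant))),
                              .state_names(p$variant))
      init_kind <- "zero"
    }
  }
  .check_state(init, p)
  nv <- length(init)
  out <- matrix(NA_real_, nrow = n_steps + 1L, ncol = nv)
  colnames(out) <- names(init)

  if (backend == "float") {
    out <- .simulate_float(p, init, I, dt, n_steps, out)
  } else {
    if (is.null(qfmt))
      .pqn_stop("fixed backend requires a qfmt", "pqn_config_error")
    eng <- .fx_engine(p, dt, qfmt, overflow)
    f <- qfmt$fraction_bits
    raw <- vapply(init, function(x) quantize(x, qfmt)$raw, numeric(1))
    I_raw <- quantize(I, qfmt)$raw
    out[1L, ] <- raw
    for (j in seq_len(n_steps)) {
      raw <- eng$step(raw, I_raw[j])
      out[j + 1L, ] <- raw
    }
    out <- out * 2^-f
  }

  tr <- data.frame(time = times, out, I_stim = I)
  attr(tr, "mode") <- p$mode
  attr(tr, "variant") <- p$variant
  attr(tr, "backend") <- backend
  attr(tr, "dt") <- dt
  attr(tr, "qfmt") <- if (!is.null(qfmt))
    sprintf("q%d.%d", qfmt$total_bits, qfmt$integer_bits) else NA_character_
  attr(tr, "init_kind") <- init_kind
  class(tr) <- c("pqn_trace", "data.frame")
  tr
}

# float backend: per-variant inlined loops (scalar arithmetic, no function
# calls in the hot path) with a divergence guard at |v| > 1e6.
.simulate_float <- function(p, init, I, dt, n_steps, out) {
  a_fn <- p$a_fn; b_fn <- p$b_fn; c_fn <- p$c_fn
  a_fp <- p$a_fp; b_fp <- p$b_fp; c_fp <- p$c_fp
  a_gn <- p$a_gn; b_gn <- p$b_gn; c_gn <- p$c_gn
  a_gp <- p$a_gp; b_gp <- p$b_gp; c_gp <- p$c_gp
  r_g <- p$r_g
  av <- dt * p$phi / p$tau; an <- dt / p$tau
  I0 <- p$I0; k <- p$k
  guard <- function(v, j) {
    if (!is.finite(v) || abs(v) > 1e6)
      stop(errorCondition(
        sprintf("simulation diverged at step %d (v = %g)", j, v),
        class = c("pqn_simulation_error", "pqn_error")))
  }
  v <- init[["v"]]; n <- init[["n"]]
  out[1L, ] <- init
  if (p$variant == "two_var") {
    for (j in seq_len(n_steps)) {
      fv <- if (v < 0) a_fn * (v - b_fn)^2 + c_fn else
        a_fp * (v - b_fp)^2 + c_fp
      gv <- if (v < r_g) a_gn * (v - b_gn)^2 + c_gn else
        a_gp * (v - b_gp)^2 + c_gp
      v1 <- v + av * (fv - n + I0 + k * I[j])
      n <- n + an * (gv - n)
      v <- v1
      guard(v, j)
      out[j + 1L, 1L] <- v; out[j + 1L, 2L] <- n
    }
    return(out)
  }
  a_hn <- p$a_hn; b_hn <- p$b_hn; c_hn <- p$c_hn
  a_hp <- p$a_hp; b_hp <- p$b_hp; c_hp <- p$c_hp
  r_h <- p$r_h
  aq <- dt * p$eps_q / p$tau
  q <- init[["q"]]
  if (p$variant == "three_var") {
    for (j in seq_len(n_steps)) {
      fv <- if (v < 0) a_fn * (v - b_fn)^2 + c_fn else
        a_fp * (v - b_fp)^2 + c_fp
      gv <- if (v < r_g) a_gn * (v - b_gn)^2 + c_gn else
        a_gp * (v - b_gp)^2 + c_gp
      hv <- if (v < r_h) a_hn * (v - b_hn)^2 + c_hn else
        a_hp * (v - b_hp)^2 + c_hp
      v1 <- v + av * (fv - n - q + I0 + k * I[j])
      n <- n + an * (gv - n)
      q <- q + aq * (hv - q)
      v <- v1
      guard(v, j)
      out[j + 1L, 1L] <- v; out[j + 1L, 2L] <- n; out[j + 1L, 3L] <- q
    }
    return(out)
  }
  au <- dt * p$eps_u / p$tau
  v0 <- p$v0; alpha_u <- p$alpha_u
  u <- init[["u"]]
  if (p$variant == "four_var") {
    for (j in seq_len(n_steps)) {
      fv <- if (v < 0) a_fn * (v - b_fn)^2 + c_fn else
        a_fp * (v - b_fp)^2 + c_fp
      gv <- if (v < r_g) a_gn * (v - b_gn)^2 + c_gn else
        a_gp * (v - b_gp)^2 + c_gp
      hv <- if (v < r_h) a_hn * (v - b_hn)^2 + c_hn else
        a_hp * (v - b_hp)^2 + c_hp
      v1 <- v + av * (fv - n - q + u + I0 + k * I[j])
      n <- n + an * (gv - n)
      q <- q + aq * (hv - q)
      u <- u + au * (v + v0 - alpha_u * u)
      v <- v1
      guard(v, j)
      out[j + 1L, ] <- c(v, n, q, u)
    }
    return(out)
  }
  eta0 <- p$eta0; eta1 <- p$eta1; r_u <- p$r_u
  an0 <- dt * eta0 / p$tau; an1 <- dt * eta1 / p$tau
  for (j in seq_len(n_steps)) {
    fv <- if (v < 0) a_fn * (v - b_fn)^2 + c_fn else
      a_fp * (v - b_fp)^2 + c_fp
    gv <- if (v < r_g) a_gn * (v - b_gn)^2 + c_gn else
      a_gp * (v - b_gp)^2 + c_gp
    hv <- if (v < r_h) a_hn * (v - b_hn)^2 + c_hn else
      a_hp * (v - b_hp)^2 + c_hp
    ann <- if (u < r_u) an0 else an1
    v1 <- v + av * (fv - n - q + I0 + k * I[j])
    n <- n + ann * (gv - n)
    q <- q + aq * (hv - q)
    u <- u + au * (v + v0 - alpha_u * u)
    v <- v1
    guard(v, j)
    out[j + 1L, ] <- c(v, n, q, u)
  }
  out
}

#' @export
print.pqn_trace <- function(x, ...) {
  cat(sprintf(
    "PQN trace: mode %s (%s), backend %s, dt %g s, %d samples, init %s\n",
    attr(x, "mode"), attr(x, "variant"), attr(x, "backend"),
    attr(x, "dt"), nrow(x), attr(x, "init_kind")))
  cat(sprintf("  v in [%.4g, %.4g]\n", min(x$v), max(x$v)))
  invisible(x)
}
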