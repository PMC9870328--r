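test_that("piecewise-quadratic evaluation takes the printed branch at the junction", {
  # vertex value on the left branch
  expect_equal(eval_piecewise_quadratic(-1, c(2, -1, 0.3, 1, 0, 0), 0), 0.3)
  # completed toy f: continuity at the junction, right branch applies at v >= r
  fb <- c(1, -1, 0, 2, -0.5, 0.5)
  expect_equal(eval_piecewise_quadratic(0, fb, 0), 1)
  expect_equal(eval_piecewise_quadratic(1, fb, 0), 2 * 1.5^2 + 0.5)  # 5.0
  expect_equal(eval_piecewise_quadratic(c(-1, 0, 1), fb, 0), c(0, 1, 5))
})

test_that("eta switch is right-continuous at its threshold and variant-guarded", {
  p <- load_mode_params("toy4ext")
  expect_equal(eval_eta(p$r_u - 1e-9, p), p$eta0)
  expect_equal(eval_eta(p$r_u, p), p$eta1)     # the >= branch is normative
  p2 <- p; p2$eta0 <- p2$eta1 <- 0.5
  expect_equal(eval_eta(c(-99, 0, 99), p2), rep(0.5, 3))
  expect_error(eval_eta(0, toy2()), class = "pqn_usage_error")
})

test_that("derivatives reproduce hand-computed right-hand sides", {
  p <- toy2()
  s <- c(v = -1, n = 0)
  expect_equal(derivatives(s, 0, p), c(v = 1, n = 2))       # f(-1)=1, g(-1)=2
  expect_equal(derivatives(s, 0.5, p), c(v = 1.5, n = 2))   # k scales dv only
  # equilibrium states are zeros of the field
  p2 <- toy2(I0 = 0.25)
  eq <- find_equilibrium(p2, 0, c(-2, 2))
  expect_equal(eq, c(v = -0.5, n = 0.5), tolerance = 1e-9)
  expect_lt(max(abs(derivatives(eq, 0, p2))), 1e-10)
  # variant/state mismatch is rejected
  expect_error(derivatives(c(v = 0, n = 0, q = 0), 0, p),
               class = "pqn_config_error")
})

test_that("the four-variable variants wire u into the stated equations only", {
  set.seed(11)
  p4 <- random_params("four_var")
  s <- random_state("four_var")
  d <- derivatives(s, 0.3, p4)
  fv <- eval_piecewise_quadratic(s[["v"]], c(p4$a_fn, p4$b_fn, p4$c_fn,
                                             p4$a_fp, p4$b_fp, p4$c_fp), 0)
  expect_equal(d[["v"]], (p4$phi / p4$tau) *
                 (fv - s[["n"]] - s[["q"]] + s[["u"]] + p4$I0 + p4$k * 0.3))
  expect_equal(d[["u"]], (p4$eps_u / p4$tau) *
                 (s[["v"]] + p4$v0 - p4$alpha_u * s[["u"]]))
  pe <- random_params("four_var_ext")
  se <- random_state("four_var_ext")
  de <- derivatives(se, 0.3, pe)
  fve <- eval_piecewise_quadratic(se[["v"]], c(pe$a_fn, pe$b_fn, pe$c_fn,
                                               pe$a_fp, pe$b_fp, pe$c_fp), 0)
  # no u term in dv/dt; eta(u) scales dn/dt
  expect_equal(de[["v"]], (pe$phi / pe$tau) *
                 (fve - se[["n"]] - se[["q"]] + pe$I0 + pe$k * 0.3))
  gve <- eval_piecewise_quadratic(se[["v"]], c(pe$a_gn, pe$b_gn, pe$c_gn,
                                               pe$a_gp, pe$b_gp, pe$c_gp), pe$r_g)
  expect_equal(de[["n"]],
               (eval_eta(se[["u"]], pe) / pe$tau) * (gve - se[["n"]]))
})

test_that("pls core functions match their definitions", {
  expect_equal(pls_core("P1", 3, 3), 0)
  expect_equal(pls_core("P1", 1, 4), 3)
  expect_equal(pls_core("L1", 2, 0, 1, 0.5), 2)
  expect_equal(pls_core("S1", 1, 2, "lo", "hi"), "lo")
  expect_equal(pls_core("S1", 2, 2, 10, 20), 20)   # x >= x0 takes the second branch
})

test_that("PLS-framework assembly equals the direct right-hand sides (I0 = 0)", {
  set.seed(202)
  for (variant in c("two_var", "three_var", "four_var", "four_var_ext")) {
    for (rep in 1:25) {
      p <- random_params(variant, I0 = 0)
      s <- random_state(variant)
      I <- stats::runif(1, -1, 1)
      expect_equal(derivatives_pls(s, I, p), derivatives(s, I, p),
                   tolerance = 1e-12)
    }
  }
})

test_that("euler_step performs one synchronous explicit update", {
  p <- toy2()
  s <- c(v = -1, n = 0)
  expect_equal(euler_step(s, 0, p, dt = 0.1), c(v = -0.9, n = 0.2))
  expect_equal(euler_step(s, 0, p, dt = 0), s)
  # synchronous semantics: both components use the time-t state
  s2 <- euler_step(s, 0, p, dt = 0.1)
  expect_equal(s2[["n"]], 0 + 0.1 * 2)   # uses v = -1, not v = -0.9
})

test_that("simulation grid, default initialisation and determinism behave as specified", {
  p <- toy2()
  tr <- pqn_simulate(p, stim_const(0), t_max = 1, dt = 1e-4,
                     init = c(v = 0.01, n = 0))
  expect_identical(nrow(tr), 10001L)
  expect_equal(tr$time[2] - tr$time[1], 1e-4)
  expect_equal(tr$time[1], 0)

  # default init: resting equilibrium is a fixed point of the stepper
  p2 <- toy2(I0 = 0.25)
  tr2 <- pqn_simulate(p2, stim_const(0), t_max = 0.01)
  expect_identical(attr(tr2, "init_kind"), "equilibrium")
  expect_equal(max(abs(tr2$v - tr2$v[1])), 0)
  expect_equal(max(abs(tr2$n - tr2$n[1])), 0)

  # byte-identical repetition
  po <- load_mode_params("toy2var_osc")
  a <- pqn_simulate(po, stim_const(0.4), 0.05)
  b <- pqn_simulate(po, stim_const(0.4), 0.05)
  expect_identical(a, b)
})

test_that("float-backend divergence is reported with the step index", {
  p <- toy2()
  expect_error(pqn_simulate(p, stim_const(0), 1, init = c(v = 2, n = 0)),
               "step", class = "pqn_simulation_error")
})

test_that("find_equilibrium returns the leftmost root or nothing", {
  p <- toy2(I0 = 0.25)   # residual 0.25 - v^2: roots at +-0.5
  eq <- find_equilibrium(p, 0, c(-2, 2))
  expect_equal(eq[["v"]], -0.5, tolerance = 1e-9)
  expect_equal(eq[["n"]], 0.5, tolerance = 1e-9)
  expect_null(find_equilibrium(toy2(I0 = -1), 0, c(-2, 2)))
  # higher variants substitute the slow-variable equilibria
  p4 <- load_mode_params("toy4var")
  eq4 <- find_equilibrium(p4, 0)
  expect_lt(max(abs(derivatives(eq4, 0, p4))), 1e-9)
})

test_that("Euler integration converges at first order on the toy system", {
  p <- load_mode_params("toy2var")
  run <- function(dt) pqn_simulate(p, stim_const(0), 0.05,
                                   init = c(v = -1, n = 0), dt = dt)
  ref <- run(0.05 / 6400)
  err <- function(dt) {
    tr <- run(dt)
    idx <- round(seq(1, nrow(ref), length.out = nrow(tr)))
    max(abs(tr$v - ref$v[idx]))
  }
  e1 <- err(0.05 / 100); e2 <- err(0.05 / 200); e4 <- err(0.05 / 400)
  expect_gt(e1 / e2, 1.7); expect_lt(e1 / e2, 2.3)
  expect_gt(e2 / e4, 1.7); expect_lt(e2 / e4, 2.3)
})

test_that("an oscillatory mode settles onto a stable limit cycle", {
  p <- load_mode_params("toy2var_osc")
  tr <- pqn_simulate(p, stim_const(0.4), 1.0)
  st <- detect_spikes(tr)$times
  isis <- diff(st[st > 0.3])
  expect_gt(length(isis), 10)
  expect_lt(max(abs(isis - mean(isis))), 2 * 1e-4)
})
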