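# toy parameter builders used across the suite (built in code, no fixtures)

toy2 <- function(I0 = 0, ...) {
  pqn_params("toy", variant = "two_var",
             phi = 1, tau = 1, I0 = I0, k = 1,
             a_fn = 1, b_fn = 0, c_fn = 0, a_fp = 1,
             a_gn = 2, b_gn = 0, c_gn = 0, a_gp = 2, r_g = 0, ...)
}

# random valid free coefficients for a variant (finite, nonzero curvatures)
random_params <- function(variant, I0 = 0) {
  rc <- function() sample(c(-1, 1), 1) * stats::runif(1, 0.2, 3)
  args <- list(mode = "rand", variant = variant,
               phi = stats::runif(1, 0.5, 5), tau = stats::runif(1, 0.5, 2),
               I0 = I0, k = stats::runif(1, 0.2, 2),
               a_fn = rc(), b_fn = stats::runif(1, -2, 2),
               c_fn = stats::runif(1, -2, 2), a_fp = rc(),
               a_gn = rc(), b_gn = stats::runif(1, -2, 2),
               c_gn = stats::runif(1, -2, 2), a_gp = rc(),
               r_g = stats::runif(1, -1, 1))
  if (variant != "two_var")
    args <- c(args, list(eps_q = stats::runif(1, 0.01, 1),
                         a_hn = rc(), b_hn = stats::runif(1, -2, 2),
                         c_hn = stats::runif(1, -2, 2), a_hp = rc(),
                         r_h = stats::runif(1, -1, 1)))
  if (variant %in% c("four_var", "four_var_ext"))
    args <- c(args, list(eps_u = stats::runif(1, 0.01, 1),
                         v0 = stats::runif(1, -1, 1),
                         alpha_u = stats::runif(1, 0.5, 3)))
  if (variant == "four_var_ext")
    args <- c(args, list(eta0 = stats::runif(1, 0.2, 2),
                         eta1 = stats::runif(1, 0.2, 2),
                         r_u = stats::runif(1, -1, 1)))
  do.call(pqn_params, args)
}

random_state <- function(variant) {
  nm <- switch(variant, two_var = c("v", "n"), three_var = c("v", "n", "q"),
               c("v", "n", "q", "u"))
  stats::setNames(stats::runif(length(nm), -2, 2), nm)
}
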