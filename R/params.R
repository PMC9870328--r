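#' @title PQN model parameters
#'
#' @description
#' The Piecewise Quadratic Neuron (PQN) model family has four variants that
#' differ in the number of state variables:
#'
#' * `two_var` — membrane potential `v` and recovery variable `n`
#'   (Hodgkin Class II excitability),
#' * `three_var` — adds the slow variable `q` (regular spiking, fast
#'   spiking, elliptic bursting),
#' * `four_var` — adds the slower variable `u` feeding back into `dv/dt`
#'   (parabolic bursting),
#' * `four_var_ext` — `u` instead switches the time constant of `n` through
#'   the step function `eta(u)` (low-threshold spiking, intrinsic bursting).
#'
#' The nullclines of `v`, `n` and `q` are piecewise quadratic: two parabolic
#' branches joined at a junction (`v = 0` for `f`, `v = r_g` for `g`,
#' `v = r_h` for `h`).  Only the negative-branch coefficients and the
#' positive-branch curvatures are free parameters; the positive-branch vertex
#' and offset are derived so that each nullcline is continuous and has a
#' continuous first derivative at its junction (see
#' [complete_parameters()]).  All state variables and parameters are
#' dimensionless; time is carried in seconds.
#'
#' @section Canonical modes:
#' The neuronal classes map onto variants as follows: `CLASS2` is
#' `two_var`; `RS_EXC`, `RS_INH`, `FS` and `EB` are `three_var`; `PB` is
#' `four_var`; `LTS` and `IB` are `four_var_ext`.  The default integration
#' step is 1 ms for `PB` and 0.1 ms for every other mode.
#'
#' @name pqn_params
NULL

.pqn_variants <- c("two_var", "three_var", "four_var", "four_var_ext")

.pqn_mode_variant <- c(
  CLASS2 = "two_var",
  RS_EXC = "three_var", RS_INH = "three_var", FS = "three_var",
  EB = "three_var",
  PB = "four_var",
  LTS = "four_var_ext", IB = "four_var_ext"
)

# free (user-supplied) fields required per variant
.pqn_fields_common <- c("phi", "tau", "I0", "k",
                        "a_fn", "b_fn", "c_fn", "a_fp",
                        "a_gn", "b_gn", "c_gn", "a_gp", "r_g")
.pqn_fields_q <- c("eps_q", "a_hn", "b_hn", "c_hn", "a_hp", "r_h")
.pqn_fields_u <- c("eps_u", "v0", "alpha_u")
.pqn_fields_eta <- c("eta0", "eta1", "r_u")

.pqn_required_fields <- function(variant) {
  switch(variant,
    two_var      = .pqn_fields_common,
    three_var    = c(.pqn_fields_common, .pqn_fields_q),
    four_var     = c(.pqn_fields_common, .pqn_fields_q, .pqn_fields_u),
    four_var_ext = c(.pqn_fields_common, .pqn_fields_q, .pqn_fields_u,
                     .pqn_fields_eta),
    stop("unknown variant: ", variant)
  )
}

.pqn_derived_fields <- function(variant) {
  d <- c("b_fp", "c_fp", "b_gp", "c_gp")
  if (variant != "two_var") d <- c(d, "b_hp", "c_hp")
  d
}

.pqn_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "pqn_error")))
}

#' Construct a PQN parameter set
#'
#' Builds a `pqn_params` object from free coefficients, derives the
#' smoothness-constrained positive-branch coefficients and validates the
#' result.  Most users will instead call [load_mode_params()] for a bundled
#' mode.
#'
#' @param mode Mode label.  One of the canonical classes (`"CLASS2"`,
#'   `"RS_EXC"`, `"RS_INH"`, `"FS"`, `"LTS"`, `"IB"`, `"EB"`, `"PB"`) or any
#'   other label (e.g. a toy set name) together with an explicit `variant`.
#' @param variant Model variant, one of `"two_var"`, `"three_var"`,
#'   `"four_var"`, `"four_var_ext"`.  Inferred from `mode` when the mode is
#'   canonical; required otherwise.
#' @param ... Named free parameters for the variant (see [pqn_params]).
#' @param dt Integration step in seconds.  Defaults to `1e-3` for `PB` and
#'   `1e-4` otherwise.
#' @param complete If `TRUE` (default) derive the positive-branch
#'   coefficients via [complete_parameters()].
#'
#' @return An object of class `pqn_params`: a named list of parameters plus
#'   `mode`, `variant` and `dt`.
#' @export
#' @examples
#' p <- pqn_params("toy", variant = "two_var",
#'                 phi = 1, tau = 1, I0 = 0, k = 1,
#'                 a_fn = 1, b_fn = -1, c_fn = 0, a_fp = 2,
#'                 a_gn = 1, b_gn = 0, c_gn = 0, a_gp = 1, r_g = 0.7)
#' p$b_fp  # derived: a_fn * b_fn / a_fp = -0.5
pqn_params <- function(mode, variant = NULL, ..., dt = NULL, complete = TRUE) {
  mode <- as.character(mode)[1L]
  if (mode %in% names(.pqn_mode_variant)) {
    canon <- .pqn_mode_variant[[mode]]
    if (!is.null(variant) && !identical(variant, canon))
      .pqn_stop(sprintf("mode %s requires variant %s, got %s",
                        mode, canon, variant), "pqn_config_error")
    variant <- canon
  }
  if (is.null(variant))
    .pqn_stop("variant must be given for non-canonical mode names",
              "pqn_config_error")
  variant <- match.arg(variant, .pqn_variants)
  vals <- list(...)
  if (length(vals) && (is.null(names(vals)) || any(names(vals) == "")))
    .pqn_stop("all parameters must be named", "pqn_config_error")
  if (is.null(dt)) dt <- if (identical(mode, "PB")) 1e-3 else 1e-4
  p <- structure(
    c(list(mode = mode, variant = variant, dt = as.numeric(dt)), vals),
    class = "pqn_params"
  )
  if (complete) p <- complete_parameters(p)
  p
}

#' Derive the smoothness-constrained positive-branch coefficients
#'
#' Each piecewise-quadratic nullcline function is
#' `a_n (v - b_n)^2 + c_n` on the left of its junction and
#' `a_p (v - b_p)^2 + c_p` on the right.  Requiring continuity of the value
#' and of the first derivative at the junction `r` fixes the positive-branch
#' vertex and offset:
#'
#' \deqn{b_p = r - a_n (r - b_n) / a_p}
#' \deqn{c_p = a_n (r - b_n)^2 + c_n - a_p (r - b_p)^2}
#'
#' with `r = 0` for `f`, `r = r_g` for `g` and `r = r_h` for `h`.  The
#' derived fields are always recomputed from the free coefficients; values
#' present on input are overwritten (smoothness is a structural invariant,
#' not data).
#'
#' @param p A `pqn_params` object with the free coefficients set.
#' @return A completed `pqn_params` object (the input is not mutated).
#' @export
complete_parameters <- function(p) {
  stopifnot(inherits(p, "pqn_params"))
  req <- .pqn_required_fields(p$variant)
  missing <- req[!vapply(req, function(f)
    !is.null(p[[f]]) && is.finite(as.numeric(p[[f]])), logical(1))]
  if (length(missing))
    .pqn_stop(paste0("missing required parameter(s): ",
                     paste(missing, collapse = ", ")), "pqn_config_error")
  for (f in c("a_fp", "a_gp", if (p$variant != "two_var") "a_hp"))
    if (p[[f]] == 0)
      .pqn_stop(paste0("positive-branch curvature ", f, " must be nonzero"),
                "pqn_domain_error")

  smooth_join <- function(a_n, b_n, c_n, a_p, r) {
    b_p <- r - a_n * (r - b_n) / a_p
    c_p <- a_n * (r - b_n)^2 + c_n - a_p * (r - b_p)^2
    list(b = b_p, c = c_p)
  }
  fj <- smooth_join(p$a_fn, p$b_fn, p$c_fn, p$a_fp, 0)
  gj <- smooth_join(p$a_gn, p$b_gn, p$c_gn, p$a_gp, p$r_g)
  p$b_fp <- fj$b; p$c_fp <- fj$c
  p$b_gp <- gj$b; p$c_gp <- gj$c
  if (p$variant != "two_var") {
    hj <- smooth_join(p$a_hn, p$b_hn, p$c_hn, p$a_hp, p$r_h)
    p$b_hp <- hj$b; p$c_hp <- hj$c
  }
  p
}

#' Validate a PQN parameter set
#'
#' Checks the structural invariants of a parameter set and reports
#' violations as structured diagnostics rather than raising errors.
#'
#' @param p A `pqn_params` object.
#' @return A data frame with columns `field`, `rule` and `value`; zero rows
#'   when all invariants hold.
#' @export
validate_parameters <- function(p) {
  diag <- list()
  note <- function(field, rule, value = NA_real_) {
    diag[[length(diag) + 1L]] <<- data.frame(
      field = field, rule = rule, value = as.numeric(value)[1L],
      stringsAsFactors = FALSE)
  }
  if (!inherits(p, "pqn_params")) {
    note("(object)", "must be a pqn_params object")
    return(do.call(rbind, diag))
  }
  if (is.null(p$variant) || !p$variant %in% .pqn_variants) {
    note("variant", "must be a known variant")
    return(do.call(rbind, diag))
  }
  if (p$mode %in% names(.pqn_mode_variant) &&
      !identical(.pqn_mode_variant[[p$mode]], p$variant))
    note("variant", sprintf("mode %s requires variant %s", p$mode,
                            .pqn_mode_variant[[p$mode]]))
  req <- .pqn_required_fields(p$variant)
  for (f in req) {
    v <- p[[f]]
    if (is.null(v) || !is.numeric(v) || !is.finite(v)) {
      note(f, "required finite numeric field is missing")
    }
  }
  for (f in intersect(c("a_fn", "a_fp", "a_gn", "a_gp", "a_hn", "a_hp"),
                      c(req, "a_fp", "a_gp",
                        if (p$variant != "two_var") "a_hp"))) {
    v <- p[[f]]
    if (!is.null(v) && is.numeric(v) && is.finite(v) && v == 0)
      note(f, "curvature coefficient must be nonzero", v)
  }
  for (f in c("phi", "tau")) {
    v <- p[[f]]
    if (!is.null(v) && is.numeric(v) && is.finite(v) && v <= 0)
      note(f, "time-scale constant must be positive", v)
  }
  if (!is.null(p$dt) && (!is.numeric(p$dt) || !is.finite(p$dt) || p$dt <= 0))
    note("dt", "integration step must be positive", p$dt)
  # derived coefficients, when present, must match the completion
  der <- .pqn_derived_fields(p$variant)
  if (all(vapply(der, function(f) is.numeric(p[[f]]) && is.finite(p[[f]]),
                 logical(1))) &&
      !length(diag)) {
    pc <- complete_parameters(p)
    for (f in der) {
      if (abs(pc[[f]] - p[[f]]) > 1e-9 * max(1, abs(pc[[f]])))
        note(f, "derived coefficient inconsistent with smoothness completion",
             p[[f]])
    }
  }
  if (!length(diag))
    return(data.frame(field = character(), rule = character(),
                      value = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, diag)
}

#' @export
print.pqn_params <- function(x, ...) {
  cat(sprintf("PQN parameters: mode %s (%s), dt = %g s\n",
              x$mode, x$variant, x$dt))
  flds <- setdiff(names(x), c("mode", "variant", "dt"))
  vals <- vapply(flds, function(f) format(x[[f]], digits = 7), character(1))
  cat(paste0("  ", format(flds, width = 8), " = ", vals, collapse = "\n"),
      "\n")
  invisible(x)
}

#' Load a bundled or on-disk PQN parameter set
#'
#' @param source Either the name of a bundled mode (case-insensitive; see
#'   Details) or a path to a JSON parameter file.
#'
#' @details
#' Bundled sets live under `inst/extdata/modes/` as one JSON document per
#' mode, keys named after the model symbols (`a_fn`, `eps_q`, `alpha_u`,
#' ...).  Two families are shipped:
#'
#' * `toy2var`, `toy3var`, `toy4var`, `toy4ext` — small documented toy sets
#'   used by the test-suite; `toy2var_osc` is a toy oscillatory set.
#' * `CLASS2`, `RS_EXC`, `RS_INH`, `FS`, `LTS`, `IB`, `EB`, `PB` — synthetic
#'   qualitative parameter sets designed in-house so that each mode
#'   reproduces the defining dynamics of its neuronal class (graded Class II
#'   response, spike-frequency adaptation, initial/elliptic/parabolic
#'   bursting, ...).  They are labelled synthetic because they were not fit
#'   against an ionic-conductance target.
#'
#' Derived (positive-branch) coefficients are always recomputed on load and
#' the result is validated; a file whose derived fields disagree with the
#' completion is accepted but silently re-completed.
#'
#' @return A completed, validated `pqn_params` object.
#' @export
load_mode_params <- function(source) {
  stopifnot(is.character(source), length(source) == 1L)
  path <- source
  if (!file.exists(path)) {
    fname <- paste0(tolower(source), ".json")
    path <- system.file("extdata", "modes", fname, package = "pqnsim")
    if (identical(path, ""))
      .pqn_stop(paste0("unknown mode name or missing file: ", source),
                "pqn_config_error")
  }
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    .pqn_stop(paste0("malformed parameter JSON: ",
                                     conditionMessage(e)),
                              "pqn_schema_error"))
  if (!is.list(doc) || is.null(doc$mode) || is.null(doc$variant))
    .pqn_stop("parameter document must contain 'mode' and 'variant'",
              "pqn_schema_error")
  mode <- as.character(doc$mode)
  variant <- as.character(doc$variant)
  if (!variant %in% .pqn_variants)
    .pqn_stop(paste0("unknown variant in parameter file: ", variant),
              "pqn_schema_error")
  dt <- if (!is.null(doc$dt)) as.numeric(doc$dt) else NULL
  drop <- c("mode", "variant", "dt", "comment",
            .pqn_derived_fields(variant))
  vals <- doc[setdiff(names(doc), drop)]
  bad <- names(vals)[!vapply(vals, function(v)
    is.numeric(v) && length(v) == 1L && is.finite(v), logical(1))]
  if (length(bad))
    .pqn_stop(paste0("non-scalar or non-numeric parameter value(s): ",
                     paste(bad, collapse = ", ")), "pqn_schema_error")
  p <- do.call(pqn_params,
               c(list(mode = mode, variant = variant, dt = dt), vals))
  d <- validate_parameters(p)
  if (nrow(d))
    .pqn_stop(paste0("invalid parameter set: ",
                     paste(d$field, d$rule, sep = ": ", collapse = "; ")),
              "pqn_config_error")
  p
}

#' Write a PQN parameter set to a JSON file
#'
#' The written document round-trips through [load_mode_params()]; derived
#' coefficients are included for human readers but recomputed on load.
#'
#' @param p A `pqn_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_params <- function(p, path) {
  stopifnot(inherits(p, "pqn_params"))
  jsonlite::write_json(unclass(p), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' List the bundled mode parameter sets
#'
#' @return Character vector of mode names accepted by [load_mode_params()].
#' @export
bundled_modes <- function() {
  dir <- system.file("extdata", "modes", package = "pqnsim")
  sub("\\.json$", "", basename(list.files(dir, pattern = "\\.json$")))
}
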