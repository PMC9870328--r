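#' Piecewise-constant stimulus programs
#'
#' A stimulus program is a right-continuous piecewise-constant function of
#' time: `amplitudes[i]` applies on `[breakpoints[i], breakpoints[i+1])`
#' and the last amplitude holds from the last breakpoint onward.  Before
#' the first breakpoint the stimulus is zero.
#'
#' @param breakpoints Strictly increasing times in seconds.
#' @param amplitudes Stimulus value on each interval (same length as
#'   `breakpoints`).
#' @return An object of class `stimulus_program`.
#' @export
#' @examples
#' stim_pulse(0.1, 0.002, 0.5)            # 2 ms pulse at t = 0.1 s
#' s <- stimulus_program(c(0, 1), c(2, 0)) # step of 2 switched off at 1 s
#' stim_eval(s, c(-1, 0, 0.5, 1, 2))
stimulus_program <- function(breakpoints, amplitudes) {
  breakpoints <- as.numeric(breakpoints)
  amplitudes <- as.numeric(amplitudes)
  if (length(breakpoints) != length(amplitudes))
    .pqn_stop("breakpoints and amplitudes must have equal length",
              "pqn_config_error")
  if (length(breakpoints) && any(diff(breakpoints) <= 0))
    .pqn_stop("breakpoints must be strictly increasing", "pqn_config_error")
  structure(list(breakpoints = breakpoints, amplitudes = amplitudes),
            class = "stimulus_program")
}

#' @rdname stimulus_program
#' @param t Times at which to evaluate (vectorised).
#' @param stim A `stimulus_program`.
#' @return `stim_eval`: numeric vector of stimulus values.
#' @export
stim_eval <- function(stim, t) {
  stopifnot(inherits(stim, "stimulus_program"))
  if (!length(stim$breakpoints)) return(numeric(length(t)))
  idx <- findInterval(t, stim$breakpoints)
  out <- numeric(length(t))
  pos <- idx > 0L
  out[pos] <- stim$amplitudes[idx[pos]]
  out
}

#' @rdname stimulus_program
#' @param amp Amplitude.
#' @export
stim_const <- function(amp) stimulus_program(0, amp)

#' @rdname stimulus_program
#' @param t0 Onset time in seconds.
#' @export
stim_step <- function(t0, amp) stimulus_program(t0, amp)

#' @rdname stimulus_program
#' @param dur Pulse duration in seconds.
#' @export
stim_pulse <- function(t0, dur, amp) {
  stopifnot(dur > 0)
  stimulus_program(c(t0, t0 + dur), c(amp, 0))
}

#' Parse a CLI stimulus specification
#'
#' Accepted forms: `const:amp=<a>`, `step:t0=<s>,amp=<a>`,
#' `pulse:t0=<s>,dur=<s>,amp=<a>`, or the path of a two-column CSV file
#' with header `time,amplitude` holding the breakpoints.
#'
#' @param spec Specification string or CSV path.
#' @return A [stimulus_program()].
#' @export
parse_stimulus_spec <- function(spec) {
  stopifnot(is.character(spec), length(spec) == 1L)
  if (file.exists(spec)) {
    df <- utils::read.csv(spec)
    if (!all(c("time", "amplitude") %in% names(df)))
      .pqn_stop("stimulus CSV needs columns 'time' and 'amplitude'",
                "pqn_parse_error")
    return(stimulus_program(df$time, df$amplitude))
  }
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  kind <- parts[1]
  kv <- list()
  if (length(parts) > 1) {
    for (item in strsplit(parts[2], ",", fixed = TRUE)[[1]]) {
      eq <- strsplit(item, "=", fixed = TRUE)[[1]]
      if (length(eq) != 2L)
        .pqn_stop(paste0("cannot parse stimulus item: ", item),
                  "pqn_parse_error")
      kv[[eq[1]]] <- as.numeric(eq[2])
    }
  }
  need <- function(k) {
    if (is.null(kv[[k]]) || is.na(kv[[k]]))
      .pqn_stop(paste0("stimulus spec '", kind, "' needs ", k),
                "pqn_parse_error")
    kv[[k]]
  }
  switch(kind,
    const = stim_const(need("amp")),
    step  = stim_step(need("t0"), need("amp")),
    pulse = stim_pulse(need("t0"), need("dur"), need("amp")),
    .pqn_stop(paste0("unknown stimulus kind: ", kind), "pqn_parse_error")
  )
}
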