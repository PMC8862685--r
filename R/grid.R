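#' Discrete simulation clock
#'
#' Defines the time step and duration shared by every trace in a simulation.
#' Sample `k` (1-based index `k + 1` in R vectors) maps to time `t = k * dt`.
#'
#' @param dt Time step in ms. Default 0.1 ms; some experiments use 0.02 ms.
#' @param duration Total simulated time L in ms.
#' @return An object of class `sim_grid` with fields `dt`, `duration`,
#'   `n_steps` and `times` (the grid times in ms, starting at 0).
#' @examples
#' g <- sim_grid(dt = 0.1, duration = 1000)
#' g$n_steps
#' @export
sim_grid <- function(dt = 0.1, duration = 1000) {
  stopifnot(is.numeric(dt), length(dt) == 1, is.finite(dt), dt > 0,
            is.numeric(duration), length(duration) == 1,
            is.finite(duration), duration > 0)
  n_steps <- as.integer(round(duration / dt))
  structure(list(dt = dt, duration = duration, n_steps = n_steps,
                 times = (seq_len(n_steps) - 1) * dt),
            class = "sim_grid")
}

#' @export
print.sim_grid <- function(x, ...) {
  cat(sprintf("<sim_grid> dt = %g ms, duration = %g ms, %d steps\n",
              x$dt, x$duration, x$n_steps))
  invisible(x)
}

assert_grid_trace <- function(grid, values, what = "trace") {
  if (length(values) != grid$n_steps) {
    stop(sprintf("%s length (%d) does not match grid n_steps (%d)",
                 what, length(values), grid$n_steps), call. = FALSE)
  }
  invisible(TRUE)
}
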