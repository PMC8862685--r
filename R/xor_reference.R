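#' Expected output of the exclusive-or computation
#'
#' Ground truth for the XOR circuit: at each grid time `t`, output is
#' expected iff exactly one of the two input trains has at least one spike
#' in the centered window `[t - t_bin/2, t + t_bin/2]` (closed on both
#' ends, truncated at the trial boundaries; the half-window is snapped to
#' the grid).
#'
#' @param grid A [sim_grid()].
#' @param i1,i2 Input spike trains (ms), aligned to the grid.
#' @param t_bin Window length (ms), conventionally 10 or 5.
#' @return An object of class `xor_expectation`: list with `expected`
#'   (logical per grid step), `t_bin` and `grid`.
#' @export
expected_xor <- function(grid, i1, i2, t_bin = 10) {
  half <- as.integer(round(t_bin / 2 / grid$dt))
  n <- grid$n_steps
  in_window <- function(sp) {
    has <- spike_counts(grid, sp) > 0
    if (!any(has)) return(logical(n))
    # running any() over a centered window of half-width `half` steps
    cs <- cumsum(c(0L, as.integer(has)))
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    (cs[hi + 1L] - cs[lo]) > 0L
  }
  structure(list(expected = in_window(i1) != in_window(i2),
                 t_bin = t_bin, grid = grid),
            class = "xor_expectation")
}

#' @export
print.xor_expectation <- function(x, ...) {
  cat(sprintf("<xor_expectation> t_bin = %g ms, expected on %.1f%% of steps\n",
              x$t_bin, 100 * mean(x$expected)))
  invisible(x)
}

#' Write an XOR expectation series as CSV
#'
#' @param x An [expected_xor()] result.
#' @param path Output path; columns `time_ms`, `expected`.
#' @export
write_xor_csv <- function(x, path) {
  utils::write.csv(data.frame(time_ms = x$grid$times,
                              expected = as.integer(x$expected)),
                   path, row.names = FALSE)
  invisible(path)
}
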