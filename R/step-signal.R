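#' Per-step plantar force signal
#'
#' One gait cycle's spatially integrated plantar force: the pressure map
#' summed over the footprint and multiplied by the cell area, giving a
#' force series in Pa * m^2 (= N) sampled every `dt` seconds, re-indexed
#' so that initial foot contact is sample 1.
#'
#' @param values Numeric force series.
#' @param dt Sampling interval in seconds.
#' @param foot `"l"`, `"r"` or `NA`.
#' @param cycle Gait-cycle index for this foot, or `NA`.
#' @param stance_len Number of frames of genuine contact; when `NULL` it
#'   is taken as the last frame whose magnitude exceeds 0.5% of the peak.
#' @param person,speed Optional labels carried through the pipeline.
#' @return An object of class `step_signal`.
#' @export
step_signal <- function(values, dt = 0.02, foot = NA_character_,
                        cycle = NA_integer_, stance_len = NULL,
                        person = NA_character_, speed = NA_character_) {
  stopifnot(is.numeric(values), length(values) >= 2, dt > 0)
  if (is.null(stance_len)) stance_len <- .stance_length(values)
  stopifnot(stance_len <= length(values))
  structure(list(values = as.numeric(values), dt = dt, foot = foot,
                 cycle = as.integer(cycle), stance_len = as.integer(stance_len),
                 person = person, speed = speed),
            class = "step_signal")
}

#' Zero-pad a step signal to a fixed length
#'
#' Truncates the signal at its stance length (everything beyond becomes an
#' exact zero) and extends it with zeros to `pad_to` frames. The padding
#' forces the modelled signal to decay to zero by the end of the window,
#' which keeps the fitted eigenvalues inside the unit circle.
#'
#' @param step A [step_signal()].
#' @param pad_to Target length in frames (default 100).
#' @return A `step_signal` of length `pad_to`.
#' @export
pad_step_signal <- function(step, pad_to = 100) {
  stopifnot(inherits(step, "step_signal"))
  if (step$stance_len > pad_to) {
    stop("stance of ", step$stance_len, " frames exceeds pad_to = ", pad_to,
         "; increase pad_to")
  }
  v <- numeric(pad_to)
  keep <- seq_len(step$stance_len)
  v[keep] <- step$values[keep]
  step_signal(v, dt = step$dt, foot = step$foot, cycle = step$cycle,
              stance_len = step$stance_len, person = step$person,
              speed = step$speed)
}

#' @export
print.step_signal <- function(x, ...) {
  cat("<step_signal>", length(x$values), "frames @", x$dt, "s | stance",
      x$stance_len, "frames | peak", format(max(x$values), digits = 4), "N")
  if (!is.na(x$foot)) cat(" | foot", x$foot)
  cat("\n")
  invisible(x)
}

#' Tidy a step signal into a time/force tibble
#'
#' @param x A `step_signal`.
#' @param ... Unused.
#' @export
tidy.step_signal <- function(x, ...) {
  tibble::tibble(frame = seq_along(x$values) - 1L,
                 time = (seq_along(x$values) - 1L) * x$dt,
                 force = x$values,
                 stance = seq_along(x$values) <= x$stance_len)
}
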