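# Structured error conditions. Every error raised by the package carries the
# class "spinetrace_error" plus a specific subclass so callers (and the CLI)
# can map failures to exit codes without string matching.

st_stop <- function(subclass, message, call = sys.call(-1)) {
  stop(structure(
    class = c(subclass, "spinetrace_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

st_io_error <- function(message) st_stop("spinetrace_io_error", message)
st_format_error <- function(message) st_stop("spinetrace_format_error", message)
st_domain_error <- function(message) st_stop("spinetrace_domain_error", message)
st_geometry_error <- function(message) st_stop("spinetrace_geometry_error", message)
st_config_error <- function(message) st_stop("spinetrace_config_error", message)

st_no_spine_error <- function(message = "no spine detected: mask has no foreground pixels") {
  st_stop("spinetrace_no_spine_error", message)
}
st_insufficient_midpoints_error <- function(message) {
  st_stop("spinetrace_insufficient_midpoints_error", message)
}
st_unmeasurable_curve_error <- function(message) {
  st_stop("spinetrace_unmeasurable_curve_error", message)
}

#' Map a condition to a command-line exit status
#'
#' The command-line interface converts pipeline failures into small integer
#' exit codes: 2 for input/output problems, 3 when no spine is found in the
#' mask, 4 when too few grid midpoints are available, 5 when a curve segment
#' has no usable tilted-vertebra candidate, and 1 for any other error.
#'
#' @param cond A condition object (typically caught with `tryCatch`).
#' @return An integer exit status.
#' @export
exit_status_for <- function(cond) {
  if (inherits(cond, "spinetrace_io_error")) return(2L)
  if (inherits(cond, "spinetrace_no_spine_error")) return(3L)
  if (inherits(cond, "spinetrace_insufficient_midpoints_error")) return(4L)
  if (inherits(cond, "spinetrace_unmeasurable_curve_error")) return(5L)
  1L
}
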