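#' External input (perturbation) signals
#'
#' An input signal is the time course of an external stimulus entering the
#' network (here typically a medium-exchange perturbation that decays as the
#' cells adapt). Supported forms:
#'
#' * `"exponential-decay"`: `u(t) = u0 * exp(-lambda * (t - t0))`, parameters
#'   `u0` (start value, default 1), `lambda` (decay rate per hour, must be
#'   > 0, default 0.5) and `t0` (default 0). Strictly decreasing for `u0 > 0`.
#' * `"linear"`: `u(t) = intercept + slope * t`.
#' * `"constant"`: `u(t) = value`.
#' * `"tabulated"`: linear interpolation through `(times, values)` pairs,
#'   constant beyond the range.
#'
#' @param kind one of `"exponential-decay"`, `"linear"`, `"constant"`,
#'   `"tabulated"`.
#' @param id identifier of the input node (default `"input"`).
#' @param ... parameters of the chosen form (see above).
#' @return Object of class `"input_signal"`; evaluate it with
#'   [eval_input()].
#' @examples
#' u <- input_signal("exponential-decay", lambda = 1)
#' eval_input(u, c(0, 1))  # 1, exp(-1)
#' @export
input_signal <- function(kind, id = "input", ...) {
  params <- list(...)
  fn <- switch(kind,
    "exponential-decay" = {
      u0 <- params$u0 %||% 1; lambda <- params$lambda %||% 0.5
      t0 <- params$t0 %||% 0
      if (lambda <= 0) stop("exponential-decay requires lambda > 0")
      function(t) u0 * exp(-lambda * (t - t0))
    },
    "linear" = {
      a <- params$intercept %||% 0; b <- params$slope %||% 0
      function(t) a + b * t
    },
    "constant" = {
      v <- params$value %||% 0
      function(t) rep(v, length(t))
    },
    "tabulated" = {
      tt <- params$times; vv <- params$values
      if (is.null(tt) || is.null(vv) || length(tt) != length(vv))
        stop("tabulated input needs matching 'times' and 'values'")
      function(t) stats::approx(tt, vv, xout = t, rule = 2)$y
    },
    stop("unknown input signal kind: ", kind)
  )
  structure(list(id = id, kind = kind, params = params, fn = fn),
            class = "input_signal")
}

#' @rdname input_signal
#' @param u an `input_signal`.
#' @param t numeric vector of times (hours).
#' @export
eval_input <- function(u, t) u$fn(t)

#' @export
print.input_signal <- function(x, ...) {
  p <- x$params
  cat(sprintf("Input signal '%s': %s%s\n", x$id, x$kind,
              if (length(p)) paste0(" (", paste(names(p), unlist(lapply(p, paste, collapse = ",")),
                                                sep = "=", collapse = ", "), ")") else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an inference configuration from YAML
#'
#' The YAML file may define `dt`, `delta` (prior weight), `input_weight`,
#' `autoreg_weight`, `alpha`, `cp_form`, `max_iter`, `seed` and an `input`
#' block (`kind` plus its parameters). Unspecified fields fall back to the
#' [extilar_control()] defaults.
#'
#' @param path YAML file path.
#' @return list with elements `control` (an `extilar_control` list) and
#'   `inputs` (list of [input_signal()]s, possibly empty).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  ctrl_args <- cfg[intersect(names(cfg),
                             names(formals(extilar_control)))]
  ctrl <- do.call(extilar_control, ctrl_args)
  inputs <- list()
  if (!is.null(cfg$input)) {
    spec <- cfg$input
    kind <- spec$kind %||% "exponential-decay"
    spec$kind <- NULL
    inputs <- list(do.call(input_signal, c(list(kind = kind), spec)))
  }
  list(control = ctrl, inputs = inputs)
}
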