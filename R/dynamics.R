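#' Right-hand side of the network ODE
#'
#' Evaluates `dx/dt = A x + D u(t)` at a state vector, where `A` and `D` are
#' the collapsed gene-level matrices of [system_matrix()]. This is also the
#' one-step map of the difference-equation form: a forward Euler step is
#' `x + dt * network_rhs(nm, x, t)`.
#'
#' @param nm an `extilar_network`.
#' @param x named (or gene-ordered) state vector.
#' @param t time in hours.
#' @return named derivative vector.
#' @export
network_rhs <- function(nm, x, t = 0) {
  sys <- system_matrix(nm)
  x <- if (!is.null(names(x))) x[nm$genes] else stats::setNames(x, nm$genes)
  dx <- drop(sys$A %*% x)
  if (ncol(sys$D))
    dx <- dx + drop(sys$D %*% vapply(sys$inputs, eval_input, 0, t = t))
  stats::setNames(dx, nm$genes)
}

#' Simulate a network model as a linear ODE system
#'
#' Integrates `dx_i/dt = sum_k sum_j (1 - b_kj) w_kj x_j b_ki + a_i x_i +
#' sum_c d_ci u_c(t)` with an adaptive explicit Runge-Kutta scheme
#' (Dormand-Prince 4/5 via \pkg{deSolve}). Genes listed in `clamp` are removed
#' from the integrated state; wherever their value appears in the coupling
#' terms of other genes the clamp function value is substituted, and their own
#' equation is ignored.
#'
#' @param nm an `extilar_network` (a fitted `"extilar"` model works too).
#' @param x0 named initial state covering all genes (clamped genes may be
#'   omitted).
#' @param times output time grid in hours.
#' @param clamp named list mapping gene id to a function of `t` (or a single
#'   number); these trajectories are imposed, not integrated.
#' @param rtol,atol solver tolerances.
#' @param method a \pkg{deSolve} integrator name (default `"ode45"`).
#' @return Object of class `"network_trajectory"`: list with `times`, `states`
#'   (time x gene matrix including clamped genes), `clamped`, `solver`.
#' @examples
#' nm <- network_model("g1", binding_matrix(data.frame(tf = "T1", gene = "g1"),
#'                                          "g1"),
#'                     autoreg = c(g1 = -1))
#' tr <- simulate_network(nm, c(g1 = 1), times = seq(0, 1, 0.1))
#' tr$states[11, "g1"]  # ~ exp(-1)
#' @export
simulate_network <- function(nm, x0, times, clamp = NULL,
                             rtol = 1e-6, atol = 1e-8, method = "ode45") {
  stopifnot(inherits(nm, "extilar_network"))
  sys <- system_matrix(nm)
  genes <- nm$genes
  clamp <- normalize_clamp(clamp, genes)
  free <- setdiff(genes, names(clamp))
  if (is.null(names(x0)) && length(x0) == length(genes)) names(x0) <- genes
  missing_x0 <- setdiff(free, names(x0))
  if (length(missing_x0))
    stop("x0 misses gene(s): ", paste(missing_x0, collapse = ", "))

  Aff <- sys$A[free, free, drop = FALSE]
  Afc <- sys$A[free, names(clamp), drop = FALSE]
  Df <- sys$D[free, , drop = FALSE]
  u_of_t <- function(t) vapply(sys$inputs, eval_input, 0, t = t)
  c_of_t <- function(t) vapply(clamp, function(f) f(t), 0)

  deriv <- function(t, y, parms) {
    dy <- drop(Aff %*% y)
    if (length(clamp)) dy <- dy + drop(Afc %*% c_of_t(t))
    if (ncol(Df)) dy <- dy + drop(Df %*% u_of_t(t))
    list(dy)
  }
  sol <- tryCatch(
    deSolve::ode(y = x0[free], times = times, func = deriv, parms = NULL,
                 method = method, rtol = rtol, atol = atol),
    error = function(e)
      stop("ODE solver failed (", conditionMessage(e),
           "); consider loosening rtol/atol or checking coefficient stability"))
  states <- matrix(NA_real_, length(times), length(genes),
                   dimnames = list(NULL, genes))
  states[, free] <- unclass(sol)[, free, drop = FALSE]
  for (g in names(clamp)) states[, g] <- clamp[[g]](times)
  structure(list(times = times, states = states, clamped = clamp,
                 solver = list(method = method, rtol = rtol, atol = atol)),
            class = "network_trajectory")
}

normalize_clamp <- function(clamp, genes) {
  if (is.null(clamp)) return(stats::setNames(list(), character()))
  stopifnot(is.list(clamp), !is.null(names(clamp)))
  unknown <- setdiff(names(clamp), genes)
  if (length(unknown)) stop("unknown gene(s) in clamp: ",
                            paste(unknown, collapse = ", "))
  lapply(clamp, function(f) {
    if (is.function(f)) function(t) vapply(t, f, 0)
    else {v <- as.numeric(f); function(t) rep(v, length(t))}
  })
}

#' @export
simulate.extilar_network <- function(object, nsim = 1, seed = NULL,
                                     x0, times, ...) {
  simulate_network(object, x0 = x0, times = times, ...)
}

#' @export
print.network_trajectory <- function(x, ...) {
  cat(sprintf("Network trajectory: %d genes on t = %g..%g h (%d points)%s\n",
              ncol(x$states), min(x$times), max(x$times), length(x$times),
              if (length(x$clamped))
                paste0("; clamped: ", paste(names(x$clamped), collapse = ", "))
              else ""))
  invisible(x)
}

#' @export
as.data.frame.network_trajectory <- function(x, ...) {
  data.frame(time = x$times, x$states, check.names = FALSE)
}

#' Write a trajectory as TSV (time, one column per gene)
#' @param traj a `network_trajectory`.
#' @param path output path.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.table(format(as.data.frame(traj), digits = 15, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' In-silico knockdown by trajectory clamping
#'
#' Replaces one gene's trajectory by a prescribed clamp function (by default
#' a linear decrease from 0 at the start of the horizon to -1 at its end, on
#' the scaled log2-FC working scale) and integrates the remaining genes. The
#' clamped gene's own equation is ignored; its clamp value is substituted
#' wherever the gene appears as a regulator.
#'
#' @param nm an `extilar_network`.
#' @param gene the gene to knock down.
#' @param clamp function of `t`, a single number, or `NULL` for the default
#'   linear 0 -> -1 ramp over `range(times)`.
#' @param x0 initial state for the unclamped genes.
#' @param times output grid (hours).
#' @param ... passed to [simulate_network()].
#' @return a `network_trajectory`.
#' @export
knockdown <- function(nm, gene, clamp = NULL, x0, times, ...) {
  stopifnot(inherits(nm, "extilar_network"))
  if (!gene %in% nm$genes) stop("unknown gene: ", gene)
  if (is.null(clamp)) {
    t0 <- min(times); t1 <- max(times)
    clamp <- function(t) -(t - t0) / (t1 - t0)
  }
  simulate_network(nm, x0 = x0, times = times,
                   clamp = stats::setNames(list(clamp), gene), ...)
}

#' Explicit forward-Euler discretization of a network model
#'
#' Iterates the difference-equation form `x[t + dt] = x[t] + dt * (A x[t] +
#' D u(t))` that the regression was built from; used to verify the
#' regression/simulation consistency and as a fixed-step reference.
#'
#' @param nm an `extilar_network`.
#' @param x0 named initial state.
#' @param dt step size (hours).
#' @param n_steps number of steps.
#' @param t0 start time.
#' @return a `network_trajectory` with `n_steps + 1` points.
#' @export
euler_discretize <- function(nm, x0, dt, n_steps, t0 = 0) {
  stopifnot(dt > 0, n_steps >= 0)
  sys <- system_matrix(nm)
  genes <- nm$genes
  if (is.null(names(x0)) && length(x0) == length(genes)) names(x0) <- genes
  x <- x0[genes]
  times <- t0 + dt * (0:n_steps)
  states <- matrix(NA_real_, n_steps + 1L, length(genes),
                   dimnames = list(NULL, genes))
  states[1L, ] <- x
  if (n_steps > 0) for (s in seq_len(n_steps)) {
    t_prev <- times[s]
    dx <- drop(sys$A %*% x)
    if (ncol(sys$D))
      dx <- dx + drop(sys$D %*% vapply(sys$inputs, eval_input, 0, t = t_prev))
    x <- x + dt * dx
    states[s + 1L, ] <- x
  }
  structure(list(times = times, states = states,
                 clamped = stats::setNames(list(), character()),
                 solver = list(method = "euler", dt = dt)),
            class = "network_trajectory")
}
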