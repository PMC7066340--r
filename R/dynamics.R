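#' Right-hand side of the rescaled compartment model
#'
#' The model tracks the fractions x = V1/N (high vulnerability),
#' y = V2/N (low vulnerability) and z = M/N (complete mental health):
#' \deqn{dx/dt = a\mu - \mu x + \epsilon x y - \alpha x}
#' \deqn{dy/dt = b\mu - \mu y - \epsilon x y + \alpha x - \delta y z + \beta z}
#' \deqn{dz/dt = c\mu - \mu z + \delta y z - \beta z}
#' Negative peer pressure (epsilon) moves V2 into V1, physical exercise
#' (alpha) moves V1 into V2, positive peer pressure (delta) moves V2 into
#' M, and technology use (beta) moves M back into V2. Summing the three
#' equations gives d(x+y+z)/dt = mu((a+b+c) - (x+y+z)), so the total
#' fraction relaxes to a+b+c at rate mu.
#'
#' @param state Numeric vector `c(x =, y =, z =)`.
#' @param params An `mdd_parameters` vector (or coercible named vector).
#' @return Named numeric vector `c(dx =, dy =, dz =)`, /day.
#' @export
derivatives <- function(state, params) {
  p <- as_parameters(params)
  x <- state[[1]]; y <- state[[2]]; z <- state[[3]]
  c(dx = p[["a"]] * p[["mu"]] - p[["mu"]] * x + p[["epsilon"]] * x * y -
        p[["alpha"]] * x,
    dy = p[["b"]] * p[["mu"]] - p[["mu"]] * y - p[["epsilon"]] * x * y +
        p[["alpha"]] * x - p[["delta"]] * y * z + p[["beta"]] * z,
    dz = p[["c"]] * p[["mu"]] - p[["mu"]] * z + p[["delta"]] * y * z -
        p[["beta"]] * z)
}

#' Right-hand side of the raw (count-scale) compartment model
#'
#' The unrescaled system in compartment counts V1, V2, M with fixed total
#' population N; dividing by N recovers [derivatives()] evaluated at the
#' fractions.
#'
#' @param counts Numeric vector `c(V1 =, V2 =, M =)`.
#' @param params Model parameters.
#' @param n Total population; positive.
#' @return Named numeric vector `c(dV1 =, dV2 =, dM =)`, counts/day.
#' @export
raw_derivatives <- function(counts, params, n) {
  if (!is.finite(n) || n <= 0) stop("n must be positive", call. = FALSE)
  p <- as_parameters(params)
  v1 <- counts[[1]]; v2 <- counts[[2]]; m <- counts[[3]]
  c(dV1 = p[["a"]] * p[["mu"]] * n - p[["mu"]] * v1 +
          p[["epsilon"]] * v1 * v2 / n - p[["alpha"]] * v1,
    dV2 = p[["b"]] * p[["mu"]] * n - p[["mu"]] * v2 -
          p[["delta"]] * v2 * m / n - p[["epsilon"]] * v1 * v2 / n +
          p[["alpha"]] * v1 + p[["beta"]] * m,
    dM = p[["c"]] * p[["mu"]] * n - p[["mu"]] * m +
         p[["delta"]] * v2 * m / n - p[["beta"]] * m)
}

#' Integrate the rescaled model
#'
#' Solves the rescaled system with an adaptive stiff-capable integrator
#' (`deSolve::ode`, lsoda). When `t_end` is `NULL` the horizon doubles
#' from `t_start` until the terminal derivative infinity-norm drops below
#' `steady_tol` (steady state) or `t_cap` is reached.
#'
#' @param params Model parameters.
#' @param init Initial fractions `c(x, y, z)`, nonnegative; defaults to
#'   the reference initial state.
#' @param t_end Integration horizon in days, or `NULL` for adaptive
#'   doubling.
#' @param dt_out Output grid spacing, days.
#' @param rtol,atol Solver relative/absolute tolerances.
#' @param normalize_entry If `TRUE`, rescale (a, b, c) to sum to 1 before
#'   integrating (the equilibrium cubic is derived under x + y + z = 1).
#' @param steady_tol Steady-state threshold on the terminal derivative
#'   infinity-norm.
#' @param t_start,t_cap Initial and maximal horizon for adaptive doubling.
#' @return An object of class `mdd_trajectory`: a data frame with columns
#'   `time`, `x`, `y`, `z` and attributes `params`, `converged` (logical:
#'   terminal derivative norm below `steady_tol`), `terminal_fnorm`,
#'   `rtol`, `atol`.
#' @examples
#' tr <- simulate_trajectory(reference_parameters(), t_end = 50)
#' tail(tr, 2)
#' @export
simulate_trajectory <- function(params, init = reference_init(),
                                t_end = NULL, dt_out = 1,
                                rtol = 1e-8, atol = 1e-10,
                                normalize_entry = FALSE,
                                steady_tol = 1e-8,
                                t_start = 100, t_cap = 2e5) {
  p <- as_parameters(params)
  if (normalize_entry) {
    s <- p[["a"]] + p[["b"]] + p[["c"]]
    if (s <= 0) stop("cannot normalize: a + b + c = 0", call. = FALSE)
    p[c("a", "b", "c")] <- p[c("a", "b", "c")] / s
  }
  init <- as.numeric(init)
  if (length(init) != 3 || any(!is.finite(init)) || any(init < 0))
    stop("init must be three nonnegative fractions", call. = FALSE)
  rhs <- function(t, s, parms) list(unname(derivatives(s, parms)))

  run <- function(te) {
    times <- unique(c(seq(0, te, by = dt_out), te))
    out <- deSolve::ode(y = c(x = init[1], y = init[2], z = init[3]),
                        times = times, func = rhs, parms = p,
                        method = "lsoda", rtol = rtol, atol = atol)
    if (attr(out, "istate")[1] < 0)
      stop("ODE solver failed (istate = ", attr(out, "istate")[1],
           ") at t_end = ", te, call. = FALSE)
    out
  }

  if (!is.null(t_end)) {
    if (t_end <= 0) stop("t_end must be positive", call. = FALSE)
    out <- run(t_end)
  } else {
    te <- t_start
    repeat {
      out <- run(te)
      fn <- max(abs(derivatives(out[nrow(out), c("x", "y", "z")], p)))
      if (fn < steady_tol || te >= t_cap) break
      te <- min(2 * te, t_cap)
    }
  }
  df <- as.data.frame(out)[, c("time", "x", "y", "z")]
  term <- unlist(df[nrow(df), c("x", "y", "z")])
  structure(df, class = c("mdd_trajectory", "data.frame"),
            params = p,
            terminal_fnorm = max(abs(derivatives(term, p))),
            converged = max(abs(derivatives(term, p))) < steady_tol,
            rtol = rtol, atol = atol)
}

#' @export
print.mdd_trajectory <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("Compartment trajectory: %d points over %g days\n",
              n, x$time[n]))
  cat(sprintf("  terminal (x, y, z) = (%.6f, %.6f, %.6f)\n",
              x$x[n], x$y[n], x$z[n]))
  cat(sprintf("  terminal |f|_inf = %.3g (%s)\n", attr(x, "terminal_fnorm"),
              if (isTRUE(attr(x, "converged"))) "steady" else "not steady"))
  invisible(x)
}

#' @export
plot.mdd_trajectory <- function(x, ...) {
  graphics::matplot(x$time, as.matrix(x[, c("x", "y", "z")]), type = "l",
                    lty = 1, lwd = 2, col = c("firebrick", "steelblue",
                                              "forestgreen"),
                    xlab = "time (days)", ylab = "population fraction", ...)
  graphics::legend("right", legend = c("x (high vuln.)", "y (low vuln.)",
                                       "z (complete)"),
                   col = c("firebrick", "steelblue", "forestgreen"),
                   lty = 1, lwd = 2, bty = "n")
  invisible(x)
}

#' Sweep one parameter and record terminal states
#'
#' Re-integrates the model over a grid of values for one of the
#' intervention rates, holding everything else fixed, and records the
#' terminal fractions -- the computation behind "as alpha increases the
#' highly vulnerable population decreases"-type statements.
#'
#' @param params Base model parameters.
#' @param param_name One of `"delta"`, `"epsilon"`, `"alpha"`, `"beta"`.
#' @param grid Nonempty vector of nonnegative parameter values.
#' @param init Initial fractions, shared across grid points.
#' @param t_end Horizon per point (`NULL` for adaptive; see
#'   [simulate_trajectory()]).
#' @param ... Further arguments passed to [simulate_trajectory()].
#' @return Data frame `param`, `value`, `x_end`, `y_end`, `z_end`,
#'   `converged`. Solver failures at single points are flagged (`NA`
#'   terminal state, `converged = FALSE`) without aborting the sweep.
#' @export
sweep_terminal <- function(params, param_name, grid,
                           init = reference_init(), t_end = NULL, ...) {
  if (!param_name %in% c("delta", "epsilon", "alpha", "beta"))
    stop("param_name must be one of delta, epsilon, alpha, beta",
         call. = FALSE)
  if (length(grid) == 0 || any(grid < 0))
    stop("grid must be nonempty and nonnegative", call. = FALSE)
  p <- as_parameters(params)
  rows <- lapply(grid, function(v) {
    p[param_name] <- v
    tr <- tryCatch(simulate_trajectory(p, init = init, t_end = t_end, ...),
                   error = function(e) NULL)
    if (is.null(tr))
      return(data.frame(param = param_name, value = v, x_end = NA_real_,
                        y_end = NA_real_, z_end = NA_real_,
                        converged = FALSE))
    n <- nrow(tr)
    data.frame(param = param_name, value = v, x_end = tr$x[n],
               y_end = tr$y[n], z_end = tr$z[n],
               converged = isTRUE(attr(tr, "converged")))
  })
  do.call(rbind, rows)
}
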