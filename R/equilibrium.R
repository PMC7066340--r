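#' Coefficients of the equilibrium cubic in y
#'
#' Setting the rescaled system to zero, eliminating z via
#' z = c mu / (beta + mu - delta y) and x via x = 1 - y - z (the derivation
#' assumes x + y + z = 1) yields a cubic A y^3 + B y^2 + C y + D = 0 with
#' \deqn{A = \epsilon\delta}
#' \deqn{B = -(\mu\delta + \epsilon\delta + \epsilon\beta + \alpha\delta + \mu\epsilon)}
#' \deqn{C = \mu\delta - a\mu\delta + \mu^2 + \mu\beta + \epsilon\mu +
#'   \epsilon\beta + \alpha\delta + \alpha\mu + \alpha\beta - c\epsilon\mu}
#' \deqn{D = a\mu^2 + a\mu\beta - \mu^2 - \mu\beta - \alpha\mu - \alpha\beta
#'   + c\mu^2 + c\mu\alpha}
#'
#' @param params Model parameters.
#' @return Named numeric vector `c(A =, B =, C =, D =)`.
#' @export
cubic_coefficients <- function(params) {
  p <- as_parameters(params)
  mu <- p[["mu"]]; a <- p[["a"]]; cc <- p[["c"]]
  d <- p[["delta"]]; e <- p[["epsilon"]]
  al <- p[["alpha"]]; be <- p[["beta"]]
  c(A = e * d,
    B = -(mu * d + e * d + e * be + al * d + mu * e),
    C = mu * d - a * mu * d + mu^2 + mu * be + e * mu + e * be +
      al * d + al * mu + al * be - cc * e * mu,
    D = a * mu^2 + a * mu * be - mu^2 - mu * be - al * mu - al * be +
      cc * mu^2 + cc * mu * al)
}

#' Vieta symmetric functions of the cubic's roots
#'
#' For A y^3 + B y^2 + C y + D = 0 with roots r1, r2, r3:
#' S1 = r1+r2+r3 = -B/A, S2 = r1 r2 + r1 r3 + r2 r3 = C/A,
#' P = r1 r2 r3 = -D/A.
#'
#' @param coefs Named vector `c(A, B, C, D)` as from
#'   [cubic_coefficients()].
#' @return Named numeric vector `c(S1 =, S2 =, P =)`.
#' @export
vieta <- function(coefs) {
  A <- coefs[["A"]]
  if (A == 0) stop("degenerate cubic: leading coefficient A = 0",
                   call. = FALSE)
  c(S1 = -coefs[["B"]] / A, S2 = coefs[["C"]] / A, P = -coefs[["D"]] / A)
}

#' Root-positivity conditions on the equilibrium cubic
#'
#' All three equilibrium roots are positive only if the Vieta sums are all
#' positive; this evaluates the three inequalities in their expanded
#' parameter form (numerators over epsilon * delta):
#' S1: (mu delta + epsilon delta + epsilon beta + alpha delta +
#' mu epsilon) / (epsilon delta) > 0, and likewise for S2 and P.
#'
#' @param params Model parameters with `epsilon * delta != 0`.
#' @return Named logical vector `c(S1_pos =, S2_pos =, P_pos =)` (strict
#'   inequalities).
#' @export
positivity_conditions <- function(params) {
  p <- as_parameters(params)
  mu <- p[["mu"]]; a <- p[["a"]]; cc <- p[["c"]]
  d <- p[["delta"]]; e <- p[["epsilon"]]
  al <- p[["alpha"]]; be <- p[["beta"]]
  ed <- e * d
  if (ed == 0) stop("degenerate: epsilon * delta = 0", call. = FALSE)
  s1 <- (mu * d + e * d + e * be + al * d + mu * e) / ed
  s2 <- (mu * d - a * mu * d + mu^2 + mu * be + e * mu + e * be +
           al * d + al * mu + al * be - cc * e * mu) / ed
  pr <- -(a * mu^2 + a * mu * be - mu^2 - mu * be - al * mu - al * be +
            cc * mu^2 + cc * mu * al) / ed
  c(S1_pos = s1 > 0, S2_pos = s2 > 0, P_pos = pr > 0)
}

# Real roots of a (possibly degenerate) cubic via companion-matrix
# eigenvalues; complex roots with small imaginary parts are taken as real.
solve_cubic <- function(coefs, imag_tol = 1e-9) {
  co <- as.numeric(coefs)  # (A, B, C, D)
  if (co[1] == 0) {
    warning("degenerate cubic (A = 0): falling back to lower degree",
            call. = FALSE)
    co <- co[-1]
    while (length(co) > 1 && co[1] == 0) co <- co[-1]
    if (length(co) == 1) return(numeric(0))
    if (length(co) == 2) return(-co[2] / co[1])
    disc <- co[2]^2 - 4 * co[1] * co[3]
    if (disc < 0) return(numeric(0))
    return(sort((-co[2] + c(-1, 1) * sqrt(disc)) / (2 * co[1])))
  }
  b <- co[-1] / co[1]  # monic: y^3 + b1 y^2 + b2 y + b3
  comp <- rbind(c(-b[1], -b[2], -b[3]),
                c(1, 0, 0),
                c(0, 1, 0))
  ev <- eigen(comp, only.values = TRUE)$values
  sort(Re(ev[abs(Im(ev)) < imag_tol * max(1, max(Mod(ev)))]))
}

#' Solve the equilibrium cubic for y
#'
#' Real roots are found as companion-matrix eigenvalues and flagged as
#' admissible when they lie in the fraction window (default \[0, 1\]; set
#' `admissible_max = a + b + c` when working with unnormalized entry
#' probabilities).
#'
#' @param params Model parameters.
#' @param admissible_max Upper end of the admissibility window.
#' @return Data frame `root` (ascending), `residual` (cubic evaluated at
#'   the root) and `admissible`.
#' @export
solve_equilibrium_y <- function(params, admissible_max = 1) {
  co <- cubic_coefficients(params)
  roots <- solve_cubic(co)
  resid <- co[["A"]] * roots^3 + co[["B"]] * roots^2 + co[["C"]] * roots +
    co[["D"]]
  data.frame(root = roots, residual = resid,
             admissible = roots >= 0 & roots <= admissible_max)
}

#' Back-substitute the equilibrium z for a given y
#'
#' At equilibrium the complete-mental-health fraction satisfies
#' z = c mu / (beta + mu - delta y).
#'
#' @param y Equilibrium low-vulnerability fraction.
#' @param params Model parameters.
#' @param singular_tol Denominators smaller than this in absolute value
#'   are treated as singular.
#' @return The equilibrium z.
#' @export
equilibrium_z <- function(y, params, singular_tol = 1e-12) {
  p <- as_parameters(params)
  den <- p[["beta"]] + p[["mu"]] - p[["delta"]] * y
  if (abs(den) < singular_tol)
    stop("singular back-substitution: beta + mu - delta*y = ", den,
         " (delta*y = ", p[["delta"]] * y, ")", call. = FALSE)
  p[["c"]] * p[["mu"]] / den
}

#' Jacobian at the disease-free equilibrium (0, 0, 1)
#'
#' @param params Model parameters.
#' @return The 3 x 3 matrix
#'   `rbind(c(-mu-alpha, 0, 0), c(alpha, -mu-delta, beta),
#'   c(0, delta, -mu-beta))`.
#' @export
jacobian_dfe <- function(params) {
  p <- as_parameters(params)
  mu <- p[["mu"]]
  rbind(c(-mu - p[["alpha"]], 0, 0),
        c(p[["alpha"]], -mu - p[["delta"]], p[["beta"]]),
        c(0, p[["delta"]], -mu - p[["beta"]]))
}

#' Stability analysis at the disease-free equilibrium
#'
#' Evaluates the Jacobian at (x, y, z) = (0, 0, 1), its closed-form
#' eigenvalues
#' \deqn{\lambda_1 = -(\mu+\alpha),\quad \lambda_2 = -\mu,\quad
#'   \lambda_3 = -(\mu+\beta+\delta),}
#' a numeric eigendecomposition as cross-check, and the two reproduction-
#' number expressions that appear in the source analysis:
#' `r0_literal = -mu + beta + delta` (the literal printed definition) and
#' `r0_bound = delta (mu + alpha) / epsilon` (the bound implied by the
#' S1 > 0 condition chain). The two are mutually inconsistent for generic
#' parameters; both are reported with provenance notes and no attempt to
#' adjudicate. The equilibrium is stable iff all eigenvalue real parts are
#' negative — which holds for every strictly positive parameter vector,
#' regardless of either R0 exceeding 1; when that tension arises it is
#' flagged in `notes`.
#'
#' Also bundles the equilibrium cubic: coefficients, Vieta sums,
#' positivity conditions and roots.
#'
#' @param params Model parameters.
#' @param admissible_max Root admissibility window upper end (see
#'   [solve_equilibrium_y()]).
#' @return An object of class `stability_report`.
#' @export
stability_analysis <- function(params, admissible_max = 1) {
  p <- as_parameters(params)
  mu <- p[["mu"]]
  J <- jacobian_dfe(p)
  eig_closed <- c(lambda1 = -(mu + p[["alpha"]]),
                  lambda2 = -mu,
                  lambda3 = -(mu + p[["beta"]] + p[["delta"]]))
  eig_num <- eigen(J, only.values = TRUE)$values
  r0_literal <- -mu + p[["beta"]] + p[["delta"]]
  r0_bound <- if (p[["epsilon"]] > 0)
    p[["delta"]] * (mu + p[["alpha"]]) / p[["epsilon"]] else NA_real_
  stable <- all(Re(eig_num) < 0)

  notes <- c(
    "eigenvalue signs follow the trace/determinant of the Jacobian's 2x2 block: lambda3 = -(mu+beta+delta)",
    "r0_literal keeps the literal printed definition R0 = -mu+beta+delta",
    "r0_bound is delta*(mu+alpha)/epsilon from the S1 > 0 condition chain")
  if (is.na(r0_bound))
    notes <- c(notes, "epsilon = 0: r0_bound undefined")
  if (stable && is.finite(r0_literal) && r0_literal >= 1)
    notes <- c(notes, paste0(
      "inconsistency: DFE is numerically stable although r0_literal = ",
      signif(r0_literal, 6),
      " >= 1, at odds with the stated 'stable whenever R0 < 1'"))

  co <- cubic_coefficients(p)
  structure(
    list(jacobian = J,
         eigenvalues = eig_closed,
         eigenvalues_numeric = eig_num,
         r0_literal = r0_literal,
         r0_bound = r0_bound,
         stable = stable,
         cubic = co,
         vieta = if (co[["A"]] != 0) vieta(co) else NULL,
         positivity = if (p[["epsilon"]] * p[["delta"]] != 0)
           positivity_conditions(p) else NULL,
         roots = if (co[["A"]] != 0) solve_equilibrium_y(p, admissible_max)
           else NULL,
         params = p,
         notes = notes),
    class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Stability of the disease-free equilibrium (0, 0, 1)\n")
  cat("  eigenvalues (closed form):",
      paste(sprintf("%.6g", x$eigenvalues), collapse = ", "), "\n")
  cat(sprintf("  stable: %s\n", x$stable))
  cat(sprintf("  R0 (literal -mu+beta+delta): %.6g\n", x$r0_literal))
  cat(sprintf("  R0 bound (delta(mu+alpha)/epsilon): %.6g\n", x$r0_bound))
  if (!is.null(x$vieta))
    cat("  Vieta sums of the equilibrium cubic: S1 =",
        sprintf("%.6g", x$vieta[["S1"]]), " S2 =",
        sprintf("%.6g", x$vieta[["S2"]]), " P =",
        sprintf("%.6g", x$vieta[["P"]]), "\n")
  if (!is.null(x$roots)) {
    adm <- x$roots$root[x$roots$admissible]
    cat("  real cubic roots:",
        paste(sprintf("%.6g", x$roots$root), collapse = ", "),
        if (length(adm)) paste0("(admissible: ",
                                paste(sprintf("%.6g", adm), collapse = ", "),
                                ")") else "(none admissible)", "\n")
  }
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}
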