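#' Fit the three-compartment MDD vulnerability model to a cohort
#'
#' The central fitting function: stratifies a questionnaire cohort into
#' the high-vulnerability (V1), low-vulnerability (V2) and
#' complete-mental-health (M) groups, summarizes band and lifestyle
#' counts, and estimates the full parameter vector of the compartment
#' model (see [derivatives()] for the equations and [estimate_all()] for
#' the estimation arithmetic).
#'
#' @param cohort Data frame of participant records (see [read_cohort()]),
#'   or a ready-made `cohort_summary`.
#' @param scheme A `scoring_scheme`; defaults to [default_scheme()].
#' @param config An [est_config()] controlling the estimation constants.
#' @return An object of class `mdd_model` with components
#'   `classification` (per-participant band/total/state; `NULL` when
#'   fitted from a summary), `summary` (the `cohort_summary`), `fractions`
#'   (x, y, z), `parameters` (`mdd_parameters`), `scheme`, `config` and
#'   `call`. Supports [print()], [summary()], [coef()], [predict()]
#'   (trajectory integration), [simulate()] (synthetic cohorts under the
#'   fitted marginals) and [plot()].
#' @examples
#' fit <- mdd_model(reference_cohort())
#' coef(fit)
#' @export
mdd_model <- function(cohort, scheme = default_scheme(),
                      config = est_config()) {
  if (inherits(cohort, "cohort_summary")) {
    classification <- NULL
    summ <- cohort
  } else {
    cohort <- validate_cohort(cohort)
    classification <- classify_cohort(cohort, scheme)
    summ <- summarize_cohort(cohort, scheme)
  }
  params <- estimate_all(summ, config)
  structure(list(classification = classification,
                 summary = summ,
                 fractions = attr(params, "fractions"),
                 parameters = params,
                 scheme = scheme,
                 config = config,
                 call = match.call()),
            class = "mdd_model")
}

#' @export
print.mdd_model <- function(x, digits = 4, ...) {
  cat("Three-compartment MDD vulnerability model\n\nCall:\n  ")
  print(x$call)
  cts <- x$summary$counts
  cat(sprintf("\nCohort: n = %d (V1 = %d, V2 = %d, M = %d)\n",
              x$summary$n_total, cts[["high_vuln"]], cts[["low_vuln"]],
              cts[["complete"]]))
  cat("Fractions (x, y, z):",
      paste(sprintf("%.4f", x$fractions), collapse = ", "), "\n\n")
  print(x$parameters, digits = digits)
  invisible(x)
}

#' @export
coef.mdd_model <- function(object, ...) {
  stats::setNames(as.numeric(object$parameters), names(object$parameters))
}

#' Summarize a fitted vulnerability model
#'
#' Augments the fit with the equilibrium and stability analysis at the
#' disease-free state (see [stability_analysis()]).
#'
#' @param object An `mdd_model`.
#' @param ... Unused.
#' @return An object of class `summary.mdd_model`.
#' @export
summary.mdd_model <- function(object, ...) {
  structure(list(fit = object,
                 stability = stability_analysis(object$parameters)),
            class = "summary.mdd_model")
}

#' @export
print.summary.mdd_model <- function(x, ...) {
  print(x$fit)
  cat("\n")
  print(x$stability)
  invisible(x)
}

#' Predict compartment trajectories from a fitted model
#'
#' Integrates the fitted model forward from the cohort's observed
#' fractions (or any supplied initial state).
#'
#' @param object An `mdd_model`.
#' @param t_end Horizon in days (`NULL` for adaptive integration to
#'   steady state).
#' @param init Initial fractions; defaults to the fitted cohort fractions.
#' @param ... Passed to [simulate_trajectory()].
#' @return An `mdd_trajectory`.
#' @export
predict.mdd_model <- function(object, t_end = NULL,
                              init = object$fractions, ...) {
  simulate_trajectory(object$parameters, init = init, t_end = t_end, ...)
}

#' Simulate synthetic cohorts from a fitted model
#'
#' Draws cohorts whose band targets, sex split and per-band lifestyle
#' category tables equal the fitted cohort's observed counts, with
#' questionnaire scores resampled within the appropriate levels (see
#' [generate_cohort()]).
#'
#' @param object An `mdd_model` fitted from record-level data.
#' @param nsim Number of cohorts.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A list of `nsim` cohort data frames (a single data frame when
#'   `nsim = 1`).
#' @export
simulate.mdd_model <- function(object, nsim = 1, seed = NULL, ...) {
  s <- object$summary
  as_tab <- function(m) {
    lapply(stats::setNames(band_levels, band_levels), function(b)
      if (sum(m[b, ]) > 0) stats::setNames(as.integer(m[b, ]),
                                           colnames(m)) else NULL)
  }
  base_seed <- if (is.null(seed)) NULL else as.integer(seed)
  out <- lapply(seq_len(nsim), function(i) {
    cfg <- synth_config(n = s$n_total,
                        sex_split = stats::setNames(as.integer(s$sex),
                                                    names(s$sex)),
                        group_targets = stats::setNames(as.integer(s$counts),
                                                        band_levels),
                        exercise_tables = as_tab(s$exercise),
                        tech_tables = as_tab(s$tech),
                        seed = if (is.null(base_seed)) NULL
                               else base_seed + i - 1L)
    generate_cohort(cfg, object$scheme)
  })
  if (nsim == 1) out[[1]] else out
}

#' Plot a fitted model's trajectory
#'
#' @param x An `mdd_model`.
#' @param t_end Horizon (days); default 50 shows the fast transient.
#' @param ... Passed to [plot.mdd_trajectory()].
#' @export
plot.mdd_model <- function(x, t_end = 50, ...) {
  plot(predict(x, t_end = t_end),
       main = "Compartment fractions under the fitted model", ...)
}
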