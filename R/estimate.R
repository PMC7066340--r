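#' Rescale compartment counts to population fractions
#'
#' @param v1,v2,m Counts in the high-vulnerability, low-vulnerability and
#'   complete-mental-health compartments.
#' @param n Total cohort size; must equal `v1 + v2 + m`.
#' @return Named numeric vector `c(x =, y =, z =)` summing to 1.
#' @examples
#' rescale_counts(88, 136, 3, 227)  # c(0.3877, 0.5991, 0.0132) to 4 dp
#' @export
rescale_counts <- function(v1, v2, m, n) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (v1 + v2 + m != n)
    stop("counts must sum to n (", v1, " + ", v2, " + ", m, " != ", n, ")",
         call. = FALSE)
  c(x = v1 / n, y = v2 / n, z = m / n)
}

#' Per-capita turnover rate from the age span
#'
#' If `1/mu` is the average time spent in the system, a span of
#' `span_years` years gives `mu = 1 / (span_years * 365)` per day. This is
#' the true arithmetic; the published analysis instead carries the value
#' [mu_canonical] (0.00342) downstream, which is an order of magnitude
#' larger than `estimate_mu(8)`.
#'
#' @param span_years Average years spent in the system (8 for ages 15--23).
#' @return Rate in /day.
#' @export
estimate_mu <- function(span_years) {
  if (!is.finite(span_years) || span_years <= 0)
    stop("span_years must be positive", call. = FALSE)
  1 / (span_years * 365)
}

#' Entry probabilities from compartment fractions
#'
#' Follows the reference procedure: each entry probability is the
#' compartment fraction divided by `mu`, then divided by 365. Applied to
#' the fractions (x, y, z) it yields (a, b, c), the probabilities of
#' entering V1, V2 and M.
#'
#' @param frac Numeric vector of compartment fractions (any length).
#' @param mu Per-capita turnover rate, /day; must be positive.
#' @return Numeric vector of probabilities, same names as `frac`.
#' @examples
#' estimate_entry_probs(c(y = 0.5991), mu = 0.00342)  # b = 0.4799
#' @export
estimate_entry_probs <- function(frac, mu) {
  if (!is.finite(mu) || mu <= 0) stop("mu must be positive", call. = FALSE)
  (frac / mu) / 365
}

#' Peer-pressure contact rate
#'
#' A contact rate is the number of qualifying contacts per day times the
#' per-contact conversion probability `1 / contacts_needed`: for the
#' positive rate delta, 5 contacts/day with 10 needed for "correction"
#' gives 0.5/day; for the negative rate epsilon, 5 contacts/day with 25
#' needed for "infection" gives 0.2/day.
#'
#' @param contacts_per_day Qualifying contacts per day.
#' @param contacts_needed Contacts needed for one conversion; positive.
#' @return Rate in /day.
#' @export
contact_rate <- function(contacts_per_day, contacts_needed) {
  if (!is.finite(contacts_needed) || contacts_needed <= 0)
    stop("contacts_needed must be positive", call. = FALSE)
  contacts_per_day * (1 / contacts_needed)
}

#' Weighted mean daily hours for a lifestyle category triple
#'
#' @param counts Numeric triple `(n_high, n_medium, n_low)` of participants
#'   per category; must sum to a positive total.
#' @param hour_weights Daily hours assigned to each category, e.g.
#'   `c(1, 0.5, 0.15)` for exercise or `c(2, 1, 0.3)` for technology use.
#' @return Weighted mean hours per day.
#' @examples
#' weighted_mean_hours(c(32, 13, 43), c(1, 0.5, 0.15))  # 0.5108
#' @export
weighted_mean_hours <- function(counts, hour_weights) {
  stopifnot(length(counts) == length(hour_weights))
  if (any(counts < 0) || any(hour_weights < 0))
    stop("counts and weights must be nonnegative", call. = FALSE)
  tot <- sum(counts)
  if (tot <= 0) stop("zero total count", call. = FALSE)
  sum(counts * hour_weights) / tot
}

#' Lifestyle transition rate from group hour means
#'
#' Averages the mean daily hours of the two groups joined by the
#' transition, multiplies by the persistence window (days of sustained
#' behaviour needed to move compartments) and divides by 24 hours:
#' `rate = mean(m1, m2) * persistence_days / 24` per day. With exercise
#' means 0.5108 and 0.5765 h and a 30-day window this gives alpha = 0.6796;
#' with technology means 0.8666 and 1.3551 h and a 15-day window,
#' beta = 0.6943.
#'
#' @param mean_hours_group1,mean_hours_group2 Mean daily hours in each
#'   group.
#' @param persistence_days Days of sustained behaviour; positive.
#' @return Rate in /day.
#' @export
lifestyle_rate <- function(mean_hours_group1, mean_hours_group2,
                           persistence_days) {
  if (!is.finite(persistence_days) || persistence_days <= 0)
    stop("persistence_days must be positive", call. = FALSE)
  if (mean_hours_group1 < 0 || mean_hours_group2 < 0)
    stop("group means must be nonnegative", call. = FALSE)
  mean(c(mean_hours_group1, mean_hours_group2)) * persistence_days / 24
}

#' Estimation configuration
#'
#' Defaults encode the reference analysis: canonical `mu` 0.00342/day,
#' peer-pressure contact assumptions (5 contacts/day; 10 needed for
#' positive correction, 25 for negative infection), category hour weights
#' (exercise 1/0.5/0.15 h, technology 2/1/0.3 h) and persistence windows
#' (30 days exercise, 15 days technology). `delta`/`epsilon` overrides, if
#' given, replace the contact-rate computation.
#'
#' @param mu Turnover rate used for entry probabilities.
#' @param delta_contacts,epsilon_contacts Length-2 vectors
#'   `(contacts_per_day, contacts_needed)`.
#' @param exercise_weights,tech_weights Hour weights for the
#'   high/medium/low categories.
#' @param exercise_persistence,tech_persistence Persistence windows, days.
#' @param delta,epsilon Optional direct overrides of the contact rates.
#' @return A list of class `est_config`.
#' @export
est_config <- function(mu = mu_canonical,
                       delta_contacts = c(5, 10),
                       epsilon_contacts = c(5, 25),
                       exercise_weights = c(high = 1, medium = 0.5, low = 0.15),
                       tech_weights = c(high = 2, medium = 1, low = 0.3),
                       exercise_persistence = 30,
                       tech_persistence = 15,
                       delta = NULL, epsilon = NULL) {
  structure(list(mu = mu, delta_contacts = delta_contacts,
                 epsilon_contacts = epsilon_contacts,
                 exercise_weights = exercise_weights,
                 tech_weights = tech_weights,
                 exercise_persistence = exercise_persistence,
                 tech_persistence = tech_persistence,
                 delta = delta, epsilon = epsilon),
            class = "est_config")
}

#' Estimate all model parameters from a cohort summary
#'
#' Composes the estimation steps: compartment fractions from band counts,
#' entry probabilities (a, b, c) from the fractions and `mu`, peer-pressure
#' rates delta and epsilon from the contact assumptions, alpha from the
#' exercise-hour means of the high- and low-vulnerability bands, and beta
#' from the technology-hour means of the complete and low-vulnerability
#' bands. All arithmetic is carried in full precision; round for display.
#'
#' @param summary A `cohort_summary` from [summarize_cohort()].
#' @param config An [est_config()].
#' @return An `mdd_parameters` vector with attributes `fractions` (x, y, z)
#'   and `hour_means` (the four weighted hour means).
#' @export
estimate_all <- function(summary, config = est_config()) {
  stopifnot(inherits(summary, "cohort_summary"))
  cts <- summary$counts
  frac <- rescale_counts(cts[["high_vuln"]], cts[["low_vuln"]],
                         cts[["complete"]], summary$n_total)
  abc <- estimate_entry_probs(frac, config$mu)

  delta <- if (!is.null(config$delta)) config$delta else
    contact_rate(config$delta_contacts[1], config$delta_contacts[2])
  epsilon <- if (!is.null(config$epsilon)) config$epsilon else
    contact_rate(config$epsilon_contacts[1], config$epsilon_contacts[2])

  need <- function(mat, band, what) {
    row <- mat[band, ]
    if (sum(row) == 0)
      stop("cannot estimate ", what, ": no participants in the '", band,
           "' band category table", call. = FALSE)
    row
  }
  hr <- weighted_mean_hours(need(summary$exercise, "high_vuln", "alpha"),
                            config$exercise_weights)
  lr <- weighted_mean_hours(need(summary$exercise, "low_vuln", "alpha"),
                            config$exercise_weights)
  cmh <- weighted_mean_hours(need(summary$tech, "complete", "beta"),
                             config$tech_weights)
  lrt <- weighted_mean_hours(need(summary$tech, "low_vuln", "beta"),
                             config$tech_weights)

  p <- model_parameters(mu = config$mu,
                        a = abc[["x"]], b = abc[["y"]], c = abc[["z"]],
                        delta = delta, epsilon = epsilon,
                        alpha = lifestyle_rate(hr, lr, config$exercise_persistence),
                        beta = lifestyle_rate(cmh, lrt, config$tech_persistence))
  attr(p, "fractions") <- frac
  attr(p, "hour_means") <- c(exercise_high_band = hr, exercise_low_band = lr,
                             tech_complete_band = cmh, tech_low_band = lrt)
  p
}
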