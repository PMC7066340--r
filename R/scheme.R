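#' Default scoring scheme for vulnerability stratification
#'
#' Builds the scheme that converts subjective well-being (SWB, measured by
#' the Satisfaction With Life Scale, totals 5--35) and Trait Meta-Mood Scale
#' subscale scores (EQ-Attention, EQ-Clarity, EQ-Repair, totals 8--40 each)
#' into per-variable levels (low / adequate / high), and totals into the
#' three vulnerability bands.
#'
#' Thresholds are sex-specific for EQ-A and EQ-C and sex-invariant for SWB
#' and EQ-R. The middle SWB level is the single score 15 (labelled
#' "Neutral" on the instrument; the canonical level name here is
#' `"adequate"` for all four variables).
#'
#' `level_scores` assigns representative points to each (variable, level)
#' pair so that level 4-tuples can be totalled: the default takes the
#' midpoint of each male-threshold level range (open-ended ranges capped at
#' the instrument bounds) and rescales each variable affinely so the all-low
#' state totals 80 and the all-high state totals 140. The map is
#' user-configurable; see [read_scoring_scheme()].
#'
#' Band cutoffs on the total: above 120 is complete mental health, 100--120
#' inclusive is low vulnerability, below 100 is high vulnerability.
#'
#' @return An object of class `scoring_scheme`: a list with `thresholds`
#'   (per variable and sex: `low_max`, `adq_min`, `adq_max`, `high_min`),
#'   `instrument_bounds`, `level_scores` (4 x 3 matrix, variables x
#'   `low`/`adequate`/`high`) and `band_cutoffs`.
#' @seealso [assign_level()], [enumerate_states()], [classify_total()]
#' @export
default_scheme <- function() {
  thr <- function(low_max, adq_max, ...) {
    c(low_max = low_max, adq_min = low_max + 1L,
      adq_max = adq_max, high_min = adq_max + 1L)
  }
  thresholds <- list(
    swb = list(male = thr(14L, 15L), female = thr(14L, 15L)),
    eqa = list(male = thr(21L, 32L), female = thr(24L, 35L)),
    eqc = list(male = thr(25L, 35L), female = thr(23L, 34L)),
    eqr = list(male = thr(23L, 34L), female = thr(23L, 34L))
  )
  instrument_bounds <- list(swb = c(5L, 35L), eqa = c(8L, 40L),
                            eqc = c(8L, 40L), eqr = c(8L, 40L))
  level_scores <- t(vapply(names(thresholds), function(v) {
    tm <- thresholds[[v]]$male
    b <- instrument_bounds[[v]]
    mids <- c(mean(c(b[1], tm["low_max"])),
              mean(c(tm["adq_min"], tm["adq_max"])),
              mean(c(tm["high_min"], b[2])))
    # affine map per variable: low -> 20, high -> 35, so the all-low state
    # totals 80 and the all-high state totals 140
    20 + 15 * (mids - mids[1]) / (mids[3] - mids[1])
  }, numeric(3)))
  colnames(level_scores) <- c("low", "adequate", "high")
  structure(
    list(thresholds = thresholds,
         instrument_bounds = instrument_bounds,
         level_scores = level_scores,
         band_cutoffs = list(low_range = c(100, 120), complete_min = 120)),
    class = "scoring_scheme")
}

#' Read a scoring scheme from a YAML or JSON file
#'
#' Missing top-level keys fall back to the defaults of [default_scheme()].
#' The file may carry `thresholds`, `instrument_bounds`, `level_scores`
#' (named lists per variable) and `band_cutoffs`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` scheme file.
#' @return A `scoring_scheme` object.
#' @export
read_scoring_scheme <- function(path) {
  stopifnot(file.exists(path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  sch <- default_scheme()
  if (!is.null(raw$thresholds)) {
    for (v in names(raw$thresholds)) for (s in names(raw$thresholds[[v]])) {
      val <- unlist(raw$thresholds[[v]][[s]])
      sch$thresholds[[v]][[s]][names(val)] <- as.integer(val)
    }
  }
  if (!is.null(raw$instrument_bounds)) {
    for (v in names(raw$instrument_bounds))
      sch$instrument_bounds[[v]] <- as.integer(unlist(raw$instrument_bounds[[v]]))
  }
  if (!is.null(raw$level_scores)) {
    for (v in names(raw$level_scores)) {
      val <- unlist(raw$level_scores[[v]])
      sch$level_scores[v, names(val)] <- as.numeric(val)
    }
  }
  if (!is.null(raw$band_cutoffs)) {
    bc <- raw$band_cutoffs
    if (!is.null(bc$low_range)) sch$band_cutoffs$low_range <- as.numeric(unlist(bc$low_range))
    if (!is.null(bc$complete_min)) sch$band_cutoffs$complete_min <- as.numeric(bc$complete_min)
  }
  validate_scheme(sch)
}

# Enforce the structural invariants: each (variable, sex) level triple
# partitions the integer score axis, and level scores are strictly
# increasing with all-low summing to 80 and all-high to 140.
validate_scheme <- function(scheme) {
  for (v in names(scheme$thresholds)) for (s in c("male", "female")) {
    t <- scheme$thresholds[[v]][[s]]
    if (t["adq_min"] != t["low_max"] + 1L || t["high_min"] != t["adq_max"] + 1L)
      stop("scoring scheme: levels for ", v, "/", s,
           " do not partition the score axis", call. = FALSE)
  }
  ls <- scheme$level_scores
  if (any(ls[, "low"] >= ls[, "adequate"]) || any(ls[, "adequate"] >= ls[, "high"]))
    stop("scoring scheme: level_scores must increase low < adequate < high",
         call. = FALSE)
  if (abs(sum(ls[, "low"]) - 80) > 1e-8 || abs(sum(ls[, "high"]) - 140) > 1e-8)
    stop("scoring scheme: all-low total must be 80 and all-high total 140",
         call. = FALSE)
  scheme
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat("Vulnerability scoring scheme\n")
  cat("  variables:", paste(toupper(names(x$thresholds)), collapse = ", "), "\n")
  cat("  level scores (representative points):\n")
  print(round(x$level_scores, 2))
  bc <- x$band_cutoffs
  cat(sprintf("  bands: total > %g complete; [%g, %g] low vulnerability; < %g high vulnerability\n",
              bc$complete_min, bc$low_range[1], bc$low_range[2], bc$low_range[1]))
  invisible(x)
}

#' Assign a level to one questionnaire score
#'
#' Maps an integer subscale score to `"low"`, `"adequate"` or `"high"`
#' using the sex-appropriate thresholds. The three level intervals
#' partition the integer score axis, so exactly one level is returned.
#'
#' @param variable One of `"swb"`, `"eqa"`, `"eqc"`, `"eqr"`
#'   (case-insensitive).
#' @param score Nonnegative integer score (non-integers are rejected, not
#'   rounded).
#' @param sex `"male"` or `"female"`.
#' @param scheme A `scoring_scheme`; defaults to [default_scheme()].
#' @return A character scalar: `"low"`, `"adequate"` or `"high"`.
#' @examples
#' assign_level("swb", 16, "male")   # "high"
#' assign_level("eqa", 22, "male")   # "adequate"
#' @export
assign_level <- function(variable, score, sex, scheme = default_scheme()) {
  variable <- tolower(variable)
  if (!variable %in% names(scheme$thresholds))
    stop("unknown variable: ", variable, call. = FALSE)
  if (!sex %in% c("male", "female"))
    stop("unknown sex: ", sex, call. = FALSE)
  if (length(score) != 1L || !is.numeric(score) || is.na(score) ||
      score != round(score) || score < 0)
    stop("score must be a single nonnegative integer", call. = FALSE)
  t <- scheme$thresholds[[variable]][[sex]]
  if (score <= t["low_max"]) "low"
  else if (score <= t["adq_max"]) "adequate"
  else "high"
}

#' Enumerate the 81 superposed vulnerability states
#'
#' Forms every combination of the three levels across the four variables
#' (3^4 = 81 states), totals each state with the scheme's representative
#' level scores, and assigns each total to a vulnerability band.
#'
#' @param scheme A `scoring_scheme`.
#' @return A data frame with 81 rows and columns `state` (e.g. `"L.A.H.H"`
#'   for SWB low, EQ-A adequate, EQ-C high, EQ-R high), `swb`, `eqa`,
#'   `eqc`, `eqr` (levels), `total` and `band`.
#' @export
enumerate_states <- function(scheme = default_scheme()) {
  lev <- c("low", "adequate", "high")
  grid <- expand.grid(swb = lev, eqa = lev, eqc = lev, eqr = lev,
                      stringsAsFactors = FALSE)
  vars <- c("swb", "eqa", "eqc", "eqr")
  total <- rowSums(vapply(vars, function(v)
    scheme$level_scores[v, grid[[v]]], numeric(nrow(grid))))
  band <- vapply(total, classify_total, character(1), scheme = scheme)
  state <- apply(grid, 1, function(r)
    paste(toupper(substr(r, 1, 1)), collapse = "."))
  data.frame(state = state, grid, total = total, band = band,
             stringsAsFactors = FALSE)
}

#' Classify a state total into a vulnerability band
#'
#' Totals above 120 are complete mental health, totals in the inclusive
#' interval 100--120 are low vulnerability, and totals below 100 are high
#' vulnerability (cutoffs configurable through the scheme). Totals outside
#' the attainable range 80--140 are still classified by the same rule, with
#' a warning.
#'
#' @param total State total in points.
#' @param scheme A `scoring_scheme`.
#' @return `"complete"`, `"low_vuln"` or `"high_vuln"`.
#' @export
classify_total <- function(total, scheme = default_scheme()) {
  stopifnot(length(total) == 1L, is.finite(total))
  if (total < 80 || total > 140)
    warning("total ", total, " outside the attainable range [80, 140]",
            call. = FALSE)
  bc <- scheme$band_cutoffs
  if (total > bc$complete_min) "complete"
  else if (total >= bc$low_range[1]) "low_vuln"
  else "high_vuln"
}

#' Classify one participant into a superposed state and band
#'
#' Assigns a level to each of the four scores with the sex-appropriate
#' thresholds, totals the resulting state with the scheme's level scores,
#' and bands the total.
#'
#' @param rec A list or one-row data frame with at least `sex`, `swb`,
#'   `eqa`, `eqc`, `eqr`.
#' @param scheme A `scoring_scheme`.
#' @return A list with `state` (label), `levels` (named character vector),
#'   `total` and `band`.
#' @export
classify_participant <- function(rec, scheme = default_scheme()) {
  vars <- c("swb", "eqa", "eqc", "eqr")
  levels <- vapply(vars, function(v)
    assign_level(v, as.numeric(rec[[v]]), as.character(rec[["sex"]]), scheme),
    character(1))
  total <- sum(scheme$level_scores[cbind(vars, levels)])
  list(state = paste(toupper(substr(levels, 1, 1)), collapse = "."),
       levels = levels, total = total,
       band = classify_total(total, scheme))
}

#' Classify a whole cohort
#'
#' @param cohort Data frame of participant records (see [read_cohort()]).
#' @param scheme A `scoring_scheme`.
#' @return Data frame `id`, `band`, `total`, `state`, one row per record.
#' @export
classify_cohort <- function(cohort, scheme = default_scheme()) {
  stopifnot(is.data.frame(cohort), nrow(cohort) > 0)
  res <- lapply(seq_len(nrow(cohort)), function(i)
    classify_participant(cohort[i, ], scheme))
  data.frame(id = as.character(cohort$id),
             band = vapply(res, `[[`, character(1), "band"),
             total = vapply(res, `[[`, numeric(1), "total"),
             state = vapply(res, `[[`, character(1), "state"),
             stringsAsFactors = FALSE)
}

band_levels <- c("high_vuln", "low_vuln", "complete")
cat3_levels <- c(exercise = "high,medium,low", tech = "high,medium,low")

#' Summarize a cohort into band and lifestyle-category counts
#'
#' Produces the counts that drive parameter estimation: participants per
#' vulnerability band, and within each band the distribution over daily
#' physical-exercise and technology-use categories, plus sex counts.
#'
#' @param cohort Data frame of participant records with `sex`, the four
#'   scores, `exercise_cat` and `tech_cat` (`"high"`/`"medium"`/`"low"`).
#' @param scheme A `scoring_scheme`.
#' @return An object of class `cohort_summary`: list with `n_total`,
#'   `counts` (named vector over `high_vuln`, `low_vuln`, `complete`),
#'   `exercise` and `tech` (3 x 3 count matrices, bands x categories) and
#'   `sex` counts.
#' @export
summarize_cohort <- function(cohort, scheme = default_scheme()) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0)
    stop("cohort must be a nonempty data frame", call. = FALSE)
  cls <- classify_cohort(cohort, scheme)
  band <- factor(cls$band, levels = band_levels)
  cat_table <- function(col) {
    cat <- factor(cohort[[col]], levels = c("high", "medium", "low"))
    as.matrix(table(band, cat))
  }
  structure(
    list(n_total = nrow(cohort),
         counts = table(band),
         exercise = cat_table("exercise_cat"),
         tech = cat_table("tech_cat"),
         sex = table(factor(cohort$sex, levels = c("female", "male")))),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary: n =", x$n_total, "\n")
  cat(sprintf("  high vulnerability (V1): %d\n  low vulnerability  (V2): %d\n  complete mental health (M): %d\n",
              x$counts[["high_vuln"]], x$counts[["low_vuln"]], x$counts[["complete"]]))
  cat("  sex: ", x$sex[["female"]], "female /", x$sex[["male"]], "male\n")
  cat("  exercise categories by band:\n"); print(x$exercise)
  cat("  technology-use categories by band:\n"); print(x$tech)
  invisible(x)
}

#' Read a cohort CSV
#'
#' Expects the header
#' `id,sex,age,swb,eqa,eqc,eqr,exercise_cat,tech_cat,social_cat`
#' (`social_cat` optional), UTF-8, lowercase category strings. Records are
#' validated: sex in male/female, age in \[15, 23\], nonnegative integer
#' scores, known categories.
#'
#' @param path Path to the CSV file.
#' @return A validated data frame of participant records.
#' @export
read_cohort <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(df)
}

validate_cohort <- function(df) {
  need <- c("id", "sex", "age", "swb", "eqa", "eqc", "eqr",
            "exercise_cat", "tech_cat")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("cohort missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!all(df$sex %in% c("male", "female")))
    stop("cohort: sex must be 'male' or 'female'", call. = FALSE)
  if (any(df$age < 15 | df$age > 23))
    stop("cohort: ages must lie in [15, 23]", call. = FALSE)
  for (v in c("swb", "eqa", "eqc", "eqr")) {
    s <- df[[v]]
    if (any(!is.finite(s) | s < 0 | s != round(s)))
      stop("cohort: ", v, " scores must be nonnegative integers", call. = FALSE)
  }
  if (!all(df$exercise_cat %in% c("high", "medium", "low")))
    stop("cohort: exercise_cat must be high/medium/low", call. = FALSE)
  if (!all(df$tech_cat %in% c("high", "medium", "low")))
    stop("cohort: tech_cat must be high/medium/low", call. = FALSE)
  df
}
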