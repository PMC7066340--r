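test_that("assign_level reproduces the published threshold table", {
  cases <- list(
    list("swb", 16, "male", "high"),
    list("eqa", 22, "male", "adequate"),
    list("swb", 15, "female", "adequate"),  # the instrument's "Neutral"
    list("eqr", 23, "female", "low"),
    list("eqa", 33, "male", "high"),
    list("eqa", 35, "female", "adequate"),
    list("eqa", 24, "female", "low"),       # repaired female EQ-A low bound
    list("eqc", 26, "male", "adequate"),
    list("eqc", 35, "female", "high"),
    list("swb", 14, "female", "low"))
  for (cs in cases)
    expect_identical(assign_level(cs[[1]], cs[[2]], cs[[3]]), cs[[4]],
                     label = paste(cs[[1]], cs[[2]], cs[[3]]))
})

test_that("levels partition every integer score exhaustively and exclusively", {
  sch <- default_scheme()
  for (v in c("swb", "eqa", "eqc", "eqr")) for (sx in c("male", "female")) {
    b <- sch$instrument_bounds[[v]]
    lev <- vapply(seq(b[1], b[2]), function(s) assign_level(v, s, sx, sch),
                  character(1))
    expect_true(all(lev %in% c("low", "adequate", "high")))
    # monotone non-decreasing in score: low block, adequate block, high block
    expect_true(all(diff(match(lev, c("low", "adequate", "high"))) >= 0),
                label = paste(v, sx))
    expect_setequal(unique(lev), c("low", "adequate", "high"))
  }
  expect_error(assign_level("xyz", 10, "male"), "unknown variable")
  expect_error(assign_level("swb", 10, "other"), "unknown sex")
  expect_error(assign_level("swb", 10.5, "male"), "integer")
})

test_that("enumerate_states yields 81 distinct states spanning totals 80 to 140", {
  st <- enumerate_states()
  expect_equal(nrow(st), 81)
  expect_equal(length(unique(st$state)), 81)
  expect_equal(min(st$total), 80)
  expect_equal(max(st$total), 140)
  all_low <- st[st$swb == "low" & st$eqa == "low" & st$eqc == "low" &
                  st$eqr == "low", ]
  all_high <- st[st$swb == "high" & st$eqa == "high" & st$eqc == "high" &
                   st$eqr == "high", ]
  expect_equal(all_low$total, 80)
  expect_equal(all_high$total, 140)
  expect_equal(sum(table(st$band)), 81)
})

test_that("classify_total applies the band cutoffs with inclusive 100-120", {
  expect_identical(classify_total(125), "complete")
  expect_identical(classify_total(95), "high_vuln")
  expect_identical(classify_total(120), "low_vuln")
  expect_identical(classify_total(100), "low_vuln")
  expect_identical(classify_total(120.5), "complete")
  expect_identical(classify_total(99.99), "high_vuln")
  expect_warning(v <- classify_total(150), "outside")
  expect_identical(v, "complete")
})

test_that("classify_total is monotone: higher totals never more vulnerable", {
  rank <- c(high_vuln = 1, low_vuln = 2, complete = 3)
  totals <- seq(80, 140, by = 0.5)
  bands <- rank[vapply(totals, classify_total, character(1))]
  expect_true(all(diff(bands) >= 0))
})

test_that("classify_participant composes levels, total and band", {
  sch <- default_scheme()
  hi <- classify_participant(
    list(sex = "male", swb = 16, eqa = 33, eqc = 36, eqr = 35), sch)
  expect_equal(unname(hi$levels), rep("high", 4))
  expect_equal(hi$total, 140)
  expect_identical(hi$band, "complete")

  lo <- classify_participant(
    list(sex = "male", swb = 14, eqa = 21, eqc = 25, eqr = 23), sch)
  expect_equal(unname(lo$levels), rep("low", 4))
  expect_equal(lo$total, 80)
  expect_identical(lo$band, "high_vuln")

  # female all scores in adequate ranges: band follows from level_scores
  mid <- classify_participant(
    list(sex = "female", swb = 15, eqa = 30, eqc = 30, eqr = 30), sch)
  expect_equal(unname(mid$levels), rep("adequate", 4))
  expect_equal(mid$total, sum(sch$level_scores[, "adequate"]))
  expect_identical(mid$band, classify_total(mid$total, sch))
})

test_that("summarize_cohort counts the fixture and is permutation-invariant", {
  co <- reference_cohort()
  s <- summarize_cohort(co)
  expect_equal(unname(as.integer(s$counts)), c(88, 136, 3))
  expect_equal(unname(s$exercise["high_vuln", ]), c(32, 13, 43))
  perm <- co[sample.int(nrow(co)), ]
  s2 <- summarize_cohort(perm)
  expect_equal(s2$counts, s$counts)
  expect_equal(s2$exercise, s$exercise)
  expect_equal(s2$tech, s$tech)
  # per-band category triples sum to the band counts
  expect_equal(unname(rowSums(s$exercise)), unname(as.integer(s$counts)))
  expect_equal(unname(rowSums(s$tech)), unname(as.integer(s$counts)))
  expect_error(summarize_cohort(co[0, ]), "nonempty")

  one <- summarize_cohort(co[1, ])
  expect_equal(sum(one$counts), 1)
  expect_equal(max(one$counts), 1)
})

test_that("the shipped scheme file round-trips to the in-code default", {
  path <- system.file("extdata", "default_scheme.yaml", package = "mddvuln")
  sch <- read_scoring_scheme(path)
  def <- default_scheme()
  expect_equal(sch$thresholds, def$thresholds)
  expect_equal(sch$level_scores, def$level_scores, tolerance = 1e-12)
  expect_equal(sch$band_cutoffs, def$band_cutoffs)
})

test_that("cohort validation rejects malformed records", {
  co <- reference_cohort()
  bad <- co; bad$age[1] <- 30
  expect_error(validate_cohort(bad), "age")
  bad <- co; bad$swb[1] <- 10.4
  expect_error(validate_cohort(bad), "integer")
  bad <- co; bad$sex[1] <- "unknown"
  expect_error(validate_cohort(bad), "sex")
  bad <- co; bad$exercise_cat[1] <- "sometimes"
  expect_error(validate_cohort(bad), "exercise_cat")
  expect_error(validate_cohort(co[, -3]), "missing columns")
})
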