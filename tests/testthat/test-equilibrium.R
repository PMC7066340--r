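# Independent oracle: re-evaluate each printed cubic coefficient monomial
# by monomial.
oracle_coefs <- function(p) {
  mu <- p[["mu"]]; a <- p[["a"]]; cc <- p[["c"]]; d <- p[["delta"]]
  e <- p[["epsilon"]]; al <- p[["alpha"]]; be <- p[["beta"]]
  terms_B <- c(mu * d, e * d, e * be, al * d, mu * e)
  terms_C <- c(mu * d, -a * mu * d, mu * mu, mu * be, e * mu, e * be,
               al * d, al * mu, al * be, -cc * e * mu)
  terms_D <- c(a * mu * mu, a * mu * be, -mu * mu, -mu * be, -al * mu,
               -al * be, cc * mu * mu, cc * mu * al)
  c(A = e * d, B = -sum(terms_B), C = sum(terms_C), D = sum(terms_D))
}

test_that("cubic coefficients match term-by-term re-evaluation", {
  expect_equal(cubic_coefficients(ref_params), oracle_coefs(ref_params),
               tolerance = 1e-12)
  p0 <- model_parameters(0, 0, 0, 0, 0, 0, 0, 0)
  expect_equal(unname(cubic_coefficients(p0)), c(0, 0, 0, 0))
  p <- ref_params
  expect_equal(cubic_coefficients(p)[["A"]],
               p[["epsilon"]] * p[["delta"]])
  set.seed(21)
  for (i in 1:50) {
    q <- random_params()
    expect_equal(cubic_coefficients(q), oracle_coefs(q), tolerance = 1e-12)
  }
})

test_that("vieta recovers the symmetric functions of known roots", {
  # (y-1)(y-2)(y-3) = y^3 - 6y^2 + 11y - 6
  v <- vieta(c(A = 1, B = -6, C = 11, D = -6))
  expect_equal(unname(v), c(6, 11, 6))
  expect_equal(unname(vieta(c(A = 1, B = 0, C = 0, D = 0))), c(0, 0, 0))
  expect_error(vieta(c(A = 0, B = 1, C = 1, D = 1)), "degenerate")
})

test_that("vieta agrees with symmetric functions of numerically found roots", {
  set.seed(22)
  for (i in 1:30) {
    p <- random_params()
    co <- cubic_coefficients(p)
    if (co[["A"]] == 0) next
    r <- polyroot(rev(unname(co)))  # independent root-finder oracle
    v <- vieta(co)
    expect_equal(v[["S1"]], Re(sum(r)), tolerance = 1e-8)
    expect_equal(v[["S2"]], Re(r[1] * r[2] + r[1] * r[3] + r[2] * r[3]),
                 tolerance = 1e-8)
    expect_equal(v[["P"]], Re(prod(r)), tolerance = 1e-8)
  }
})

test_that("positivity conditions equal sign checks on the Vieta sums", {
  pc <- positivity_conditions(ref_params)
  expect_true(pc[["S1_pos"]])  # sum of positive rate products
  set.seed(23)
  for (i in 1:50) {
    p <- random_params()
    if (p[["epsilon"]] * p[["delta"]] == 0) next
    expect_equal(unname(positivity_conditions(p)),
                 unname(vieta(cubic_coefficients(p)) > 0))
  }
  # all rates zero except epsilon = delta = 1: the S1 numerator reduces to
  # epsilon*delta = 1 (> 0) while S2 and P collapse to zero sums, which
  # fail the strict inequality
  degen <- model_parameters(0, 0, 0, 0, 1, 1, 0, 0)
  expect_equal(unname(positivity_conditions(degen)), c(TRUE, FALSE, FALSE))
  expect_error(positivity_conditions(model_parameters(1, 0, 0, 0, 0, 1, 0, 0)),
               "degenerate")
})

test_that("equilibrium cubic roots have tiny residuals and known factorizations", {
  r <- mddvuln:::solve_cubic(c(1, -6, 11, -6))
  expect_equal(r, c(1, 2, 3), tolerance = 1e-9)

  sol <- solve_equilibrium_y(ref_params)
  co <- cubic_coefficients(ref_params)
  scale <- max(1, abs(co))
  expect_true(all(abs(sol$residual) < 1e-9 * scale))
  expect_true(all(diff(sol$root) >= 0))
  expect_equal(sol$admissible, sol$root >= 0 & sol$root <= 1)
  set.seed(24)
  for (i in 1:30) {
    p <- random_params()
    co <- cubic_coefficients(p)
    if (co[["A"]] == 0) next
    sol <- solve_equilibrium_y(p)
    expect_true(all(abs(sol$residual) < 1e-9 * max(1, abs(co))))
  }
})

test_that("degenerate cubics fall back to lower degree with a warning", {
  p <- model_parameters(0.1, 0.2, 0.5, 0.3, 0.5, 0, 0.4, 0.3)  # epsilon = 0
  expect_warning(sol <- solve_equilibrium_y(p), "degenerate")
  co <- cubic_coefficients(p)
  for (r in sol$root)
    expect_lt(abs(co[["B"]] * r^2 + co[["C"]] * r + co[["D"]]), 1e-9)
})

test_that("equilibrium_z back-substitution matches hand evaluation", {
  p <- ref_params
  expect_equal(equilibrium_z(0.5, p),
               p[["c"]] * p[["mu"]] / (0.69752 - 0.25), tolerance = 1e-9)
  pz <- p; pz[["c"]] <- 0
  expect_equal(equilibrium_z(0.3, pz), 0)
  pd <- p; pd[["delta"]] <- 0
  expect_equal(equilibrium_z(0.9, pd),
               p[["c"]] * p[["mu"]] / (p[["beta"]] + p[["mu"]]))
  y_sing <- (p[["beta"]] + p[["mu"]]) / p[["delta"]]
  expect_error(equilibrium_z(y_sing, p), "singular")
})

test_that("jacobian_dfe matches the printed matrix and finite differences", {
  p <- ref_params
  J <- jacobian_dfe(p)
  expect_equal(J[1, 1], -(p[["mu"]] + p[["alpha"]]))
  expect_equal(J, rbind(c(-p[["mu"]] - p[["alpha"]], 0, 0),
                        c(p[["alpha"]], -p[["mu"]] - p[["delta"]], p[["beta"]]),
                        c(0, p[["delta"]], -p[["mu"]] - p[["beta"]])))
  expect_equal(jacobian_dfe(model_parameters(0, 0, 0, 0, 0, 0, 0, 0)),
               matrix(0, 3, 3))
  # finite-difference oracle on the dynamics module at (0, 0, 1)
  h <- 1e-6
  s0 <- c(0, 0, 1)
  num <- sapply(1:3, function(j) {
    e <- numeric(3); e[j] <- h
    (derivatives(s0 + e, p) - derivatives(s0 - e, p)) / (2 * h)
  })
  expect_equal(unname(J), unname(num), tolerance = 1e-5)
})

test_that("stability report carries closed-form eigenvalues and both R0 forms", {
  triv <- stability_analysis(model_parameters(1, 0, 0, 0, 0, 1e-9, 0, 0))
  expect_equal(unname(triv$eigenvalues), c(-1, -1, -1))
  expect_true(triv$stable)

  rep <- stability_analysis(ref_params)
  expect_equal(rep$eigenvalues[["lambda2"]], -0.00342)
  expect_true(all(rep$eigenvalues < 0))
  expect_true(rep$stable)
  expect_equal(rep$r0_literal,
               -0.00342 + 0.6941 + 0.5, tolerance = 1e-12)
  expect_gt(rep$r0_literal, 1)
  expect_equal(rep$r0_bound, 0.5 * (0.00342 + 0.6796) / 0.2)
  expect_true(any(grepl("inconsistency", rep$notes)))
  # numeric eigensolver agrees with the closed forms
  expect_equal(sort(Re(rep$eigenvalues_numeric)),
               sort(unname(rep$eigenvalues)), tolerance = 1e-10)

  noeps <- stability_analysis(model_parameters(0.1, 0.1, 0.1, 0.1,
                                               0.5, 0, 0.4, 0.3))
  expect_true(is.na(noeps$r0_bound))
  expect_true(any(grepl("epsilon = 0", noeps$notes)))
})

test_that("closed-form eigenvalues match numeric ones over random draws", {
  set.seed(25)
  for (i in 1:300) {
    p <- random_params()
    closed <- c(-(p[["mu"]] + p[["alpha"]]), -p[["mu"]],
                -(p[["mu"]] + p[["beta"]] + p[["delta"]]))
    num <- eigen(jacobian_dfe(p), only.values = TRUE)$values
    expect_lt(max(abs(Im(num))), 1e-10)
    expect_equal(sort(Re(num)), sort(closed), tolerance = 1e-10)
  }
})

test_that("the DFE is stable for every strictly positive parameter vector", {
  set.seed(26)
  for (i in 1:200) {
    p <- random_params()  # mu > 0 by construction
    expect_true(stability_analysis(p)$stable)
  }
})
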