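# Rate-law identities, limits, and the closed-form double-reciprocal
# coefficients against a brute-force regression oracle.

test_that("Michaelis-Menten law satisfies half-saturation and boundary identities", {
  p <- kinetic_params(V = 1, KM = 0.1)
  expect_equal(rate_mm(0.1, p), 0.5)
  expect_equal(rate_mm(0, p), 0)
  # half-saturation at the NAD+ apparent constants: v = kcat*E0/2
  p_nad <- kinetic_params(kcat = 17.7, E0 = 1e-6, KM = 0.081)
  expect_equal(rate_mm(0.081, p_nad), 8.85e-6)
  # saturation limit
  expect_equal(rate_mm(1e9, p), 1, tolerance = 1e-8)
})

test_that("kinetic_params enforces positivity and the V = kcat*E0 link", {
  expect_error(kinetic_params(V = -1, KM = 0.1), "positive")
  expect_error(kinetic_params(V = 1, KM = 0), "positive")
  expect_error(kinetic_params(kcat = 2, KM = 0.1), "E0")
  expect_error(kinetic_params(V = 3, kcat = 2, E0 = 1, KM = 0.1),
               "kcat \\* E0")
  expect_equal(kinetic_params(kcat = 2, E0 = 0.5, KM = 0.1)$V, 1)
  expect_error(rate_mm(-0.1, kinetic_params(V = 1, KM = 0.1)))
})

test_that("substrate-inhibition law peaks at sqrt(KM*Ksi) and nests plain MM", {
  p <- kinetic_params(V = 1, KM = 0.1, Ksi = 1.0)
  Speak <- sqrt(p$KM * p$Ksi)
  # closed-form peak value 1/(1 + 2*sqrt(KM/Ksi))
  expect_equal(rate_mm_substrate_inhibition(Speak, p),
               1 / (1 + 2 * sqrt(p$KM / p$Ksi)), tolerance = 1e-12)
  expect_equal(rate_mm_substrate_inhibition(0, p), 0)
  # peak is a maximum
  eps <- 1e-4
  expect_gt(rate_mm_substrate_inhibition(Speak, p),
            rate_mm_substrate_inhibition(Speak - eps, p))
  expect_gt(rate_mm_substrate_inhibition(Speak, p),
            rate_mm_substrate_inhibition(Speak + eps, p))
  # Ksi -> Inf limit recovers MM; finite Ksi is strictly below MM
  p_inf <- kinetic_params(V = 1, KM = 0.1, Ksi = 1e12)
  S <- c(0.01, 0.1, 1, 10)
  expect_equal(rate_mm_substrate_inhibition(S, p_inf),
               rate_mm(S, kinetic_params(V = 1, KM = 0.1)),
               tolerance = 1e-9)
  expect_true(all(rate_mm_substrate_inhibition(S, p) <
                  rate_mm(S, kinetic_params(V = 1, KM = 0.1))))
})

test_that("Bi-Bi laws reproduce symmetric points, limits and hand-evaluated values", {
  # ping-pong
  pp <- kinetic_params(V = 1, Ka = 0.05, Kb = 0.13)
  expect_equal(rate_ping_pong(0.05, 0.13, pp), 1 / 3)
  expect_equal(rate_ping_pong(0.2, 1e9, pp), 1 * 0.2 / (0.05 + 0.2),
               tolerance = 1e-8)
  pp2 <- kinetic_params(V = 17.8, Ka = 0.05, Kb = 0.13)
  expect_equal(rate_ping_pong(0.25, 0.125, pp2),
               17.8 * 0.25 * 0.125 / (0.13 * 0.25 + 0.05 * 0.125 + 0.25 * 0.125))
  # ordered steady-state
  oss <- kinetic_params(V = 1, Ka = 0.05, Kb = 0.13, Kia = 0.05)
  expect_equal(rate_ordered_ss(0.1, 0.1, oss),
               1 * 0.01 / (0.05 * 0.13 + 0.05 * 0.1 + 0.13 * 0.1 + 0.01))
  expect_equal(rate_ordered_ss(1e9, 0.1, oss), 0.1 / (0.13 + 0.1),
               tolerance = 1e-8)
  # Ka -> 0 nests rapid equilibrium ordered
  oss0 <- kinetic_params(V = 1, Ka = 1e-12, Kb = 0.13, Kia = 0.05)
  reo <- kinetic_params(V = 1, Kb = 0.13, Kia = 0.05)
  A <- c(0.05, 0.1, 0.25); B <- c(0.0125, 0.05, 0.25)
  expect_equal(rate_ordered_ss(A, B, oss0), rate_req_ordered(A, B, reo),
               tolerance = 1e-9)
  # rapid equilibrium ordered
  reo2 <- kinetic_params(V = 1, Kia = 0.05, Kb = 0.13)
  expect_equal(rate_req_ordered(0.05, 0.13, reo2), 1 / 3)
  expect_equal(rate_req_ordered(0.01, 1e12, reo2), 1, tolerance = 1e-8)
  reo3 <- kinetic_params(V = 17.8, Kia = 0.05, Kb = 0.13)
  expect_equal(rate_req_ordered(0.25, 0.125, reo3),
               17.8 * 0.25 * 0.125 / (0.05 * 0.13 + 0.13 * 0.25 + 0.25 * 0.125))
  expect_equal(rate_req_ordered(0.25, 0.125, reo3), 7.9181, tolerance = 1e-4)
  # rapid equilibrium random
  rer <- kinetic_params(V = 1, Ka = 0.05, Kb = 0.13, alpha = 1)
  expect_equal(rate_req_random(0.05, 0.13, rer), 1 / 4)
  expect_equal(rate_req_random(0.1, 0.26, rer), 4 / 9)
  rer_big <- kinetic_params(V = 1, Ka = 0.05, Kb = 0.13, alpha = 1e12)
  expect_lt(rate_req_random(0.1, 0.1, rer_big), 1e-6)
})

test_that("rate laws are bounded by V and monotone in each substrate", {
  set.seed(101)
  for (nm in BIBI_MODELS) {
    q <- draw_params()
    p <- params_for(nm, q)
    m <- mechanism_model(nm)
    A <- sort(stats::runif(8, 0.005, 0.5))
    B <- sort(stats::runif(8, 0.005, 0.5))
    for (b in B) {
      v <- rate_law(m, A, b, p)
      expect_true(all(v >= 0 & v <= q$V))
      expect_true(all(diff(v) > 0))  # increasing in A
    }
    for (a in A) {
      v <- rate_law(m, a, B, p)
      expect_true(all(diff(v) > 0))  # increasing in B
    }
  }
})

test_that("model descriptors declare required parameters and reject misuse", {
  expect_equal(required_params("RAPID_EQ_ORDERED"), c("V", "Kb", "Kia"))
  expect_error(mechanism_model("NOT_A_MODEL"))
  # missing required parameter rejected
  expect_error(rate_req_ordered(0.1, 0.1, kinetic_params(V = 1, Kb = 0.1)),
               "Kia")
  expect_error(
    reciprocal_coefficients(mechanism_model("MM_SUBSTRATE_INHIBITION"),
                            kinetic_params(V = 1, KM = 0.1, Ksi = 1),
                            "A", 0.1),
    "no linear")
})

test_that("reciprocal coefficients match brute-force regression of exact reciprocal rates", {
  # oracle: regress 1/v on 1/[varied] at each fixed level; the closed forms
  # must reproduce the regression coefficients exactly (R^2 = 1)
  set.seed(202)
  varied_levels <- c(0.02, 0.05, 0.1, 0.2, 0.5)
  for (i in 1:100) {
    nm <- sample(BIBI_MODELS, 1)
    q <- draw_params()
    p <- params_for(nm, q)
    m <- mechanism_model(nm)
    varied <- sample(c("A", "B"), 1)
    f <- stats::runif(1, 0.02, 0.5)
    v <- if (varied == "A") rate_law(m, varied_levels, f, p)
         else rate_law(m, f, varied_levels, p)
    line <- stats::lm(y ~ x, data.frame(x = 1 / varied_levels, y = 1 / v))
    cf <- reciprocal_coefficients(m, p, varied, f)
    expect_equal(unname(stats::coef(line)[2]), cf$slope, tolerance = 1e-8)
    expect_equal(unname(stats::coef(line)[1]), cf$intercept, tolerance = 1e-8)
    expect_gt(suppressWarnings(summary(line)$r.squared), 1 - 1e-12)
  }
})

test_that("ping-pong reciprocal slope is constant and REO varied-B intercept is 1/V", {
  pp <- kinetic_params(V = 3, Ka = 0.07, Kb = 0.2)
  cf <- reciprocal_coefficients(mechanism_model("PING_PONG"), pp, "A",
                                c(0.05, 0.1, 0.4))
  expect_equal(cf$slope, rep(0.07 / 3, 3))
  reo <- reo_truth()
  cf2 <- reciprocal_coefficients(mechanism_model("RAPID_EQ_ORDERED"), reo,
                                 "B", c(0.05, 0.1, 0.15, 0.25))
  expect_equal(cf2$intercept, rep(1 / reo$V, 4))
})

test_that("reciprocal coefficients reproduce 1/rate at arbitrary abscissae", {
  set.seed(303)
  for (nm in BIBI_MODELS) {
    q <- draw_params()
    p <- params_for(nm, q)
    m <- mechanism_model(nm)
    f <- 0.08
    s_levels <- c(0.01, 0.04, 0.09, 0.21, 0.44)
    cf <- reciprocal_coefficients(m, p, "A", f)
    expect_equal(cf$intercept + cf$slope / s_levels,
                 1 / rate_law(m, s_levels, f, p), tolerance = 1e-8)
  }
})
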