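# Primary/secondary replot diagnostics and the mechanism classifier.

test_that("primary reciprocal fits match the closed-form coefficients on exact data", {
  d <- exact_reo_dataset()
  p <- reo_truth()
  m <- mechanism_model("RAPID_EQ_ORDERED")
  for (varied in c("A", "B")) {
    fam <- primary_reciprocal_fits(d, varied)
    cf <- reciprocal_coefficients(m, p, varied, fam$fixed_conc)
    expect_equal(fam$slope, cf$slope, tolerance = 1e-8)
    expect_equal(fam$intercept, cf$intercept, tolerance = 1e-8)
  }
  # varied-B family shares the common intercept 1/V
  famB <- primary_reciprocal_fits(d, "B")
  expect_equal(famB$intercept, rep(1 / p$V, nrow(famB)), tolerance = 1e-8)
})

test_that("zero rates are dropped with a warning and sparse levels rejected", {
  d <- exact_reo_dataset()
  d$v[1] <- 0
  expect_warning(primary_reciprocal_fits(d, "A"), "zero-rate")
  small <- exact_reo_dataset()
  small <- small[small$A %in% unique(small$A)[1:2], ]
  expect_error(primary_reciprocal_fits(small, "B"), ">= 3")
})

test_that("parallelism test separates ping-pong from sequential families", {
  pp <- kinetic_params(V = 10, Ka = 0.08, Kb = 0.1)
  dpp <- generate_initial_rates(mechanism_model("PING_PONG"), pp,
                                reference_bisubstrate_design())
  for (varied in c("A", "B")) {
    fam <- primary_reciprocal_fits(dpp, varied)
    expect_true(test_parallelism(fam)$parallel)
  }
  # REO slopes scale with 1/[B]: decisively non-parallel
  fam_reo <- primary_reciprocal_fits(exact_reo_dataset(), "A")
  res <- test_parallelism(fam_reo)
  expect_false(res$parallel)
  expect_lt(res$p, 0.001)
})

test_that("intersection estimates reproduce the analytic REO geometry", {
  d <- exact_reo_dataset()
  p <- reo_truth()
  famA <- primary_reciprocal_fits(d, "A")
  intA <- estimate_intersection(famA, bootstrap_n = 200, seed = 1)
  # varied leading substrate: lines cross at x = -1/Kia, y = 1/V
  expect_equal(intA$x, -1 / p$Kia, tolerance = 1e-6)
  expect_equal(intA$y, 1 / p$V, tolerance = 1e-6)
  expect_false(intA$on_axis)
  famB <- primary_reciprocal_fits(d, "B")
  intB <- estimate_intersection(famB, bootstrap_n = 200, seed = 1)
  expect_true(intB$on_axis)
  expect_equal(intB$y, 1 / p$V, tolerance = 1e-8)
  # ordered steady-state: left of axis in both orientations
  oss <- kinetic_params(V = 5, Ka = 0.06, Kb = 0.11, Kia = 0.09)
  doss <- generate_initial_rates(mechanism_model("ORDERED_STEADY_STATE"), oss,
                                 reference_bisubstrate_design())
  for (varied in c("A", "B")) {
    fam <- primary_reciprocal_fits(doss, varied)
    int <- estimate_intersection(fam, bootstrap_n = 200, seed = 2)
    expect_lt(int$x, 0)
    expect_false(int$on_axis)
  }
  # analytic check for the varied-A orientation: x* = -1/Kia
  famA_oss <- primary_reciprocal_fits(doss, "A")
  expect_equal(estimate_intersection(famA_oss, bootstrap_n = 100,
                                     seed = 3)$x,
               -1 / oss$Kia, tolerance = 1e-6)
})

test_that("secondary slope replots distinguish origin-passing from offset lines", {
  d <- exact_reo_dataset()
  p <- reo_truth()
  famA <- primary_reciprocal_fits(d, "A")
  secA <- secondary_slope_replot(famA)
  # REO varied-leading-substrate replot passes through the origin with
  # slope Kia*Kb/V
  expect_lt(abs(secA$intercept), 1e-8 * mean(abs(secA$y)))
  expect_true(secA$passes_origin)
  expect_equal(secA$slope, p$Kia * p$Kb / p$V, tolerance = 1e-8)
  famB <- primary_reciprocal_fits(d, "B")
  secB <- secondary_slope_replot(famB)
  expect_false(secB$passes_origin)
  expect_equal(secB$intercept, p$Kb / p$V, tolerance = 1e-8)
  # ordered steady-state varied-A replot has intercept Ka/V > 0
  oss <- kinetic_params(V = 5, Ka = 0.06, Kb = 0.11, Kia = 0.09)
  doss <- generate_initial_rates(mechanism_model("ORDERED_STEADY_STATE"), oss,
                                 reference_bisubstrate_design())
  sec_oss <- secondary_slope_replot(primary_reciprocal_fits(doss, "A"))
  expect_false(sec_oss$passes_origin)
  expect_equal(sec_oss$intercept, oss$Ka / oss$V, tolerance = 1e-8)
  # explicit point subsets are honored
  sec3 <- secondary_slope_replot(famA, use = 1:3)
  expect_equal(sec3$n, 3)
})

test_that("global AICc selection ranks the generating model first on exact data", {
  d <- exact_reo_dataset()
  sel <- global_fit_model_selection(d)
  expect_equal(sel$model[1], "RAPID_EQ_ORDERED")
  expect_equal(sel$leading[1], "NAD+")
  expect_gte(sel$dAICc[2], 2)
  # fitting the generating model recovers its parameters
  pars <- attr(sel, "params")[["RAPID_EQ_ORDERED[NAD+]"]]
  expect_equal(pars$V, 17.8, tolerance = 1e-6)
  expect_equal(pars$Kia, 0.081, tolerance = 1e-6)
  expect_equal(pars$Kb, 0.13, tolerance = 1e-6)
  # the swapped substrate order fits strictly worse
  ss_right <- sel$ss[sel$model == "RAPID_EQ_ORDERED" & sel$leading == "NAD+"]
  ss_wrong <- sel$ss[sel$model == "RAPID_EQ_ORDERED" & sel$leading == "D-SLA"]
  expect_gt(ss_wrong, ss_right + 1e-6)
})

test_that("classifier is exact on noise-free data for all mechanisms and orders", {
  set.seed(77)
  des <- reference_bisubstrate_design()
  for (nm in BIBI_MODELS) {
    for (swap in if (nm %in% c("ORDERED_STEADY_STATE", "RAPID_EQ_ORDERED"))
                   c(FALSE, TRUE) else FALSE) {
      q <- draw_params()
      p <- params_for(nm, q)
      d <- if (swap) swapped_dataset(nm, p, des) else
        generate_initial_rates(mechanism_model(nm), p, des)
      vd <- classify_mechanism(d, bootstrap_n = 100, seed = 13)
      expected <- switch(nm,
        PING_PONG = "PING_PONG",
        RAPID_EQ_ORDERED = "RAPID_EQ_ORDERED",
        "SEQUENTIAL_STEADY_STATE")
      expect_equal(vd$classification, expected,
                   label = paste(nm, "swap =", swap))
      if (nm == "RAPID_EQ_ORDERED")
        expect_equal(vd$leading_substrate, if (swap) "D-SLA" else "NAD+")
    }
  }
})

test_that("classifier verdict maps under A/B relabeling of the input", {
  d <- exact_reo_dataset()
  # swap the columns and labels: same experiment, opposite bookkeeping
  d_swapped <- rate_dataset(d$B, d$A, d$v, d$replicate,
                            a_label = attr(d, "b_label"),
                            b_label = attr(d, "a_label"))
  v1 <- classify_mechanism(d, bootstrap_n = 100, seed = 3)
  v2 <- classify_mechanism(d_swapped, bootstrap_n = 100, seed = 3)
  expect_equal(v1$classification, v2$classification)
  expect_equal(v1$leading_substrate, v2$leading_substrate)  # label, not column
})

test_that("classifier returns UNDETERMINED on an insufficient design", {
  des <- design_grid(c(0.05, 0.1), c(0.05, 0.125, 0.25), replicates = 2)
  d <- generate_initial_rates(reo_model(), reo_truth(), des)
  vd <- classify_mechanism(d, bootstrap_n = 50)
  expect_equal(vd$classification, "UNDETERMINED")
})

test_that("classifier stays accurate under realistic assay noise", {
  # 60 seeded replicates at the default 5% CV noise on the reference grid;
  # the acceptance suite runs the full 200-seed version
  ok <- vapply(1:60, function(s) {
    d <- generate_initial_rates(reo_model(), reo_truth(),
                                reference_bisubstrate_design(),
                                noise = default_noise(), seed = s)
    v <- classify_mechanism(d, bootstrap_n = 300, seed = s)
    v$classification == "RAPID_EQ_ORDERED" &&
      identical(v$leading_substrate, "NAD+")
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("the SLA dehydrogenase evidence pattern yields REO with NAD+ first", {
  # qualitative pattern of the real experiment: origin-passing varied-NAD+
  # secondary replot, positive-intercept varied-SLA replot, intersections
  # near (varied SLA) and left of (varied NAD+) the y axis, at 5% CV noise
  d <- generate_initial_rates(reo_model(), reo_truth(),
                              reference_bisubstrate_design(),
                              noise = default_noise(), seed = 2024)
  vd <- classify_mechanism(d, bootstrap_n = 500, seed = 2024)
  expect_equal(vd$classification, "RAPID_EQ_ORDERED")
  expect_equal(vd$leading_substrate, "NAD+")
  expect_true(vd$confidence %in% c("clear", "indicative"))
})
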