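# Conversions, derivations and input validation.

test_that("rate_to_probability matches hand-evaluated cases and errors on bad input", {
  expect_equal(rate_to_probability(0, t_i = 5, t = 1), 0)
  expect_equal(rate_to_probability(0.3, t_i = 1, t = 1), 0.3)
  # survival over two 1-year cycles must square back to the 2-year survival
  p1 <- rate_to_probability(0.5, t_i = 2, t = 1)
  expect_equal(p1, 1 - exp(log(0.5) / 2))
  expect_equal((1 - p1)^2, 0.5)
  expect_error(rate_to_probability(1, 1, 1), "p_i")
  expect_error(rate_to_probability(0.5, 0, 1), "t_i")
  expect_error(rate_to_probability(0.5, 1, -1), "`t` must")
})

test_that("rate_to_probability is monotone in t and p_i and round-trips at t = t_i = 1", {
  p <- seq(0, 0.9, by = 0.1)
  expect_equal(rate_to_probability(p, 1, 1), p, tolerance = 1e-12)
  expect_equal(1 - exp(-probability_to_rate(p)), p, tolerance = 1e-12)
  for (pi in c(0.05, 0.3, 0.7)) {
    tt <- c(0.5, 1, 2, 4)
    expect_true(all(diff(rate_to_probability(pi, 2, tt)) > 0))
  }
  expect_true(all(diff(rate_to_probability(seq(0.1, 0.8, 0.1), 3, 1)) > 0))
})

test_that("odds_ratio_to_relative_risk matches the 2x2-table oracle and its limits", {
  expect_equal(odds_ratio_to_relative_risk(1, 0.718), 1)
  expect_equal(odds_ratio_to_relative_risk(0.57, 0), 0.57)
  # oracle: build the exposed risk directly from odds
  or <- 0.57; p0 <- 0.718
  odds1 <- or * p0 / (1 - p0)
  p1 <- odds1 / (1 + odds1)
  expect_equal(odds_ratio_to_relative_risk(or, p0), p1 / p0,
               tolerance = 1e-12)
  expect_equal(odds_ratio_to_relative_risk(or, p0), 0.8245,
               tolerance = 1e-4)
  expect_error(odds_ratio_to_relative_risk(0.5, 1), "p0")
  expect_error(odds_ratio_to_relative_risk(-1, 0.5), "or")
})

test_that("OR-to-RR conversion is bounded by OR and 1 and monotone in p0", {
  for (or in c(0.2, 0.57, 1.5, 4)) {
    p0 <- seq(0, 0.95, by = 0.05)
    rr <- odds_ratio_to_relative_risk(or, p0)
    expect_true(all(rr >= min(or, 1) - 1e-12 & rr <= max(or, 1) + 1e-12))
    if (or < 1) expect_true(all(diff(rr) > 0)) else
      if (or > 1) expect_true(all(diff(rr) < 0))
  }
})

test_that("derive_inactivity_probabilities applies the product and SPA rules", {
  cfg <- model_config()
  bands <- data.frame(
    sex = "female",
    age_lower = c(50, 55, 60, 65, 70), age_upper = c(54, 59, 64, 69, 100),
    employment = c(1, 0.718, 0.718, 0.107, 0),
    unemployment = c(0, 0.028, 0.028, 0.016, 0),
    lt_sickness = NA_real_, early_retirement = NA_real_,
    disability = NA_real_)
  inact <- inactivity_inputs(
    lt_sickness_mean = 0.1, early_retirement_mean = 0.05,
    disability_prob = data.frame(age_lower = c(50, 65),
                                 age_upper = c(64, 100),
                                 value = c(0.1, 0.2)),
    disabled_inactivity_prevalence = data.frame(
      age_lower = c(50, 65), age_upper = c(64, 100), value = c(0.4, 0.5)))
  out <- derive_inactivity_probabilities(baseline_participation(bands),
                                         inact, cfg)
  # fully employed band: no inactivity to distribute
  expect_equal(out$lt_sickness[1], 0)
  expect_equal(out$early_retirement[1], 0)
  # mean x share not active
  expect_equal(out$lt_sickness[2], 0.1 * (1 - 0.746))
  expect_equal(out$early_retirement[2], 0.05 * (1 - 0.746))
  # disability: product rule, band 65-69 keeps it, SPA zeroes unemployment
  # and early retirement; bands starting above SPA lose disability too
  expect_equal(out$disability[4], 0.2 * 0.5)
  expect_equal(out$unemployment[4], 0)
  expect_equal(out$early_retirement[4], 0)
  expect_equal(out$disability[5], 0)
  sums <- rowSums(as.matrix(as.data.frame(out)[
    c("employment", "unemployment", "lt_sickness", "early_retirement",
      "disability")]))
  expect_true(all(sums <= 1 + 1e-12))
})

test_that("derived per-band sums never exceed 1 for random valid inputs", {
  cfg <- model_config()
  set.seed(11)
  for (i in 1:50) {
    e <- runif(3, 0, 0.9)
    u <- pmin(runif(3, 0, 0.2), 1 - e)
    bands <- data.frame(
      sex = "male", age_lower = c(50, 60, 70), age_upper = c(59, 69, 100),
      employment = e, unemployment = u, lt_sickness = NA_real_,
      early_retirement = NA_real_, disability = NA_real_)
    m1 <- runif(1)
    inact <- inactivity_inputs(
      m1, runif(1, 0, 1 - m1),
      data.frame(age_lower = 50, age_upper = 100, value = runif(1)),
      data.frame(age_lower = 50, age_upper = 100, value = runif(1)))
    out <- derive_inactivity_probabilities(baseline_participation(bands),
                                           inact, cfg)
    sums <- rowSums(as.matrix(as.data.frame(out)[
      c("employment", "unemployment", "lt_sickness", "early_retirement",
        "disability")]))
    expect_true(all(sums <= 1 + 1e-9))
  }
})

test_that("apply_relative_effects multiplies via OR conversion and is the identity for unit effects", {
  inp <- make_uk_inputs()
  base <- inp$baseline
  cfg <- model_config()
  # null effects of either measure leave the table untouched
  null_set <- relative_effect_set("moderate", lapply(
    c("employment", "lt_sickness"), function(o)
      relative_effect(o, if (o == "employment") "odds_ratio" else
        "relative_risk", 1, 1, 1)))
  out <- apply_relative_effects(base, null_set, cfg)
  expect_equal(as.data.frame(out), as.data.frame(base),
               ignore_attr = TRUE)
  expect_equal(as.data.frame(apply_relative_effects(base, NULL, cfg)),
               as.data.frame(base), ignore_attr = TRUE)
  # employment OR 0.57 at p0 = 0.718 -> x RR 0.82476
  eset <- relative_effect_set("moderate", list(
    relative_effect("employment", "odds_ratio", 0.57, 0.21, 1.54),
    relative_effect("lt_sickness", "relative_risk", 2)))
  out <- apply_relative_effects(base, eset, cfg)
  expect_equal(out$employment[1], 0.718 * odds_ratio_to_relative_risk(0.57, 0.718),
               tolerance = 1e-9)
  expect_equal(out$employment[1], 0.5920, tolerance = 1e-3)
  expect_equal(out$lt_sickness[1], 2 * 0.031)
})

test_that("odds ratios below the rarity threshold are used as relative risks directly", {
  base <- baseline_participation(data.frame(
    sex = "female", age_lower = 50, age_upper = 100,
    employment = 0.5, unemployment = 0.05, lt_sickness = 0.02,
    early_retirement = 0.01, disability = 0.02))
  eset <- relative_effect_set("moderate", list(
    relative_effect("employment", "odds_ratio", 0.8),
    relative_effect("unemployment", "odds_ratio", 2)))
  out <- apply_relative_effects(base, eset, model_config())
  # p0 = 0.05 < 0.10: OR taken as RR
  expect_equal(out$unemployment[1], 0.05 * 2)
  # p0 = 0.5 >= 0.10: converted
  expect_equal(out$employment[1],
               0.5 * odds_ratio_to_relative_risk(0.8, 0.5))
  # override: always convert
  out2 <- apply_relative_effects(base, eset, model_config(),
                                 convert_or = "always")
  expect_equal(out2$unemployment[1],
               0.05 * odds_ratio_to_relative_risk(2, 0.05))
})

test_that("probability overflow is clipped and renormalised with employment preserved", {
  base <- baseline_participation(data.frame(
    sex = "female", age_lower = 50, age_upper = 100,
    employment = 0.4, unemployment = 0.2, lt_sickness = 0.3,
    early_retirement = 0.05, disability = 0.05))
  eset <- relative_effect_set("moderate", list(
    relative_effect("employment", "relative_risk", 1),
    relative_effect("lt_sickness", "relative_risk", 3)))
  expect_warning(out <- apply_relative_effects(base, eset, model_config()),
                 "renormalised")
  vals <- as.matrix(as.data.frame(out)[c("employment", "unemployment",
                                         "lt_sickness", "early_retirement",
                                         "disability")])
  expect_equal(sum(vals), 1, tolerance = 1e-12)
  expect_equal(out$employment[1], 0.4)           # anchor untouched
  expect_true(attr(out, "adjusted")$renormalised)
  # quiet mode records the event without warning
  expect_silent(out3 <- apply_relative_effects(base, eset, model_config(),
                                               quiet = TRUE))
  expect_true(attr(out3, "adjusted")$renormalised)
})

test_that("adjust_mortality scales rates by the hazard ratios and equalises arms in the base case", {
  lt <- lifetable(data.frame(age = rep(50:60, 2),
                             sex = rep(c("female", "male"), each = 11),
                             rate = rep(seq(0.01, 0.02, length.out = 11), 2)))
  cfg <- model_config()
  adj <- mortality_adjustment(oa_excess_hr = 1, womac_hr_per_10 = 1.04)
  out <- adjust_mortality(lt, adj, "controlled", cfg)
  expect_equal(out$prob, lt$rate)                # identity HR, 1-year rates
  # base case: differential mortality off -> arms identical at every age
  adj2 <- mortality_adjustment()
  c0 <- adjust_mortality(lt, adj2, "controlled", cfg)
  u0 <- adjust_mortality(lt, adj2, "uncontrolled", cfg)
  expect_equal(c0$prob, u0$prob)
  expect_equal(c0$prob, pmin(lt$rate * 1.11, 1))
  # differential scenario: one 10-point WOMAC step multiplies by 1.04
  cfg2 <- model_config(differential_mortality = TRUE)
  u1 <- adjust_mortality(lt, adj2, "uncontrolled", cfg2, womac_delta = 10)
  expect_equal(u1$prob, pmin(lt$rate * 1.11 * 1.04, 1))
})

test_that("input constructors reject invalid values", {
  expect_error(model_config(discount_rate = 1.2), "discount_rate")
  expect_error(model_config(start_age = 66), "start_age")
  expect_error(model_config(state_pension_age = 75, max_working_age = 70),
               "max_working_age")
  expect_error(relative_effect("employment", "odds_ratio", -1), "positive")
  expect_error(relative_effect("employment", "odds_ratio", 1, 2, 3),
               "ci_low")
  expect_error(relative_effect_set("moderate", list(
    relative_effect("disability", "relative_risk", 2))), "employment")
  expect_error(baseline_participation(data.frame(
    sex = "female", age_lower = 50, age_upper = 54, employment = 0.9,
    unemployment = 0.3, lt_sickness = 0, early_retirement = 0,
    disability = 0)), "sum")
  expect_error(lifetable(data.frame(age = c(50, 52), sex = "male",
                                    rate = c(0.1, 0.1))), "consecutive")
})
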