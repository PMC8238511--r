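# Cash flows, discounting, incremental net tax and the report shape.

test_that("state cash flows follow the tariff and eligibility rules", {
  sch <- fiscal_schedule()
  cfg <- model_config()
  # dead and unknown are tax neutral
  expect_equal(sum(state_cash_flows("DEAD", 55, sch, cfg)), 0)
  expect_equal(sum(state_cash_flows("UNKNOWN", 55, sch, cfg)), 0)
  # unemployed below SPA: allowance plus indirect tax on the gross benefit
  u <- state_cash_flows("UNEMPLOYED", 55, sch, cfg)
  expect_equal(u[["jobseekers"]], 3866)
  expect_equal(u[["indirect_tax"]], 0.137 * 3866)
  # disabled past SPA: pension plus half the attendance allowance
  d <- state_cash_flows("DISABLED", 67, sch, cfg)
  expect_equal(d[["pension_attendance"]], 9110 + 0.5 * 3258)
  expect_equal(d[["pip"]], 0)
  # disabled below SPA: PIP
  d2 <- state_cash_flows("DISABLED", 60, sch, cfg)
  expect_equal(d2[["pip"]], 6102)
  # employed: earnings backed out of the labour-tax amount via the wedge,
  # indirect tax on disposable labour income
  e <- state_cash_flows("EMPLOYED", 55, sch, cfg)
  expect_equal(e[["direct_tax"]], 10886)
  expect_equal(e[["earnings"]], 10886 / 0.309)
  expect_equal(e[["indirect_tax"]], 0.137 * (10886 / 0.309 - 10886))
  # age-banded labour tax
  expect_equal(state_cash_flows("EMPLOYED", 62, sch, cfg)[["direct_tax"]],
               10015)
  expect_equal(state_cash_flows("EMPLOYED", 68, sch, cfg)[["direct_tax"]],
               8825)
  # early retirement and ordinary retirement draw the basic pension
  expect_equal(state_cash_flows("EARLY_RETIRED", 60, sch,
                                cfg)[["early_retirement_pension"]], 9110)
  expect_equal(state_cash_flows("RETIRED", 70, sch,
                                cfg)[["pension_attendance"]], 9110)
  expect_error(state_cash_flows("LIMBO", 55, sch, cfg), "unknown state")
})

test_that("annual healthcare cost composes the printed components and uplifts", {
  cfg <- model_config()
  zero <- healthcare_costs(drug = 0, appointment = 0, referral_share = 0,
                           referral_cost = 0,
                           primary = data.frame(name = "hip", prob = 0,
                                                cost = 0),
                           revision = data.frame(name = "x", prob = 0,
                                                 cost = 0))
  expect_equal(annual_healthcare_cost("severe", zero, cfg), 0)
  basic <- healthcare_costs(revision = data.frame(
    name = "none", prob = 0, cost = 0))
  base <- 203 + 713 + 0.7082 * 82
  expect_equal(annual_healthcare_cost("controlled", basic, cfg), base)
  expect_equal(annual_healthcare_cost("moderate", basic, cfg), base * 1.2)
  expect_equal(annual_healthcare_cost("severe", basic, cfg), base * 1.3)
  # expected revision cost is probability x cost
  hip <- healthcare_costs(drug = 0, appointment = 0, referral_share = 0,
                          revision = data.frame(name = "hip_aseptic",
                                                prob = 0.0047,
                                                cost = 12444))
  expect_equal(annual_healthcare_cost("controlled", hip, cfg),
               0.0047 * 12444)
})

test_that("npv discounts with t = 0 undiscounted and is linear", {
  expect_equal(npv(c(100, 100, 100), 0), 300)
  expect_equal(npv(c(0, 1000), 0.035), 1000 / 1.035)
  set.seed(3)
  a <- rnorm(10); b <- rnorm(10)
  expect_equal(npv(a + b, 0.035), npv(a, 0.035) + npv(b, 0.035),
               tolerance = 1e-9)
  expect_equal(npv(3 * a, 0.07), 3 * npv(a, 0.07), tolerance = 1e-9)
  expect_error(npv(a, -1.5), "greater than -1")
})

test_that("incremental net tax is the arm difference and antisymmetric", {
  mk <- function(net) {
    comps <- setNames(rep(0, 10),
                      c("earnings", "direct_tax", "indirect_tax",
                        "jobseekers", "esa", "pip",
                        "early_retirement_pension", "pension_attendance",
                        "healthcare", "life_years"))
    comps["direct_tax"] <- net
    fiscal_result(comps)
  }
  expect_equal(incremental_net_tax(mk(5), mk(5)), 0)
  # published round-figure identities
  expect_equal(incremental_net_tax(mk(56119), mk(15778)), 40341)
  # published INT 70754 reflects rounding of the arm-level nets
  expect_equal(incremental_net_tax(mk(56119), mk(-14634)), 70754,
               tolerance = 2e-5)
  expect_equal(incremental_net_tax(mk(10), mk(30)),
               -incremental_net_tax(mk(30), mk(10)))
})

test_that("fiscal_result enforces net tax = gross tax - transfers - healthcare", {
  comps <- c(earnings = 1000, direct_tax = 300, indirect_tax = 50,
             jobseekers = 20, esa = 10, pip = 40,
             early_retirement_pension = 30, pension_attendance = 5,
             healthcare = 60, life_years = 10)
  fr <- fiscal_result(comps)
  expect_equal(fr$gross_tax, 350)
  expect_equal(fr$total_transfers, 20 + 10 + 40 + 30 + 5 + 60)
  expect_equal(fr$net_tax, 350 - 165)
})

test_that("a zero-benefit schedule makes net tax equal gross tax minus healthcare", {
  inp <- make_uk_inputs("employment-only")
  inp$schedule <- fiscal_schedule(jobseekers = 0, esa = 0, pip = 0,
                                  state_pension = 0, attendance = 0)
  res <- run_model(inp, model_config(), quiet = TRUE)
  for (arm in c("controlled", "moderate", "severe"))
    expect_equal(res[[arm]]$net_tax,
                 res[[arm]]$gross_tax - res[[arm]]$healthcare,
                 tolerance = 1e-9)
})

test_that("base-case run satisfies its internal identities and Table-4 sign conventions", {
  inp <- make_uk_inputs()
  res <- run_model(inp, model_config(), quiet = TRUE)
  tab <- disaggregate(res)
  for (arm in c("controlled", "moderate", "severe")) {
    fr <- res[[arm]]
    expect_equal(fr$net_tax, fr$gross_tax - fr$total_transfers,
                 tolerance = 1e-6)
    expect_equal(fr$total_transfers,
                 fr$jobseekers + fr$esa + fr$pip +
                   fr$early_retirement_pension + fr$pension_attendance +
                   fr$healthcare, tolerance = 1e-9)
  }
  expect_equal(unname(res$int["moderate"]),
               res$controlled$net_tax - res$moderate$net_tax)
  # incremental columns are controlled minus uncontrolled
  inc <- tab$incremental_moderate
  expect_equal(inc, tab$controlled - tab$moderate, tolerance = 1e-9)
  # transfers negative (uncontrolled receives more), taxes positive
  expect_lt(tab$incremental_moderate[tab$component == "Total transfers"], 0)
  expect_gt(tab$incremental_moderate[tab$component == "Gross tax revenue"],
            0)
  expect_gt(tab$incremental_severe[tab$component == "Earnings"],
            tab$incremental_moderate[tab$component == "Earnings"])
  # life-years identical across arms when differential mortality is off
  expect_equal(res$controlled$life_years, res$moderate$life_years,
               tolerance = 1e-12)
  expect_equal(res$controlled$life_years, res$severe$life_years,
               tolerance = 1e-12)
})

test_that("INT is zero under null effects with no uplift, positive under employment-reducing effects", {
  cfg0 <- model_config(healthcare_uplift_moderate = 0,
                       healthcare_uplift_severe = 0)
  res0 <- run_model(make_uk_inputs("null"), cfg0, quiet = TRUE)
  expect_equal(unname(res0$int), c(0, 0), tolerance = 1e-9)
  # with default uplifts, null effects leave exactly the healthcare increment
  res1 <- run_model(make_uk_inputs("null"), model_config(), quiet = TRUE)
  expect_equal(unname(res1$int["moderate"]),
               0.2 * res1$controlled$healthcare, tolerance = 1e-6)
  expect_equal(unname(res1$int["moderate"]),
               res1$moderate$healthcare - res1$controlled$healthcare,
               tolerance = 1e-9)
  # random employment-reducing effect sets always cost the government
  set.seed(21)
  for (i in 1:10) {
    orr <- runif(1, 0.2, 0.95)
    eset <- relative_effect_set("moderate", list(
      relative_effect("employment", sample(c("odds_ratio",
                                             "relative_risk"), 1), orr)))
    inp <- make_uk_inputs("null")
    inp$effects$moderate <- eset
    res <- run_model(inp, cfg0, quiet = TRUE)
    expect_gt(unname(res$int["moderate"]), 0)
  }
})

test_that("results are linear in the cohort sex mix", {
  inp <- make_uk_inputs()
  # give the sexes different baselines so the weighting is visible
  inp$baseline$employment[inp$baseline$sex == "male" &
                            inp$baseline$age_lower < 65] <- 0.80
  f <- run_model(inp, model_config(female_share = 1), quiet = TRUE)
  m <- run_model(inp, model_config(female_share = 0), quiet = TRUE)
  w <- run_model(inp, model_config(female_share = 0.586), quiet = TRUE)
  for (k in c("earnings", "gross_tax", "total_transfers", "net_tax",
              "life_years"))
    expect_equal(w$controlled[[k]],
                 0.586 * f$controlled[[k]] + 0.414 * m$controlled[[k]],
                 tolerance = 1e-9)
  expect_equal(unname(w$int["severe"]),
               unname(0.586 * f$int["severe"] + 0.414 * m$int["severe"]),
               tolerance = 1e-9)
})
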