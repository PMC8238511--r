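# Fiscal accounting: per-state cash flows (taxes, transfers, healthcare),
# net-present-value aggregation and the incremental net tax (INT), plus the
# two-arm / two-sex model orchestrator and the disaggregated report.

.components <- c("earnings", "direct_tax", "indirect_tax", "jobseekers",
                 "esa", "pip", "early_retirement_pension",
                 "pension_attendance")

#' Tax and transfer schedule
#'
#' Annualised per-capita tax amounts and benefit tariffs with their
#' eligibility rules. Defaults are 2020 UK values: median labour tax by age
#' band (the 30.9% employee+employer tax wedge applied to median income),
#' 13.7% indirect taxation of gross income, jobseeker's allowance,
#' employment and support allowance (ESA), personal independence payment
#' (PIP), the basic state pension and attendance allowance (paid to half of
#' disabled people after pension age).
#'
#' @param labour_tax Data frame `age_lower`, `age_upper`, `amount`: annual
#'   labour tax per employed person by age band.
#' @param tax_wedge Combined direct tax + national insurance share of labour
#'   income; used to back out gross earnings from the labour-tax amount.
#' @param indirect_rate Indirect tax rate applied to disposable labour
#'   income and to gross benefit income.
#' @param jobseekers,esa,pip,state_pension,attendance Annual amounts (GBP).
#' @param attendance_share Share of post-pension-age disabled people
#'   receiving attendance allowance. Default 0.5.
#' @return An object of class `fiscal_schedule`.
#' @export
fiscal_schedule <- function(labour_tax = data.frame(
                              age_lower = c(50, 60, 65),
                              age_upper = c(59, 64, 120),
                              amount = c(10886, 10015, 8825)),
                            tax_wedge = 0.309, indirect_rate = 0.137,
                            jobseekers = 3866, esa = 4885, pip = 6102,
                            state_pension = 9110, attendance = 3258,
                            attendance_share = 0.5) {
  amounts <- c(labour_tax$amount, jobseekers, esa, pip, state_pension,
               attendance)
  if (any(amounts < 0)) stop("amounts must be >= 0", call. = FALSE)
  for (r in c(tax_wedge, indirect_rate, attendance_share))
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]", call. = FALSE)
  if (tax_wedge == 0) stop("`tax_wedge` must be positive", call. = FALSE)
  structure(list(labour_tax = labour_tax, tax_wedge = tax_wedge,
                 indirect_rate = indirect_rate, jobseekers = jobseekers,
                 esa = esa, pip = pip, state_pension = state_pension,
                 attendance = attendance,
                 attendance_share = attendance_share),
            class = "fiscal_schedule")
}

labour_tax_at <- function(schedule, age) {
  tab <- schedule$labour_tax[order(schedule$labour_tax$age_lower), ]
  i <- findInterval(age, tab$age_lower)
  if (i < 1) i <- 1
  tab$amount[min(i, nrow(tab))]
}

#' Healthcare utilisation and unit-cost table
#'
#' Annual per-person resource use for managing chronic osteoarthritis pain:
#' drugs, appointments, pain-management referrals, primary joint replacement
#' and surgical revision (expected costs as probability x unit cost).
#' Defaults are the 2020 UK estimates; primary surgery probabilities are not
#' published and default to 0 (configurable).
#'
#' @param drug,appointment Annual costs (GBP).
#' @param referral_share Share of patients referred per year.
#' @param referral_cost Unit cost per referral.
#' @param primary Data frame `name`, `prob`, `cost` for primary surgery.
#' @param revision Data frame `name`, `prob`, `cost` for revision surgery.
#' @return An object of class `healthcare_costs`.
#' @export
healthcare_costs <- function(drug = 203, appointment = 713,
                             referral_share = 0.7082, referral_cost = 82,
                             primary = data.frame(
                               name = c("hip", "knee"),
                               prob = c(0, 0), cost = c(6714, 6296)),
                             revision = data.frame(
                               name = c("hip_aseptic", "hip_septic",
                                        "knee_aseptic", "knee_septic"),
                               prob = c(0.0047, 0.0004, 0.0035, 0.0009),
                               cost = c(12444, 22946, 10325, 32094))) {
  probs <- c(referral_share, primary$prob, revision$prob)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (any(c(drug, appointment, referral_cost, primary$cost,
            revision$cost) < 0))
    stop("costs must be >= 0", call. = FALSE)
  structure(list(drug = drug, appointment = appointment,
                 referral_share = referral_share,
                 referral_cost = referral_cost,
                 primary = primary, revision = revision),
            class = "healthcare_costs")
}

#' Expected annual healthcare cost per living person
#'
#' Base cost = drugs + appointments + referral share x referral cost +
#' expected primary surgery and revision costs; the uncontrolled arms add
#' the configured uplift (20% moderate, 30% severe by default).
#'
#' @param arm `"controlled"`, `"moderate"` or `"severe"`.
#' @param table A [healthcare_costs()] object.
#' @param config A [model_config()].
#' @return Annual cost in GBP per living person-year.
#' @export
annual_healthcare_cost <- function(arm = c("controlled", "moderate",
                                           "severe"),
                                   table = healthcare_costs(),
                                   config = model_config()) {
  arm <- match.arg(arm)
  base <- table$drug + table$appointment +
    table$referral_share * table$referral_cost +
    sum(table$primary$prob * table$primary$cost) +
    sum(table$revision$prob * table$revision$cost)
  uplift <- switch(arm, controlled = 0,
                   moderate = config$healthcare_uplift_moderate,
                   severe = config$healthcare_uplift_severe)
  if (uplift < -1) stop("healthcare uplift below -1", call. = FALSE)
  base * (1 + uplift)
}

#' Per-person-year cash flows of one fiscal state
#'
#' Employed people generate earnings (labour tax / tax wedge), pay the
#' labour-tax amount directly and indirect tax on their disposable labour
#' income. Benefit recipients receive their tariff (jobseeker's allowance
#' below SPA, ESA for long-term sickness, PIP for disability below SPA, the
#' basic state pension for early and ordinary retirees, and pension plus a
#' share of attendance allowance for disabled people past SPA) and generate
#' indirect tax on the gross benefit. Unknown and dead generate nothing.
#'
#' @param state One of [fiscal_states()].
#' @param age Attained age in years.
#' @param schedule A [fiscal_schedule()].
#' @param config A [model_config()].
#' @return Named numeric vector of components: `earnings`, `direct_tax`,
#'   `indirect_tax`, `jobseekers`, `esa`, `pip`,
#'   `early_retirement_pension`, `pension_attendance` (GBP per person-year).
#' @export
state_cash_flows <- function(state, age, schedule = fiscal_schedule(),
                             config = model_config()) {
  if (!state %in% .states) stop("unknown state: ", state, call. = FALSE)
  z <- setNames(numeric(length(.components)), .components)
  post_spa <- age >= config$state_pension_age
  ir <- schedule$indirect_rate
  if (state == "EMPLOYED") {
    lt <- labour_tax_at(schedule, age)
    earn <- lt / schedule$tax_wedge
    z["earnings"] <- earn
    z["direct_tax"] <- lt
    z["indirect_tax"] <- ir * (earn - lt)
  } else if (state == "UNEMPLOYED") {
    if (!post_spa) {
      z["jobseekers"] <- schedule$jobseekers
      z["indirect_tax"] <- ir * schedule$jobseekers
    }
  } else if (state == "LT_SICK") {
    z["esa"] <- schedule$esa
    z["indirect_tax"] <- ir * schedule$esa
  } else if (state == "DISABLED") {
    if (post_spa) {
      amt <- schedule$state_pension +
        schedule$attendance_share * schedule$attendance
      z["pension_attendance"] <- amt
      z["indirect_tax"] <- ir * amt
    } else {
      z["pip"] <- schedule$pip
      z["indirect_tax"] <- ir * schedule$pip
    }
  } else if (state == "EARLY_RETIRED") {
    z["early_retirement_pension"] <- schedule$state_pension
    z["indirect_tax"] <- ir * schedule$state_pension
  } else if (state == "RETIRED") {
    z["pension_attendance"] <- schedule$state_pension
    z["indirect_tax"] <- ir * schedule$state_pension
  }
  z
}

# component matrices [state x age] for fast trace x cash aggregation
cash_arrays <- function(ages, schedule, config) {
  arrs <- lapply(.components, function(comp)
    matrix(0, 8, length(ages), dimnames = list(.states, ages)))
  names(arrs) <- .components
  for (j in seq_along(ages))
    for (s in .states) {
      v <- state_cash_flows(s, ages[j], schedule, config)
      for (comp in .components) arrs[[comp]][s, j] <- v[[comp]]
    }
  arrs
}

#' Net present value of a flow stream
#'
#' @param flows Numeric vector of per-cycle flows, the first at time 0
#'   (undiscounted).
#' @param r Annual discount rate (> -1).
#' @return `sum(flows / (1 + r)^t)` with `t = 0, 1, ...`.
#' @export
npv <- function(flows, r = 0.035) {
  if (r <= -1) stop("`r` must be greater than -1", call. = FALSE)
  sum(flows / (1 + r) ^ (seq_along(flows) - 1))
}

# Discounted component totals for one trace.
trace_components <- function(occ, ages, cash, hc_cost, r) {
  T <- length(ages)
  disc <- (1 + r) ^ -(0:(T - 1))
  occT <- occ[seq_len(T), , drop = FALSE]
  out <- vapply(.components, function(comp)
    sum(disc * rowSums(occT * t(cash[[comp]]))), numeric(1))
  living <- 1 - occT[, "DEAD"]
  out["healthcare"] <- hc_cost * sum(disc * living)
  out["life_years"] <- sum(disc * living)
  out
}

#' Assemble a fiscal result from discounted components
#'
#' @param components Named numeric vector with entries `earnings`,
#'   `direct_tax`, `indirect_tax`, `jobseekers`, `esa`, `pip`,
#'   `early_retirement_pension`, `pension_attendance`, `healthcare`,
#'   `life_years` (discounted NPVs / discounted life-years).
#' @param arm Arm label.
#' @return An object of class `fiscal_result`: the components plus
#'   `gross_tax`, `total_transfers` (transfers plus healthcare, reported as
#'   a non-negative outflow) and `net_tax = gross_tax - total_transfers`.
#' @export
fiscal_result <- function(components, arm = NA_character_) {
  x <- as.list(components)
  x$gross_tax <- x$direct_tax + x$indirect_tax
  x$total_transfers <- x$jobseekers + x$esa + x$pip +
    x$early_retirement_pension + x$pension_attendance + x$healthcare
  x$net_tax <- x$gross_tax - x$total_transfers
  x$arm <- arm
  structure(x, class = "fiscal_result")
}

#' Incremental net tax
#'
#' The headline quantity of the analysis: the difference in discounted net
#' tax between the controlled-pain and uncontrolled-pain cohorts. Positive
#' values mean uncontrolled pain costs the government.
#'
#' @param controlled,uncontrolled `fiscal_result` objects.
#' @return `net_tax(controlled) - net_tax(uncontrolled)` in GBP.
#' @export
incremental_net_tax <- function(controlled, uncontrolled) {
  controlled$net_tax - uncontrolled$net_tax
}

# ---- engine ---------------------------------------------------------------

# Precompute everything that does not change across arms / sensitivity
# draws: per-sex band tables, per-age baseline matrices, lifetable rates,
# cash-flow arrays and discount factors.
prepare_engine <- function(inputs, config) {
  T <- if (isTRUE(config$lifetime))
    max(inputs$lifetable$age) - config$start_age else config$horizon
  ages <- config$start_age + 0:(T - 1)
  sexes <- c("female", "male")
  weights <- setNames(c(config$female_share, 1 - config$female_share), sexes)
  bands <- lapply(setNames(sexes, sexes), function(s) {
    rows <- inputs$baseline[inputs$baseline$sex == s, , drop = FALSE]
    rows[order(rows$age_lower), , drop = FALSE]
  })
  idx <- lapply(bands, function(rows) {
    i <- findInterval(ages, rows$age_lower)
    pmax(i, 1)
  })
  rates <- lapply(setNames(sexes, sexes), function(s)
    lifetable_rates(inputs$lifetable, ages, s))
  list(config = config, inputs = inputs, T = T, ages = ages,
       sexes = sexes, weights = weights, bands = bands, idx = idx,
       rates = rates, cash = cash_arrays(ages, inputs$schedule, config),
       hc_base = annual_healthcare_cost("controlled", inputs$healthcare,
                                        config))
}

# One arm, both sexes, weighted. Returns components (+ traces if asked).
engine_arm <- function(eng, effects = NULL, arm = "controlled",
                       hr = NULL, womac_mult = 1, keep_traces = FALSE,
                       quiet = TRUE) {
  cfg <- eng$config
  hr <- hr %||% eng$inputs$mortality$oa_excess_hr
  hc <- eng$hc_base * (1 + switch(arm, controlled = 0,
                                  moderate = cfg$healthcare_uplift_moderate,
                                  severe = cfg$healthcare_uplift_severe))
  comps <- 0
  traces <- list()
  valid <- TRUE
  for (s in eng$sexes) {
    band <- eng$bands[[s]]
    if (!is.null(effects)) {
      band <- apply_relative_effects(band, effects, cfg, quiet = quiet)
      adj <- attr(band, "adjusted")
      if (adj$clipped || adj$renormalised) valid <- FALSE
    }
    bmat <- as.matrix(as.data.frame(band)[eng$idx[[s]], .outcomes,
                                          drop = FALSE])
    q <- pmin(eng$rates[[s]] * hr * womac_mult, 1)
    q <- ifelse(q < 1, 1 - exp(log(1 - q)), 1)
    occ <- matrix(0, eng$T + 1, 8, dimnames = list(NULL, .states))
    occ[1, ] <- initial_occupancy(bmat[1, ])
    v <- occ[1, , drop = FALSE]
    for (t in seq_len(eng$T)) {
      m <- build_transition_matrix(eng$ages[t], bmat[t, ], q[t], cfg)
      v <- v %*% m
      occ[t + 1, ] <- v
    }
    comps <- comps + eng$weights[[s]] *
      trace_components(occ, eng$ages, eng$cash, hc,
                       cfg$discount_rate)
    if (keep_traces)
      traces[[s]] <- structure(occ, class = c("cohort_trace", "matrix"),
                               ages = c(eng$ages,
                                        eng$ages[eng$T] + 1),
                               arm = arm, sex = s)
  }
  res <- fiscal_result(comps, arm = arm)
  attr(res, "traces") <- if (keep_traces) traces else NULL
  attr(res, "valid") <- valid
  res
}

womac_multiplier <- function(inputs, config, severity) {
  if (!isTRUE(config$differential_mortality)) return(1)
  delta <- switch(severity, moderate = config$womac_delta_moderate,
                  severe = config$womac_delta_severe)
  inputs$mortality$womac_hr_per_10 ^ (delta / 10)
}

#' Run the full fiscal cohort model
#'
#' Runs the controlled arm and the uncontrolled moderate and severe arms for
#' both sexes, weights results by the female share, and returns discounted
#' fiscal results with incremental net tax per comparison.
#'
#' @param inputs A model input bundle as produced by [make_uk_inputs()] or
#'   [make_synthetic_inputs()]: a list with elements `baseline`
#'   ([baseline_participation()]), `effects` (list with `moderate` and
#'   `severe` [relative_effect_set()]s, each possibly `NULL`), `lifetable`,
#'   `mortality`, `schedule`, `healthcare`.
#' @param config A [model_config()].
#' @param keep_traces Retain per-sex cohort traces on each arm result.
#' @param quiet Suppress probability-clipping warnings from effect
#'   application.
#' @return An object of class `oafiscal_result`: list with `controlled`,
#'   `moderate`, `severe` (`fiscal_result`s), `int` (named vector of
#'   incremental net tax for the two comparisons) and the `config`.
#' @export
run_model <- function(inputs, config = model_config(), keep_traces = FALSE,
                      quiet = FALSE) {
  eng <- prepare_engine(inputs, config)
  controlled <- engine_arm(eng, NULL, "controlled", keep_traces = keep_traces)
  arms <- list(controlled = controlled)
  int <- c()
  for (sev in c("moderate", "severe")) {
    eff <- inputs$effects[[sev]]
    arms[[sev]] <- engine_arm(eng, eff, sev,
                              womac_mult = womac_multiplier(inputs, config,
                                                            sev),
                              keep_traces = keep_traces, quiet = quiet)
    int[sev] <- incremental_net_tax(controlled, arms[[sev]])
  }
  structure(c(arms, list(int = int, config = config)),
            class = "oafiscal_result")
}

#' Disaggregated fiscal report
#'
#' Tabulates the discounted components per arm with incremental columns
#' (controlled minus uncontrolled, so transfer rows come out negative when
#' the uncontrolled cohort receives more).
#'
#' @param result An `oafiscal_result` from [run_model()].
#' @return A tibble with one row per fiscal component and columns
#'   `controlled`, `moderate`, `incremental_moderate`, `severe`,
#'   `incremental_severe` (GBP; life-years in years). All monetary values
#'   are nominal GBP.
#' @export
disaggregate <- function(result) {
  rows <- c(earnings = "Earnings", gross_tax = "Gross tax revenue",
            jobseekers = "Jobseeker's allowance",
            esa = "Employment and support allowance",
            pip = "Personal independence payment",
            early_retirement_pension = "Early retirement pension",
            pension_attendance = "State pension + attendance allowance",
            healthcare = "Healthcare costs",
            total_transfers = "Total transfers", net_tax = "Net tax",
            life_years = "Life-years")
  pull <- function(arm) vapply(names(rows), function(k)
    result[[arm]][[k]], numeric(1))
  ctrl <- pull("controlled"); mod <- pull("moderate"); sev <- pull("severe")
  tibble::tibble(component = unname(rows), controlled = unname(ctrl),
                 moderate = unname(mod),
                 incremental_moderate = unname(ctrl - mod),
                 severe = unname(sev),
                 incremental_severe = unname(ctrl - sev))
}

#' Share of incremental government cost attributable to healthcare
#'
#' @param result An `oafiscal_result`.
#' @param severity `"moderate"` or `"severe"`.
#' @return Fraction in \[0, 1\]: incremental healthcare NPV over the
#'   incremental total transfers (which include healthcare).
#' @export
healthcare_share <- function(result, severity = c("moderate", "severe")) {
  severity <- match.arg(severity)
  u <- result[[severity]]; c0 <- result$controlled
  inc_hc <- u$healthcare - c0$healthcare
  inc_tr <- u$total_transfers - c0$total_transfers
  inc_hc / inc_tr
}

#' @export
print.oafiscal_result <- function(x, ...) {
  cat("Fiscal cohort model result (GBP, discounted at ",
      sprintf("%.1f%%", 100 * x$config$discount_rate), ")\n", sep = "")
  cat(sprintf("  Incremental net tax, moderate: %10.0f\n", x$int["moderate"]))
  cat(sprintf("  Incremental net tax, severe:   %10.0f\n", x$int["severe"]))
  cat(sprintf("  Life-years (controlled):       %10.3f\n",
              x$controlled$life_years))
  invisible(x)
}

#' @export
print.fiscal_result <- function(x, ...) {
  cat("Fiscal result [", x$arm, "] (GBP)\n", sep = "")
  for (k in c("earnings", "gross_tax", "total_transfers", "healthcare",
              "net_tax"))
    cat(sprintf("  %-16s %12.0f\n", k, x[[k]]))
  cat(sprintf("  %-16s %12.3f\n", "life_years", x$life_years))
  invisible(x)
}
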