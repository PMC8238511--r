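# Model inputs: age-banded participation tables, relative effects,
# lifetables, mortality adjustments and the run configuration, together
# with the probability derivations that turn published summary inputs
# into per-cycle transition probabilities.

#' Model configuration
#'
#' Collects the run-level settings of the fiscal cohort model: cohort entry
#' age, state pension age (SPA), maximum working age, time horizon, discount
#' rate, cohort sex mix and the healthcare uplifts applied to the
#' uncontrolled-pain arms. Cycle length is fixed at one year.
#'
#' @param start_age Age (years) at cohort entry. Default 50.
#' @param state_pension_age SPA in years; no transitions into unemployment or
#'   early retirement at or after this age, and pension payments begin.
#'   Default 65.
#' @param max_working_age Oldest age at which employment is possible.
#'   Default 70.
#' @param horizon Number of annual cycles. Default 15 (remaining work
#'   expectancy of a 50-year-old).
#' @param lifetime If `TRUE`, the horizon is extended to the end of the
#'   lifetable (age 100) instead of `horizon` cycles.
#' @param discount_rate Annual discount rate as a fraction. Default 0.035.
#' @param female_share Share of females in the cohort. Default 0.586.
#' @param healthcare_uplift_moderate,healthcare_uplift_severe Additional
#'   healthcare resource use in the uncontrolled arms, as a fraction of the
#'   controlled-pain cost. Defaults 0.20 and 0.30.
#' @param differential_mortality If `TRUE`, the uncontrolled arm carries
#'   extra mortality scaling with the WOMAC score difference between arms
#'   (scenario analysis); the base case is `FALSE`.
#' @param womac_delta_moderate,womac_delta_severe WOMAC point difference
#'   between each uncontrolled arm and the controlled arm, used only when
#'   `differential_mortality` is on.
#' @param unknown_recurrent If `TRUE` (default) the residual probability mass
#'   of every cycle's reallocation goes to the tax-neutral UNKNOWN state,
#'   which routes back to employment one cycle later; if `FALSE` the
#'   residual stays with employment and UNKNOWN only holds the entry
#'   residual.
#' @param or_threshold Baseline-probability threshold at or above which odds
#'   ratios are converted to relative risks before application; below it the
#'   OR is used as the RR directly (rare-outcome approximation).
#' @param seed Optional integer seed recorded with results.
#'
#' @return An object of class `model_config` (a validated list).
#' @export
model_config <- function(start_age = 50, state_pension_age = 65,
                         max_working_age = 70, horizon = 15,
                         lifetime = FALSE, discount_rate = 0.035,
                         female_share = 0.586,
                         healthcare_uplift_moderate = 0.20,
                         healthcare_uplift_severe = 0.30,
                         differential_mortality = FALSE,
                         womac_delta_moderate = 20,
                         womac_delta_severe = 40,
                         unknown_recurrent = TRUE,
                         or_threshold = 0.10,
                         seed = NULL) {
  cfg <- list(start_age = start_age, state_pension_age = state_pension_age,
              max_working_age = max_working_age, horizon = horizon,
              lifetime = lifetime, discount_rate = discount_rate,
              female_share = female_share, cycle_length = 1,
              healthcare_uplift_moderate = healthcare_uplift_moderate,
              healthcare_uplift_severe = healthcare_uplift_severe,
              differential_mortality = differential_mortality,
              womac_delta_moderate = womac_delta_moderate,
              womac_delta_severe = womac_delta_severe,
              unknown_recurrent = unknown_recurrent,
              or_threshold = or_threshold, seed = seed)
  validate_model_config(cfg)
}

validate_model_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (cfg$discount_rate < 0 || cfg$discount_rate >= 1)
    stop("`discount_rate` must be in [0, 1)", call. = FALSE)
  if (cfg$female_share < 0 || cfg$female_share > 1)
    stop("`female_share` must be in [0, 1]", call. = FALSE)
  if (!(cfg$start_age < cfg$state_pension_age))
    stop("`start_age` must be below `state_pension_age`", call. = FALSE)
  if (!(cfg$state_pension_age <= cfg$max_working_age))
    stop("`state_pension_age` must not exceed `max_working_age`",
         call. = FALSE)
  if (!cfg$lifetime && (!is.numeric(cfg$horizon) || cfg$horizon < 1))
    stop("`horizon` must be a positive number of cycles", call. = FALSE)
  if (cfg$healthcare_uplift_moderate < -1 || cfg$healthcare_uplift_severe < -1)
    stop("healthcare uplifts must be greater than -1", call. = FALSE)
  structure(cfg, class = "model_config")
}

# ---- age bands ------------------------------------------------------------

check_age_bands <- function(lower, upper, what = "age bands") {
  if (any(lower > upper))
    stop(what, ": `age_lower` must not exceed `age_upper`", call. = FALSE)
  ord <- order(lower)
  lo <- lower[ord]; hi <- upper[ord]
  if (length(lo) > 1 && any(lo[-1] != hi[-length(hi)] + 1))
    stop(what, ": bands must be contiguous and non-overlapping",
         call. = FALSE)
  invisible(TRUE)
}

#' Baseline labour-market participation table
#'
#' Age-banded probabilities of the five fiscal outcomes (employment,
#' unemployment, long-term sickness, early retirement, disability) for the
#' controlled-pain (general-population) cohort, per sex. The residual mass
#' of each band belongs to the tax-neutral "unknown" state.
#'
#' @param df A data frame with columns `sex` ("female"/"male"), `age_lower`,
#'   `age_upper`, `employment`, `unemployment`, `lt_sickness`,
#'   `early_retirement`, `disability`. `NA` is permitted in the three
#'   inactivity columns when they are to be filled by
#'   [derive_inactivity_probabilities()].
#'
#' @return A validated `baseline_participation` data frame.
#' @export
baseline_participation <- function(df) {
  need <- c("sex", "age_lower", "age_upper", .outcomes)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("baseline table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- as.data.frame(df)[need]
  for (s in unique(df$sex)) {
    rows <- df[df$sex == s, ]
    check_age_bands(rows$age_lower, rows$age_upper,
                    paste0("baseline table (", s, ")"))
  }
  vals <- as.matrix(df[.outcomes])
  if (any(vals < 0 | vals > 1, na.rm = TRUE))
    stop("baseline probabilities must lie in [0, 1]", call. = FALSE)
  sums <- rowSums(vals)
  if (any(!is.na(sums) & sums > 1 + 1e-9)) {
    bad <- which(!is.na(sums) & sums > 1 + 1e-9)[1]
    stop(sprintf("baseline probabilities sum to %.4f (> 1) for %s band %d-%d",
                 sums[bad], df$sex[bad], df$age_lower[bad], df$age_upper[bad]),
         call. = FALSE)
  }
  structure(df, class = c("baseline_participation", "data.frame"))
}

# Expand a band-level table for one sex to a per-age outcome matrix.
# Ages below the first band carry the first band back (used by the
# early-onset scenario); ages above the last band use the last band.
expand_baseline <- function(bp, ages, sex) {
  rows <- bp[bp$sex == sex, , drop = FALSE]
  if (!nrow(rows))
    stop("no baseline rows for sex '", sex, "'", call. = FALSE)
  rows <- rows[order(rows$age_lower), , drop = FALSE]
  idx <- findInterval(ages, rows$age_lower)
  idx[idx < 1] <- 1
  out <- as.matrix(rows[idx, .outcomes, drop = FALSE])
  rownames(out) <- ages
  out
}

#' Single-year inactivity inputs
#'
#' The published sources report long-term sickness and early retirement as
#' single mean proportions of the inactive population, and disability as an
#' age-specific probability of being disabled together with the age-specific
#' prevalence of economic inactivity among disabled people. These feed
#' [derive_inactivity_probabilities()].
#'
#' @param lt_sickness_mean,early_retirement_mean Single mean rates in
#'   \[0, 1\].
#' @param disability_prob Data frame `age_lower`, `age_upper`, `value`:
#'   probability of being disabled per band.
#' @param disabled_inactivity_prevalence Data frame with the same shape:
#'   prevalence of economic inactivity among disabled people per band.
#' @return An object of class `inactivity_inputs`.
#' @export
inactivity_inputs <- function(lt_sickness_mean, early_retirement_mean,
                              disability_prob,
                              disabled_inactivity_prevalence) {
  for (x in c(lt_sickness_mean, early_retirement_mean,
              disability_prob$value, disabled_inactivity_prevalence$value))
    if (any(x < 0 | x > 1))
      stop("inactivity inputs must lie in [0, 1]", call. = FALSE)
  # both means are shares of the same inactive pool
  if (lt_sickness_mean + early_retirement_mean > 1)
    stop("lt_sickness_mean + early_retirement_mean must not exceed 1",
         call. = FALSE)
  structure(list(lt_sickness_mean = lt_sickness_mean,
                 early_retirement_mean = early_retirement_mean,
                 disability_prob = disability_prob,
                 disabled_inactivity_prevalence =
                   disabled_inactivity_prevalence),
            class = "inactivity_inputs")
}

# ---- relative effects -----------------------------------------------------

#' Relative measure of effect for one fiscal outcome
#'
#' A published odds ratio or relative risk describing how uncontrolled pain
#' shifts the probability of one labour-market outcome, with its 95% CI.
#'
#' @param outcome One of `"employment"`, `"unemployment"`, `"lt_sickness"`,
#'   `"early_retirement"`, `"disability"`.
#' @param measure `"odds_ratio"` or `"relative_risk"`.
#' @param point Point estimate (strictly positive).
#' @param ci_low,ci_high 95% confidence bounds; default to `point`.
#' @param age_lower,age_upper Optional age band when the effect is
#'   age-specific; `NULL` applies it to all ages.
#' @return An object of class `relative_effect`.
#' @export
relative_effect <- function(outcome, measure = c("relative_risk", "odds_ratio"),
                            point, ci_low = point, ci_high = point,
                            age_lower = NULL, age_upper = NULL) {
  outcome <- match.arg(outcome, .outcomes)
  measure <- match.arg(measure)
  if (any(c(point, ci_low, ci_high) <= 0))
    stop("effect estimates must be strictly positive", call. = FALSE)
  if (!(ci_low <= point && point <= ci_high))
    stop("need ci_low <= point <= ci_high for outcome '", outcome, "'",
         call. = FALSE)
  structure(list(outcome = outcome, measure = measure, point = point,
                 ci_low = ci_low, ci_high = ci_high,
                 age_lower = age_lower, age_upper = age_upper),
            class = "relative_effect")
}

#' Relative-effect set for one severity arm
#'
#' @param severity `"moderate"` or `"severe"`.
#' @param effects List of [relative_effect()] objects, at most one per
#'   (outcome, age band). Must include an employment effect: the likelihood
#'   of employment is the model's most influential parameter.
#' @return An object of class `relative_effect_set`.
#' @export
relative_effect_set <- function(severity = c("moderate", "severe"), effects) {
  severity <- match.arg(severity)
  if (inherits(effects, "relative_effect")) effects <- list(effects)
  if (!all(vapply(effects, inherits, logical(1), "relative_effect")))
    stop("`effects` must be a list of relative_effect objects", call. = FALSE)
  key <- vapply(effects, function(e)
    paste(e$outcome, e$age_lower %||% "all", sep = ":"), character(1))
  if (anyDuplicated(key))
    stop("at most one effect per (outcome, age band): duplicated ",
         key[duplicated(key)][1], call. = FALSE)
  if (!any(vapply(effects, function(e) e$outcome == "employment", logical(1))))
    stop("an employment effect is required", call. = FALSE)
  structure(list(severity = severity, effects = effects),
            class = "relative_effect_set")
}

# ---- lifetable and mortality ----------------------------------------------

#' Lifetable of annual mortality rates
#'
#' @param df Data frame with columns `age`, `sex`, `rate` (annual mortality
#'   rate, non-negative), covering every single year of age from the model
#'   start to 100 for each sex present.
#' @return A validated `lifetable` data frame.
#' @export
lifetable <- function(df) {
  need <- c("age", "sex", "rate")
  if (!all(need %in% names(df)))
    stop("lifetable needs columns age, sex, rate", call. = FALSE)
  if (any(df$rate < 0))
    stop("lifetable rates must be non-negative", call. = FALSE)
  for (s in unique(df$sex)) {
    a <- sort(df$age[df$sex == s])
    if (any(diff(a) != 1))
      stop("lifetable for sex '", s, "' must cover consecutive single years",
           call. = FALSE)
  }
  structure(as.data.frame(df)[need], class = c("lifetable", "data.frame"))
}

lifetable_rates <- function(lt, ages, sex) {
  rows <- lt[lt$sex == sex, ]
  idx <- match(ages, rows$age)
  if (anyNA(idx))
    stop("lifetable does not cover ages ",
         paste(ages[is.na(idx)], collapse = ", "), " for sex '", sex, "'",
         call. = FALSE)
  rows$rate[idx]
}

#' Mortality adjustment parameters
#'
#' Excess mortality of the osteoarthritis cohort relative to the general
#' population (applied to both arms), and the per-10-WOMAC-point hazard
#' ratio used in the differential-mortality scenario.
#'
#' @param oa_excess_hr Hazard ratio for OA excess mortality; default 1.11.
#' @param oa_excess_ci 95% CI; default `c(1.06, 1.17)`.
#' @param womac_hr_per_10 Hazard ratio per 10-point WOMAC increase; default
#'   1.04.
#' @param womac_ci 95% CI; default `c(1.01, 1.07)`.
#' @return An object of class `mortality_adjustment`.
#' @export
mortality_adjustment <- function(oa_excess_hr = 1.11,
                                 oa_excess_ci = c(1.06, 1.17),
                                 womac_hr_per_10 = 1.04,
                                 womac_ci = c(1.01, 1.07)) {
  if (oa_excess_hr <= 0 || womac_hr_per_10 <= 0)
    stop("hazard ratios must be strictly positive", call. = FALSE)
  structure(list(oa_excess_hr = oa_excess_hr, oa_excess_ci = oa_excess_ci,
                 womac_hr_per_10 = womac_hr_per_10, womac_ci = womac_ci),
            class = "mortality_adjustment")
}

# ---- conversions ----------------------------------------------------------

#' Convert a probability over one period to a cycle-length probability
#'
#' Re-expresses a probability `p_i` observed over `t_i` years as a
#' probability over `t` years under a constant hazard:
#' `1 - exp(log(1 - p_i) / t_i * t)`.
#'
#' @param p_i Probability over the source period, in \[0, 1).
#' @param t_i Source period length in years (> 0).
#' @param t Target cycle length in years (> 0). Default 1.
#' @return The converted probability, vectorised over `p_i`.
#' @export
#' @examples
#' rate_to_probability(0.5, t_i = 2)  # 1 - sqrt(0.5)
rate_to_probability <- function(p_i, t_i = 1, t = 1) {
  if (any(p_i < 0) || any(p_i >= 1))
    stop("`p_i` must lie in [0, 1)", call. = FALSE)
  if (any(t_i <= 0)) stop("`t_i` must be positive", call. = FALSE)
  if (any(t <= 0)) stop("`t` must be positive", call. = FALSE)
  1 - exp(log(1 - p_i) / t_i * t)
}

#' Convert an annual probability to a constant annual rate
#'
#' Inverse companion of [rate_to_probability()]: `-log(1 - p)`.
#'
#' @param p Annual probability in \[0, 1).
#' @return The annual rate.
#' @export
probability_to_rate <- function(p) {
  if (any(p < 0) || any(p >= 1))
    stop("`p` must lie in [0, 1)", call. = FALSE)
  -log(1 - p)
}

#' Convert an odds ratio to a relative risk
#'
#' Uses the baseline (unexposed) probability `p0`:
#' `RR = OR / (1 - p0 + p0 * OR)`.
#'
#' @param or Odds ratio (> 0).
#' @param p0 Probability of the outcome in the unexposed, in \[0, 1).
#' @return The implied relative risk, vectorised.
#' @export
#' @examples
#' odds_ratio_to_relative_risk(0.57, 0.718)
odds_ratio_to_relative_risk <- function(or, p0) {
  if (any(or <= 0)) stop("`or` must be strictly positive", call. = FALSE)
  if (any(p0 < 0) || any(p0 >= 1))
    stop("`p0` must lie in [0, 1)", call. = FALSE)
  or / (1 - p0 + p0 * or)
}

# ---- derivations ----------------------------------------------------------

#' Derive age-stratified inactivity probabilities
#'
#' Long-term sickness and early retirement are published as single mean
#' proportions of the inactive population; they are stratified by age by
#' multiplying the means by the share of each band that is neither employed
#' nor unemployed. Disability per band is the product of the probability of
#' being disabled and the prevalence of economic inactivity among disabled
#' people (taken as zero for bands starting above the state pension age,
#' and capped at the band's remaining probability mass so the five outcomes
#' never exceed 1). Unemployment and early retirement are zeroed for bands
#' at or above SPA.
#'
#' @param base A [baseline_participation()] table with the employment and
#'   unemployment columns filled.
#' @param inputs An [inactivity_inputs()] object.
#' @param config A [model_config()].
#' @return The completed `baseline_participation` table.
#' @export
derive_inactivity_probabilities <- function(base, inputs,
                                            config = model_config()) {
  stopifnot(inherits(inputs, "inactivity_inputs"))
  df <- as.data.frame(base)
  spa <- config$state_pension_age

  band_value <- function(tab, lower, what) {
    i <- findInterval(lower, tab$age_lower[order(tab$age_lower)])
    tab <- tab[order(tab$age_lower), ]
    if (i < 1 || lower > max(tab$age_upper))
      stop("missing ", what, " coverage for band starting at ", lower,
           call. = FALSE)
    tab$value[i]
  }

  for (i in seq_len(nrow(df))) {
    lo <- df$age_lower[i]
    not_active <- 1 - df$employment[i] - df$unemployment[i]
    if (not_active < -1e-9)
      stop("employment + unemployment exceeds 1 for band starting at ", lo,
           call. = FALSE)
    not_active <- max(not_active, 0)
    df$lt_sickness[i] <- inputs$lt_sickness_mean * not_active
    df$early_retirement[i] <- inputs$early_retirement_mean * not_active
    dis <- if (lo > spa) 0 else
      band_value(inputs$disability_prob, lo, "disability probability") *
      band_value(inputs$disabled_inactivity_prevalence, lo,
                 "disabled inactivity prevalence")
    # disability cannot exceed the band's remaining probability mass
    df$disability[i] <- min(dis, max(0, 1 - df$employment[i] -
                                       df$unemployment[i] -
                                       df$lt_sickness[i] -
                                       df$early_retirement[i]))
    if (lo >= spa) {
      df$unemployment[i] <- 0
      df$early_retirement[i] <- 0
    }
  }
  baseline_participation(df)
}

#' Apply relative effects to a baseline table
#'
#' Produces the uncontrolled-pain participation table by multiplying each
#' outcome's baseline probability by the corresponding relative effect.
#' Odds ratios are first converted to relative risks via
#' [odds_ratio_to_relative_risk()] using that outcome's baseline probability
#' whenever it is at or above `config$or_threshold` (below the threshold the
#' OR is used directly as an RR; `convert_or` overrides this rule). Results
#' are clipped to \[0, 1\] with a warning, and if a band's five outcomes come
#' to exceed 1 the excess is first absorbed by the band's unknown residual
#' and then removed by proportionally rescaling the non-employment outcomes
#' (employment, the anchor parameter, is preserved).
#'
#' @param base A [baseline_participation()] table.
#' @param effects A [relative_effect_set()], or `NULL` for no change.
#' @param config A [model_config()].
#' @param convert_or `"auto"` (threshold rule), `"always"`, or `"never"`.
#' @param quiet Suppress clipping/renormalisation warnings (the outcome is
#'   still recorded in the `"adjusted"` attribute).
#' @return The adjusted table, with attribute `"adjusted"` being a list with
#'   logical flags `clipped` and `renormalised`.
#' @export
apply_relative_effects <- function(base, effects, config = model_config(),
                                   convert_or = c("auto", "always", "never"),
                                   quiet = FALSE) {
  convert_or <- match.arg(convert_or)
  df <- as.data.frame(base)
  adjusted <- list(clipped = FALSE, renormalised = FALSE)
  if (!is.null(effects)) {
    stopifnot(inherits(effects, "relative_effect_set"))
    for (e in effects$effects) {
      rows <- if (is.null(e$age_lower)) seq_len(nrow(df)) else
        which(df$age_lower >= e$age_lower & df$age_upper <= e$age_upper)
      for (i in rows) {
        p0 <- df[[e$outcome]][i]
        rr <- if (e$measure == "odds_ratio" &&
                  (convert_or == "always" ||
                   (convert_or == "auto" && p0 >= config$or_threshold)))
          odds_ratio_to_relative_risk(e$point, p0) else e$point
        df[[e$outcome]][i] <- p0 * rr
      }
    }
    vals <- as.matrix(df[.outcomes])
    if (any(vals > 1)) {
      adjusted$clipped <- TRUE
      if (!quiet)
        warning("effect application pushed a probability above 1; clipped",
                call. = FALSE)
      vals[vals > 1] <- 1
    }
    sums <- rowSums(vals)
    over <- which(sums > 1 + 1e-12)
    if (length(over)) {
      adjusted$renormalised <- TRUE
      if (!quiet)
        warning("per-band probabilities exceeded 1 after applying effects; ",
                "non-employment outcomes renormalised", call. = FALSE)
      for (i in over) {
        e <- vals[i, "employment"]
        others <- vals[i, setdiff(.outcomes, "employment")]
        vals[i, setdiff(.outcomes, "employment")] <-
          others * (1 - e) / sum(others)
      }
    }
    df[.outcomes] <- vals
  }
  out <- baseline_participation(df)
  attr(out, "adjusted") <- adjusted
  out
}

#' Arm-specific annual death probabilities
#'
#' Multiplies lifetable annual mortality rates by the OA excess hazard ratio
#' (both arms) and, when differential mortality is enabled, further scales
#' the uncontrolled arm by `womac_hr_per_10 ^ (womac_delta / 10)`. Adjusted
#' rates are converted to annual probabilities via [rate_to_probability()]
#' and capped at 1.
#'
#' @param table A [lifetable()].
#' @param adj A [mortality_adjustment()].
#' @param arm `"controlled"` or `"uncontrolled"`.
#' @param config A [model_config()].
#' @param womac_delta WOMAC difference between arms; defaults to the
#'   moderate-arm value in `config`. Ignored unless
#'   `config$differential_mortality` is `TRUE` and `arm = "uncontrolled"`.
#' @return A data frame `age`, `sex`, `prob` of annual death probabilities.
#' @export
adjust_mortality <- function(table, adj, arm = c("controlled", "uncontrolled"),
                             config = model_config(),
                             womac_delta = config$womac_delta_moderate) {
  arm <- match.arg(arm)
  stopifnot(inherits(adj, "mortality_adjustment"))
  hr <- adj$oa_excess_hr
  if (arm == "uncontrolled" && isTRUE(config$differential_mortality))
    hr <- hr * adj$womac_hr_per_10 ^ (womac_delta / 10)
  rate <- pmin(table$rate * hr, 1)
  prob <- ifelse(rate < 1, rate_to_probability(rate, 1, 1), 1)
  data.frame(age = table$age, sex = table$sex, prob = pmin(prob, 1))
}
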