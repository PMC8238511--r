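# One-way sensitivity analysis over CI bounds, probabilistic sensitivity
# analysis (Monte-Carlo over fitted parameter distributions) and the
# declarative scenario runner.

# All uncertain parameters of one comparison: the severity arm's relative
# effects plus the OA excess-mortality HR (and the WOMAC HR when the
# differential-mortality scenario is active). Baseline probabilities and
# fiscal tariffs are national statistics and are deliberately excluded.
sensitivity_parameters <- function(inputs, config, severity) {
  params <- list()
  eff <- inputs$effects[[severity]]
  if (!is.null(eff))
    for (k in seq_along(eff$effects)) {
      e <- eff$effects[[k]]
      id <- paste0(severity, ":", e$outcome,
                   if (!is.null(e$age_lower)) paste0(":", e$age_lower))
      params[[id]] <- list(id = id, kind = "effect", index = k,
                           point = e$point, ci_low = e$ci_low,
                           ci_high = e$ci_high)
    }
  m <- inputs$mortality
  params[["oa_excess_hr"]] <- list(id = "oa_excess_hr", kind = "hr",
                                   point = m$oa_excess_hr,
                                   ci_low = m$oa_excess_ci[1],
                                   ci_high = m$oa_excess_ci[2])
  if (isTRUE(config$differential_mortality))
    params[["womac_hr_per_10"]] <- list(id = "womac_hr_per_10",
                                        kind = "womac",
                                        point = m$womac_hr_per_10,
                                        ci_low = m$womac_ci[1],
                                        ci_high = m$womac_ci[2])
  params
}

# INT for one comparison with substituted parameter values.
# `values` is a named vector keyed by parameter id; missing ids keep the
# point estimate. Returns list(int, valid).
engine_int <- function(eng, params, severity, values = NULL) {
  inputs <- eng$inputs
  eff <- inputs$effects[[severity]]
  hr <- inputs$mortality$oa_excess_hr
  womac_hr <- inputs$mortality$womac_hr_per_10
  if (!is.null(values))
    for (id in names(values)) {
      p <- params[[id]]
      if (is.null(p)) stop("unknown parameter: ", id, call. = FALSE)
      if (p$kind == "effect") {
        eff$effects[[p$index]]$point <- values[[id]]
        eff$effects[[p$index]]$ci_low <-
          min(eff$effects[[p$index]]$ci_low, values[[id]])
        eff$effects[[p$index]]$ci_high <-
          max(eff$effects[[p$index]]$ci_high, values[[id]])
      } else if (p$kind == "hr") hr <- values[[id]]
      else if (p$kind == "womac") womac_hr <- values[[id]]
    }
  wm <- if (isTRUE(eng$config$differential_mortality))
    womac_hr ^ (switch(severity,
                       moderate = eng$config$womac_delta_moderate,
                       severe = eng$config$womac_delta_severe) / 10) else 1
  controlled <- engine_arm(eng, NULL, "controlled", hr = hr)
  uncontrolled <- engine_arm(eng, eff, severity, hr = hr, womac_mult = wm)
  list(int = incremental_net_tax(controlled, uncontrolled),
       valid = attr(uncontrolled, "valid"))
}

#' One-way sensitivity analysis
#'
#' Re-evaluates the incremental net tax with each uncertain parameter set in
#' turn to the lower and then the upper bound of its 95% CI, all other
#' parameters held at their point estimates. Entries are sorted by
#' descending INT range, ready for a tornado plot. Baseline participation
#' probabilities and fiscal tariffs (national statistics) are not varied.
#'
#' @param inputs Model input bundle (see [run_model()]).
#' @param config A [model_config()].
#' @param severity Which uncontrolled arm to compare: `"moderate"` or
#'   `"severe"`.
#' @param targets Optional character vector of parameter ids (as in the
#'   output) to restrict the analysis; default all uncertain parameters.
#' @return A tibble `parameter`, `low_int`, `high_int`, `base_int`, `range`
#'   sorted by descending `range`, with the base INT as attribute
#'   `"base_int"`.
#' @export
one_way_sensitivity <- function(inputs, config = model_config(),
                                severity = c("moderate", "severe"),
                                targets = NULL) {
  severity <- match.arg(severity)
  eng <- prepare_engine(inputs, config)
  params <- sensitivity_parameters(inputs, config, severity)
  if (!is.null(targets)) {
    unknown <- setdiff(targets, names(params))
    if (length(unknown))
      stop("unknown sensitivity targets: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    params <- params[targets]
  }
  base_int <- engine_int(eng, params, severity)$int
  rows <- lapply(params, function(p) {
    if (is.na(p$ci_low) || is.na(p$ci_high)) {
      warning("parameter '", p$id, "' has no CI; skipped", call. = FALSE)
      return(NULL)
    }
    lo <- engine_int(eng, params, severity,
                     setNames(p$ci_low, p$id))$int
    hi <- engine_int(eng, params, severity,
                     setNames(p$ci_high, p$id))$int
    if (base_int < min(lo, hi) - 1e-6 || base_int > max(lo, hi) + 1e-6)
      warning("base INT lies outside the bound interval for '", p$id,
              "' (non-monotone response)", call. = FALSE)
    tibble::tibble(parameter = p$id, low_int = lo, high_int = hi,
                   base_int = base_int, range = abs(hi - lo))
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- tibble::tibble(parameter = character(), low_int = numeric(),
                          high_int = numeric(), base_int = numeric(),
                          range = numeric())
  out <- out[order(-out$range), ]
  attr(out, "base_int") <- base_int
  out
}

# ---- distributions --------------------------------------------------------

#' Fit a sampling distribution to a point estimate and 95% CI
#'
#' Ratio measures (OR/RR/HR) get a lognormal with the log point estimate as
#' the median and `log(ci_high / ci_low) / (2 * 1.96)` as the log-SD;
#' probabilities get a beta matched by moments to the point and the
#' CI-implied SD `(ci_high - ci_low) / 3.92`; costs get a gamma matched the
#' same way. A zero-width CI yields a degenerate sampler. The fit is
#' validated at build time: beta/gamma means must be within 2% of the point
#' estimate (they are exact by construction) and the lognormal median must
#' equal the point.
#'
#' @param point Point estimate.
#' @param ci_low,ci_high 95% confidence bounds.
#' @param quantity `"ratio"`, `"probability"` or `"cost"`; selects the
#'   family when `kind = "auto"`.
#' @param kind `"auto"`, `"beta"`, `"gamma"` or `"lognormal"`.
#' @return An object of class `oaf_sampler`: list with `sample(n)`,
#'   `kind` and `params`.
#' @export
fit_distribution <- function(point, ci_low, ci_high,
                             quantity = c("ratio", "probability", "cost"),
                             kind = c("auto", "beta", "gamma",
                                      "lognormal")) {
  quantity <- match.arg(quantity)
  kind <- match.arg(kind)
  if (!(ci_low <= point && point <= ci_high))
    stop("need ci_low <= point <= ci_high", call. = FALSE)
  if (kind == "auto")
    kind <- switch(quantity, ratio = "lognormal", probability = "beta",
                   cost = "gamma")
  if (ci_low == ci_high) {
    out <- list(kind = "degenerate", params = list(point = point),
                sample = function(n) rep(point, n))
    return(structure(out, class = "oaf_sampler"))
  }
  if (kind == "lognormal") {
    if (ci_low <= 0 || point <= 0)
      stop("lognormal requires strictly positive point and bounds",
           call. = FALSE)
    sdlog <- log(ci_high / ci_low) / (2 * qnorm(0.975))
    meanlog <- log(point)
    params <- list(meanlog = meanlog, sdlog = sdlog)
    if (abs(exp(meanlog) - point) > 0.02 * point)
      stop("lognormal fit failed median validation", call. = FALSE)
    sample <- function(n) rlnorm(n, meanlog, sdlog)
  } else {
    m <- point
    v <- ((ci_high - ci_low) / (2 * qnorm(0.975))) ^ 2
    if (kind == "beta") {
      if (m <= 0 || m >= 1)
        stop("beta requires a point estimate strictly inside (0, 1)",
             call. = FALSE)
      if (v >= m * (1 - m))
        stop("CI too wide for a beta distribution at this mean",
             call. = FALSE)
      k <- m * (1 - m) / v - 1
      params <- list(shape1 = m * k, shape2 = (1 - m) * k)
      mean_fit <- params$shape1 / (params$shape1 + params$shape2)
      sample <- function(n) rbeta(n, params$shape1, params$shape2)
    } else {
      if (m <= 0 || ci_low < 0)
        stop("gamma requires positive point and non-negative bounds",
             call. = FALSE)
      params <- list(shape = m ^ 2 / v, rate = m / v)
      mean_fit <- params$shape / params$rate
      sample <- function(n) rgamma(n, params$shape, params$rate)
    }
    if (abs(mean_fit - m) > 0.02 * m)
      stop(kind, " fit failed mean validation", call. = FALSE)
  }
  structure(list(kind = kind, params = params, sample = sample),
            class = "oaf_sampler")
}

# Independent per-parameter substream: the seed for a parameter depends only
# on the master seed and the parameter id, so adding parameters never
# perturbs another parameter's draws.
substream_seed <- function(master, id) {
  h <- sum(utf8ToInt(id) * seq_along(utf8ToInt(id)))
  as.integer((as.numeric(master) * 48271 + h * 16807) %% 2147483647L) + 1L
}

#' Probabilistic sensitivity analysis
#'
#' Samples all uncertain parameters jointly and independently from
#' distributions fitted to their CIs ([fit_distribution()]), evaluates the
#' full model for each draw, and summarises the incremental net tax by its
#' mean and empirical 2.5th / 97.5th percentiles (credible interval). Draws
#' whose effects would push a probability past 1 are rejected and resampled
#' (an error is raised if more than 10% of draws are rejected).
#'
#' @param inputs Model input bundle.
#' @param config A [model_config()].
#' @param severity `"moderate"` or `"severe"`.
#' @param n Number of retained draws (>= 2). Default 10 000.
#' @param seed Master seed; per-parameter substreams are derived from it.
#' @param keep_draws Retain the per-draw INT vector.
#' @param sampler Optional joint sampler hook: a `function(n, params)`
#'   returning an `n`-row matrix with one named column per parameter id,
#'   replacing the independent per-parameter draws (use it to impose a
#'   correlation structure).
#' @return An object of class `psa_result`: `n_samples`, `mean_int`,
#'   `ci_low`, `ci_high`, `median_int`, `n_rejected`, `seed` and optionally
#'   `draws`.
#' @export
run_psa <- function(inputs, config = model_config(),
                    severity = c("moderate", "severe"), n = 10000,
                    seed = 1, keep_draws = FALSE, sampler = NULL) {
  severity <- match.arg(severity)
  if (n < 2) stop("`n` must be at least 2", call. = FALSE)
  eng <- prepare_engine(inputs, config)
  params <- sensitivity_parameters(inputs, config, severity)
  n_total <- n + max(ceiling(0.25 * n), 20)
  if (!is.null(sampler)) {
    set.seed(seed)
    draws <- sampler(n_total, params)
    missing_ids <- setdiff(names(params), colnames(draws))
    if (length(missing_ids))
      stop("joint sampler did not return column(s): ",
           paste(missing_ids, collapse = ", "), call. = FALSE)
    draws <- draws[, names(params), drop = FALSE]
  } else {
    draws <- matrix(NA_real_, n_total, length(params),
                    dimnames = list(NULL, names(params)))
    for (id in names(params)) {
      p <- params[[id]]
      marginal <- fit_distribution(p$point, p$ci_low, p$ci_high,
                                   quantity = "ratio")
      set.seed(substream_seed(seed, id))
      draws[, id] <- marginal$sample(n_total)
    }
  }
  ints <- numeric(n)
  rejected <- 0L
  ptr <- 1L
  for (i in seq_len(n)) {
    repeat {
      if (ptr > n_total)
        stop("PSA exhausted its resampling reserve", call. = FALSE)
      r <- engine_int(eng, params, severity, draws[ptr, ])
      ptr <- ptr + 1L
      if (r$valid) break
      rejected <- rejected + 1L
      if (rejected > 0.1 * n)
        stop("more than 10% of PSA draws produced invalid probabilities",
             call. = FALSE)
    }
    ints[i] <- r$int
  }
  structure(list(n_samples = n,
                 mean_int = mean(ints),
                 ci_low = unname(quantile(ints, 0.025)),
                 ci_high = unname(quantile(ints, 0.975)),
                 median_int = unname(quantile(ints, 0.5)),
                 n_rejected = rejected, seed = seed,
                 draws = if (keep_draws) ints else NULL),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf(
    "PSA (%d draws, seed %s): mean INT %.0f, 95%% CrI [%.0f, %.0f]\n",
    x$n_samples, format(x$seed), x$mean_int, x$ci_low, x$ci_high))
  if (x$n_rejected) cat("  rejected draws:", x$n_rejected, "\n")
  invisible(x)
}

# ---- scenarios ------------------------------------------------------------

#' Declare a scenario
#'
#' @param name Scenario name.
#' @param overrides Named list of [model_config()] fields to override
#'   (unknown fields raise an error at run time).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, overrides = list()) {
  structure(list(name = name, overrides = overrides),
            class = "scenario_spec")
}

#' The standard scenario set
#'
#' Base case plus the canonical assumption challenges: a lifetime horizon,
#' lifetime horizon with state pension age 67, the healthcare uplifts moved
#' down and up by 10 percentage points, differential pain-related mortality,
#' and disease onset at 45 with a 20-year work expectancy.
#'
#' @param config A [model_config()] supplying the base uplifts.
#' @return Named list of [scenario_spec()]s.
#' @export
standard_scenarios <- function(config = model_config()) {
  um <- config$healthcare_uplift_moderate
  us <- config$healthcare_uplift_severe
  list(
    base = scenario_spec("base"),
    lifetime = scenario_spec("lifetime", list(lifetime = TRUE)),
    spa67 = scenario_spec("spa67", list(lifetime = TRUE,
                                        state_pension_age = 67)),
    hc_uplift_minus10 = scenario_spec("hc_uplift_minus10", list(
      healthcare_uplift_moderate = um - 0.10,
      healthcare_uplift_severe = us - 0.10)),
    hc_uplift_plus10 = scenario_spec("hc_uplift_plus10", list(
      healthcare_uplift_moderate = um + 0.10,
      healthcare_uplift_severe = us + 0.10)),
    pain_mortality = scenario_spec("pain_mortality",
                                   list(differential_mortality = TRUE)),
    onset45 = scenario_spec("onset45", list(start_age = 45, horizon = 20)))
}

#' Run a single scenario
#'
#' @param spec A [scenario_spec()].
#' @param inputs Model input bundle.
#' @param config Base [model_config()] to override.
#' @param reference Optional `oafiscal_result` against which percent changes
#'   in INT are reported.
#' @return List with `name`, `result` (an `oafiscal_result`), `int` and
#'   `pct_change` (named vectors over severities; `pct_change` is `NA`
#'   without a reference).
#' @export
run_scenario <- function(spec, inputs, config = model_config(),
                         reference = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  unknown <- setdiff(names(spec$overrides), names(unclass(config)))
  if (length(unknown))
    stop("scenario '", spec$name, "' overrides unknown config field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  cfg <- validate_model_config(modifyList(unclass(config), spec$overrides))
  res <- run_model(inputs, cfg, quiet = TRUE)
  pct <- if (is.null(reference)) setNames(rep(NA_real_, 2),
                                          c("moderate", "severe")) else
    100 * (res$int - reference$int) / abs(reference$int)
  list(name = spec$name, result = res, int = res$int, pct_change = pct)
}

#' Run a set of scenarios
#'
#' Runs each scenario and reports INT and percent change against the first
#' scenario in the list (the reference, normally the base case).
#'
#' @param inputs Model input bundle.
#' @param config Base [model_config()].
#' @param scenarios Named list of [scenario_spec()]s; default
#'   [standard_scenarios()].
#' @return A long tibble: `scenario`, `severity`, `int`,
#'   `pct_change_vs_reference`, `incremental_earnings`,
#'   `incremental_gross_tax`, `incremental_transfers`, `healthcare_share`.
#' @export
run_scenarios <- function(inputs, config = model_config(),
                          scenarios = standard_scenarios(config)) {
  if (!length(scenarios))
    return(tibble::tibble(scenario = character(), severity = character(),
                          int = numeric(),
                          pct_change_vs_reference = numeric(),
                          incremental_earnings = numeric(),
                          incremental_gross_tax = numeric(),
                          incremental_transfers = numeric(),
                          healthcare_share = numeric()))
  reference <- run_scenario(scenarios[[1]], inputs, config)$result
  rows <- lapply(scenarios, function(sp) {
    sc <- run_scenario(sp, inputs, config, reference)
    res <- sc$result
    do.call(rbind, lapply(c("moderate", "severe"), function(sev) {
      u <- res[[sev]]; c0 <- res$controlled
      tibble::tibble(
        scenario = sc$name, severity = sev, int = unname(sc$int[sev]),
        pct_change_vs_reference = unname(sc$pct_change[sev]),
        incremental_earnings = c0$earnings - u$earnings,
        incremental_gross_tax = c0$gross_tax - u$gross_tax,
        incremental_transfers = c0$total_transfers - u$total_transfers,
        healthcare_share = healthcare_share(res, sev))
    }))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
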