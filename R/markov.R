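# Cohort engine: per-cycle transition matrices over the fiscal state space
# (tunnel unemployment / long-term sickness, absorbing disability and early
# retirement, post-SPA retirement, tax-neutral unknown, dead) and the
# matrix-product cohort trace.

.states <- c("EMPLOYED", "UNEMPLOYED", "LT_SICK", "DISABLED",
             "EARLY_RETIRED", "RETIRED", "UNKNOWN", "DEAD")

#' Fiscal states of the cohort model
#'
#' @return Character vector of the eight state names in canonical order.
#'   `UNEMPLOYED` and `LT_SICK` are one-cycle tunnel states; `DISABLED`,
#'   `EARLY_RETIRED`, `RETIRED` and `DEAD` permit no return to employment;
#'   `UNKNOWN` is tax-neutral and routes to employment after one cycle.
#' @export
fiscal_states <- function() .states

# Reallocation probabilities conditional on survival for states whose
# occupants re-enter the labour-market draw (employed + tunnel exits).
structural_row <- function(age, baseline, config) {
  e  <- baseline[["employment"]]
  u  <- baseline[["unemployment"]]
  s  <- baseline[["lt_sickness"]]
  er <- baseline[["early_retirement"]]
  di <- baseline[["disability"]]
  if (age > config$max_working_age) e <- 0
  if (age >= config$state_pension_age) { u <- 0; er <- 0 }
  tot <- e + u + s + er + di
  if (tot > 1 + 1e-9)
    stop(sprintf(
      "outcome probabilities sum to %.6f (> 1) at age %d", tot, age),
      call. = FALSE)
  resid <- max(0, 1 - tot)
  out <- setNames(numeric(8), .states)
  out[c("EMPLOYED", "UNEMPLOYED", "LT_SICK", "DISABLED", "EARLY_RETIRED")] <-
    c(e, u, s, di, er)
  if (age >= config$state_pension_age) {
    out["RETIRED"] <- resid          # non-employed survivors draw a pension
  } else if (isTRUE(config$unknown_recurrent)) {
    out["UNKNOWN"] <- resid
  } else {
    out["EMPLOYED"] <- out["EMPLOYED"] + resid
  }
  out
}

#' Build the one-cycle transition matrix at a given age
#'
#' Death is applied first from every living state; conditional on survival,
#' occupants of the employed, tunnel (unemployed, long-term sick) and
#' unknown states are reallocated using the age-specific baseline
#' probabilities, with the structural rules: no entry into unemployment or
#' early retirement at or after the state pension age, no entry into
#' employment above the maximum working age, residual mass to the
#' tax-neutral unknown state (to retirement after SPA), early retirees
#' converting to ordinary retirement at SPA, and disability, retirement and
#' death absorbing.
#'
#' @param age Attained age (years) at the start of the cycle.
#' @param baseline Named numeric vector (or one-row slice) with entries
#'   `employment`, `unemployment`, `lt_sickness`, `early_retirement`,
#'   `disability` for this age.
#' @param death_prob Annual death probability at this age.
#' @param config A [model_config()].
#' @return An 8 x 8 row-stochastic matrix with dimnames [fiscal_states()].
#' @export
build_transition_matrix <- function(age, baseline, death_prob,
                                    config = model_config()) {
  if (death_prob < 0 || death_prob > 1)
    stop("`death_prob` must lie in [0, 1]", call. = FALSE)
  d <- death_prob
  redist <- structural_row(age, baseline, config)
  m <- matrix(0, 8, 8, dimnames = list(.states, .states))
  for (s in c("EMPLOYED", "UNEMPLOYED", "LT_SICK"))
    m[s, ] <- (1 - d) * redist
  m["DISABLED", "DISABLED"] <- 1 - d
  if (age >= config$state_pension_age) {
    m["EARLY_RETIRED", "RETIRED"] <- 1 - d
    m["UNKNOWN", "RETIRED"] <- 1 - d
  } else {
    m["EARLY_RETIRED", "EARLY_RETIRED"] <- 1 - d
    m["UNKNOWN", "EMPLOYED"] <- 1 - d
  }
  m["RETIRED", "RETIRED"] <- 1 - d
  m[, "DEAD"] <- m[, "DEAD"] + d
  m["DEAD", ] <- 0
  m["DEAD", "DEAD"] <- 1
  bad <- which(abs(rowSums(m) - 1) > 1e-10)
  if (length(bad))
    stop("transition-matrix row does not sum to 1: ", .states[bad[1]],
         call. = FALSE)
  m
}

#' Initial occupancy vector
#'
#' The cohort enters distributed over the five outcome states according to
#' the (arm-specific) baseline probabilities at the entry age, with the
#' residual in the unknown state.
#'
#' @param baseline Named numeric vector of the five outcome probabilities at
#'   the entry age.
#' @return Named occupancy vector over [fiscal_states()] summing to 1.
#' @export
initial_occupancy <- function(baseline) {
  v <- setNames(numeric(8), .states)
  v[c("EMPLOYED", "UNEMPLOYED", "LT_SICK", "DISABLED", "EARLY_RETIRED")] <-
    c(baseline[["employment"]], baseline[["unemployment"]],
      baseline[["lt_sickness"]], baseline[["disability"]],
      baseline[["early_retirement"]])
  v["UNKNOWN"] <- max(0, 1 - sum(v))
  v
}

#' Run a cohort trace
#'
#' Iterates `occupancy(t + 1) = occupancy(t) %*% matrix(t)` over the supplied
#' per-cycle transition matrices. Works for any state space (matrices need
#' only be square, row-stochastic and mutually conformable), so small toy
#' chains can be traced with the same engine.
#'
#' @param initial Occupancy vector summing to 1.
#' @param matrices List of per-cycle transition matrices, one per cycle.
#' @param ages Optional vector of attained ages per cycle (length
#'   `length(matrices) + 1`).
#' @param arm,sex Optional labels stored as attributes.
#' @return A `cohort_trace`: a `(T + 1) x n_states` occupancy matrix with
#'   attributes `ages`, `arm`, `sex`.
#' @export
run_cohort <- function(initial, matrices, ages = NULL, arm = NA_character_,
                       sex = NA_character_) {
  if (!length(matrices)) stop("need at least one cycle", call. = FALSE)
  n <- length(initial)
  if (abs(sum(initial) - 1) > 1e-9 || any(initial < -1e-12))
    stop("`initial` must be a non-negative vector summing to 1",
         call. = FALSE)
  occ <- matrix(0, length(matrices) + 1, n)
  colnames(occ) <- names(initial) %||% colnames(matrices[[1]])
  occ[1, ] <- initial
  v <- matrix(initial, 1, n)
  for (t in seq_along(matrices)) {
    m <- matrices[[t]]
    if (!is.matrix(m) || nrow(m) != n || ncol(m) != n)
      stop("transition matrix for cycle ", t, " is not ", n, " x ", n,
           call. = FALSE)
    v <- v %*% m
    occ[t + 1, ] <- v
  }
  sums <- rowSums(occ)
  if (any(abs(sums - 1) > 1e-10) || any(occ < -1e-12))
    stop("cohort trace lost probability mass", call. = FALSE)
  structure(occ, class = c("cohort_trace", "matrix"),
            ages = ages, arm = arm, sex = sex)
}

#' Discounted life-years of a trace
#'
#' Sum over cycles of living occupancy at cycle start times the cycle length
#' (1 year), discounted at `discount_rate` with cycle 0 undiscounted.
#'
#' @param trace A `cohort_trace` whose states include `DEAD` (a trace with
#'   no `DEAD` column is treated as fully alive).
#' @param discount_rate Annual discount rate; default 0.
#' @return Discounted life-years (bounded by the number of cycles).
#' @export
life_years <- function(trace, discount_rate = 0) {
  T <- nrow(trace) - 1
  living <- if ("DEAD" %in% colnames(trace))
    1 - trace[seq_len(T), "DEAD"] else rep(1, T)
  sum(living / (1 + discount_rate) ^ (0:(T - 1)))
}

#' Tidy a cohort trace
#'
#' @param x A `cohort_trace`.
#' @param row.names,optional,... Standard [as.data.frame()] arguments
#'   (ignored).
#' @return A tibble with columns `cycle`, `age`, `state`, `occupancy`,
#'   `arm`, `sex`.
#' @export
as.data.frame.cohort_trace <- function(x, row.names = NULL, optional = FALSE,
                                       ...) {
  T1 <- nrow(x)
  states <- colnames(x)
  ages <- attr(x, "ages") %||% rep(NA_integer_, T1)
  out <- tibble::tibble(
    cycle = rep(0:(T1 - 1), times = length(states)),
    age = rep(ages, times = length(states)),
    state = rep(states, each = T1),
    occupancy = as.vector(unclass(x)),
    arm = attr(x, "arm"), sex = attr(x, "sex"))
  as.data.frame(out)
}
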