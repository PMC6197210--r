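#' Specify a reproductive-risk scenario
#'
#' A scenario is a named perturbation of the baseline age schedules,
#' emulating the ways in which the sex making the greater reproductive
#' investment can differ from the other: elevated infection during the
#' reproductive window, elevated infection-associated mortality (a `mu_d`
#' multiplier) with unchanged infection probability, elevated background
#' mortality, a fertility schedule rising with age (total fertility held at
#' the baseline amount, isolating the schedule effect), fertility discounted
#' by sensitivity (for example reproduction lost to anti-fetal immune
#' responses), and infection concentrated early or late in life at equal
#' total incidence.
#'
#' @param kind One of `"baseline"`, `"infection_boost"`,
#'   `"infection_mortality_boost"`, `"background_mortality_boost"`,
#'   `"fertility_rising_with_age"`, `"fertility_sensitivity_penalty"`,
#'   `"infection_early"`, `"infection_late"`.
#' @param boost_factor Positive multiplier applied inside the window for the
#'   boost scenarios.
#' @param window Integer age interval `c(from, to)` the boost applies to;
#'   defaults to maturity through the final age class.
#' @param penalty_c Coefficient in `[0, 1]` of the multiplicative fertility
#'   penalty `1 - penalty_c * s_e`.
#' @param pivot Age splitting early from late infection; defaults to the
#'   age at maturity.
#' @return A list of class `"scenario_spec"`.
#' @examples
#' scenario_spec("infection_boost", boost_factor = 2)
#' @export
scenario_spec <- function(kind = c("baseline", "infection_boost",
                                   "infection_mortality_boost",
                                   "background_mortality_boost",
                                   "fertility_rising_with_age",
                                   "fertility_sensitivity_penalty",
                                   "infection_early", "infection_late"),
                          boost_factor = 2, window = NULL, penalty_c = 0.5,
                          pivot = NULL) {
  kind <- match.arg(kind)
  if (boost_factor <= 0) abort("`boost_factor` must be positive.")
  if (penalty_c < 0 || penalty_c > 1) abort("`penalty_c` must lie in [0, 1].")
  structure(list(kind = kind, boost_factor = boost_factor, window = window,
                 penalty_c = penalty_c, pivot = pivot),
            class = "scenario_spec")
}

#' Materialise a scenario into age schedules
#'
#' Applies the perturbation described by a [scenario_spec()] to a baseline
#' [age_schedules()] object. Infection probabilities pushed above 1 are
#' capped at 1 with a warning. The fertility--sensitivity penalty does not
#' alter the stored schedule; it is recorded in the `fertility_penalty`
#' attribute and applied at evaluation time by [build_leslie()], because the
#' penalty depends on the strategy under evaluation.
#'
#' @param spec A [scenario_spec()].
#' @param base The baseline [age_schedules()].
#' @return An `"age_schedules"` tibble with attributes `fertility_penalty`
#'   and `scenario`.
#' @examples
#' make_schedule(scenario_spec("infection_boost"), age_schedules(n_ages = 30))
#' @export
make_schedule <- function(spec, base = age_schedules()) {
  stopifnot(inherits(spec, "scenario_spec"), inherits(base, "age_schedules"))
  A <- nrow(base)
  m <- attr(base, "maturity")
  win <- spec$window %||% c(m, A)
  if (win[1] < 1 || win[2] > A || win[1] > win[2]) {
    abort("`window` must be an increasing age interval within [1, n_ages].")
  }
  idx <- seq(win[1], win[2])
  out <- base
  penalty <- 0
  switch(spec$kind,
    baseline = NULL,
    infection_boost = {
      ix <- out$i_x
      ix[idx] <- ix[idx] * spec$boost_factor
      if (any(ix > 1)) {
        warn("boosted infection probabilities exceed 1; capped at 1.")
        ix <- pmin(ix, 1)
      }
      out$i_x <- ix
    },
    infection_mortality_boost = {
      out$mud_multiplier[idx] <- out$mud_multiplier[idx] * spec$boost_factor
    },
    background_mortality_boost = {
      out$mu_b[idx] <- out$mu_b[idx] * spec$boost_factor
    },
    fertility_rising_with_age = {
      rep_ages <- seq(m, A)
      total <- sum(out$f[rep_ages])
      ramp <- seq(0.2, 1.8, length.out = length(rep_ages))
      out$f[rep_ages] <- ramp * total / sum(ramp)
    },
    fertility_sensitivity_penalty = {
      penalty <- spec$penalty_c
    },
    infection_early = {
      pivot <- spec$pivot %||% m
      total <- sum(out$i_x)
      ix <- rep(0, A)
      ix[seq_len(pivot - 1L)] <- total / (pivot - 1L)
      if (any(ix > 1)) {
        warn("redistributed infection probabilities exceed 1; capped at 1.")
        ix <- pmin(ix, 1)
      }
      out$i_x <- ix
    },
    infection_late = {
      pivot <- spec$pivot %||% m
      total <- sum(out$i_x)
      ix <- rep(0, A)
      ix[seq(pivot, A)] <- total / (A - pivot + 1L)
      if (any(ix > 1)) {
        warn("redistributed infection probabilities exceed 1; capped at 1.")
        ix <- pmin(ix, 1)
      }
      out$i_x <- ix
    }
  )
  attr(out, "fertility_penalty") <- penalty
  attr(out, "scenario") <- spec$kind
  out
}

#' Run the cross-scenario experiment table
#'
#' For each scenario: materialises its schedules, finds the lifespan-optimal
#' sensitivity by [optimize_lifespan_sensitivity()], and records the optimal
#' strategy, the growth rate at the optimum, and (optionally) the per-age
#' survivorship, stable structure, reproductive values and survival
#' sensitivities at the optimum. Deterministic.
#'
#' @param specs A list of [scenario_spec()] objects (or a single one).
#' @param params An [immune_params()] object.
#' @param base Baseline [age_schedules()] shared by all scenarios.
#' @param curves If `TRUE` (default) attach a list-column of per-age tibbles.
#' @inheritParams optimize_lifespan_sensitivity
#' @return A tibble of class `"scenario_table"` with one row per scenario:
#'   `scenario`, `boost_factor`, `penalty_c`, `optimal_sp`, `optimal_se`,
#'   `lambda`, and (if `curves`) `ages`, a list-column with columns `age`,
#'   `survival`, `survivorship`, `w_norm`, `v`, `sens_survival`.
#' @examples
#' p <- immune_params(gamma = 4, eta = 0.8, rho = 0.01, mu_d = 1)
#' specs <- list(scenario_spec("baseline"), scenario_spec("infection_boost"))
#' run_scenario_table(specs, p, base = age_schedules(n_ages = 30),
#'                    curves = FALSE)
#' @export
run_scenario_table <- function(specs, params, base = age_schedules(),
                               curves = TRUE, n_grid = 257, tol = 1e-7) {
  if (inherits(specs, "scenario_spec")) specs <- list(specs)
  if (length(specs) == 0) abort("`specs` must be a non-empty list.")
  rows <- map(specs, function(sp) {
    sched <- make_schedule(sp, base)
    pen <- attr(sched, "fertility_penalty")
    opt <- optimize_lifespan_sensitivity(sched, params,
                                         fertility_penalty = pen,
                                         n_grid = n_grid, tol = tol)
    row <- tibble(scenario = sp$kind, boost_factor = sp$boost_factor,
                  penalty_c = pen, optimal_sp = opt$s_p,
                  optimal_se = opt$s_e, lambda = opt$lambda)
    if (curves) {
      M <- build_leslie(sched, params, opt$s_p, fertility_penalty = pen)
      es <- eigen_summary(M)
      s_x <- survival_by_age(sched, params, opt$s_p)
      ages <- tibble(age = sched$age, survival = s_x,
                     survivorship = c(1, cumprod(s_x[-length(s_x)])),
                     w_norm = es$ages$w_norm, v = es$ages$v,
                     sens_survival = es$ages$sens_survival)
      row$ages <- list(ages)
    }
    row
  })
  out <- list_rbind(rows)
  class(out) <- c("scenario_table", class(out))
  out
}

#' @rdname run_scenario_table
#' @param x A `"scenario_table"`.
#' @param ... Unused.
#' @export
tidy.scenario_table <- function(x, ...) {
  if (!"ages" %in% names(x)) {
    return(as_tibble(x))
  }
  x |>
    dplyr::select("scenario", "ages") |>
    tidyr::unnest("ages")
}

#' @rdname run_scenario_table
#' @param object A `"scenario_table"`.
#' @export
autoplot.scenario_table <- function(object, ...) {
  long <- tidy(object)
  if (!"age" %in% names(long)) {
    abort("re-run `run_scenario_table()` with `curves = TRUE` to plot.")
  }
  long <- pivot_longer(long[, c("scenario", "age", "survivorship", "w_norm", "v")],
                       c("survivorship", "w_norm", "v"),
                       names_to = "quantity", values_to = "value")
  ggplot(long, aes(x = .data$age, y = .data$value,
                   colour = .data$scenario)) +
    geom_line() +
    facet_wrap(~ .data$quantity, scales = "free_y") +
    labs(x = "age", y = NULL, colour = "scenario") +
    theme_minimal()
}
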