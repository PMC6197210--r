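#' Age-specific survival under competing immune hazards
#'
#' Survival of an age class over one time step is the exponential of the
#' summed competing mortality hazards,
#' \deqn{s_x = \exp\{-[\mu_b + (1-i_x)\,\mu_i\,(1-s_p)
#'   + i_x\,\mu_d\,e^{-\gamma(1-s_p)} + i_x\,\mu_{id}\,(1-e^{-\gamma(1-s_p)})]\},}
#' where \eqn{e^{-\gamma(1-s_p)} = 1 - s_e} is the false-negative rate:
#' uninfected hosts (probability \eqn{1-i_x}) risk immunopathology on false
#' positives, infected hosts risk \eqn{\mu_d} when the infection is missed and
#' \eqn{\mu_{id}} when it is detected and fought.
#'
#' @param params An [immune_params()] object.
#' @param s_p Specificity; vectorised over `[0, 1]`.
#' @param mu_d Undetected-infection hazard; defaults to `params$mu_d`.
#'   Vectorised (recycled against `s_p`). Under an active hazard trade-off,
#'   `mu_i` and `mu_id` are recomputed from each `mu_d`.
#' @return Survival probabilities in `(0, 1]`.
#' @examples
#' p <- immune_params(gamma = 4, eta = 0.8, rho = 0.01, mu_b = 1 / 60,
#'                    mu_d = 1, i_x = 0.5)
#' survival_age(p, s_p = 0.5)   # ~0.8199
#' @export
survival_age <- function(params, s_p, mu_d = params$mu_d) {
  stopifnot(inherits(params, "immune_params"))
  if (any(s_p < 0 | s_p > 1)) abort("`s_p` must lie in [0, 1].")
  if (any(mu_d < 0)) abort("`mu_d` must be non-negative.")
  hz <- hazards_at(params, mu_d)
  fn <- exp(-params$gamma * (1 - s_p))  # false-negative rate, 1 - s_e
  H <- params$mu_b +
    (1 - params$i_x) * hz$mu_i * (1 - s_p) +
    params$i_x * mu_d * fn +
    params$i_x * hz$mu_id * (1 - fn)
  exp(-H)
}

#' Derivative of age-specific survival with respect to specificity
#'
#' The marginal survival value of specificity,
#' \deqn{\frac{d s_x}{d s_p} = s_x\,[(1-i_x)\mu_i
#'   - \gamma i_x \mu_d e^{-\gamma(1-s_p)}
#'   + \gamma i_x \mu_{id} e^{-\gamma(1-s_p)}],}
#' balances the gain from fewer false positives against the loss from
#' missed and (beneficially) fought infections. Its root is the within-age
#' optimal specificity, [optimal_specificity()].
#'
#' @inheritParams survival_age
#' @return The derivative \eqn{d s_x / d s_p}, vectorised like `s_p`.
#' @export
dsurvival_dsp <- function(params, s_p, mu_d = params$mu_d) {
  s_x <- survival_age(params, s_p, mu_d)
  hz <- hazards_at(params, mu_d)
  fn <- exp(-params$gamma * (1 - s_p))
  s_x * ((1 - params$i_x) * hz$mu_i -
           params$gamma * params$i_x * mu_d * fn +
           params$gamma * params$i_x * hz$mu_id * fn)
}

#' Derivative of age-specific survival with respect to effector magnitude
#'
#' With the exponential hazard trade-off substituted
#' (\eqn{\mu_i = e^{-\eta\mu_d}}, \eqn{\mu_{id} = \rho e^{-\eta\mu_d}}),
#' \deqn{\frac{d s_x}{d \mu_d} = s_x\,[\eta(1-i_x)(1-s_p)e^{-\eta\mu_d}
#'   - i_x e^{-\gamma(1-s_p)}
#'   + \eta i_x \rho (1 - e^{-\gamma(1-s_p)}) e^{-\eta\mu_d}].}
#' Its root is the within-age optimal effector setting, [optimal_mud()].
#'
#' @inheritParams survival_age
#' @return The derivative \eqn{d s_x / d \mu_d}, vectorised like `mu_d`.
#' @export
dsurvival_dmud <- function(params, s_p, mu_d = params$mu_d) {
  if (params$tradeoff != "exponential") {
    abort("`dsurvival_dmud()` requires the exponential hazard trade-off.")
  }
  s_x <- survival_age(params, s_p, mu_d)
  fn <- exp(-params$gamma * (1 - s_p))
  em <- exp(-params$eta * mu_d)
  s_x * (params$eta * (1 - params$i_x) * (1 - s_p) * em -
           params$i_x * fn +
           params$eta * params$i_x * params$rho * (1 - fn) * em)
}

#' Closed-form within-age optimal specificity
#'
#' The specificity maximising [survival_age()] within one age class is
#' \deqn{s_p^* = \frac{1}{\gamma}\left[\log\frac{\mu_i}{\mu_d-\mu_{id}}
#'   + \log\frac{1-i_x}{i_x} + \log\frac{1}{\gamma}\right] + 1,}
#' clamped to the feasible interval `[0, 1]`. Baseline mortality `mu_b` does
#' not appear: it scales survival uniformly and cannot move the optimum.
#' Degenerate incidence is handled as an explicit boundary case rather than
#' passed to the logarithms: with `i_x = 0` there is nothing to detect and
#' \eqn{s_p^* = 1}; with `i_x = 1` false positives are impossible and
#' \eqn{s_p^* = 0}.
#'
#' @inheritParams survival_age
#' @param mu_d Effector setting at which the hazards are evaluated; defaults
#'   to `params$mu_d`.
#' @return A one-row tibble of class `"immune_strategy"` with columns `s_p`,
#'   `s_e`, `mu_d` and `interior` (`TRUE` when the unclamped optimum lies
#'   strictly inside `(0, 1)`).
#' @section Errors:
#' `mu_d <= mu_id` makes the response never beneficial and the log ratio
#' undefined; this raises a trade-off degeneracy error.
#' @examples
#' p <- immune_params(gamma = 4, mu_i = 0.5, mu_id = 0, mu_d = 1,
#'                    i_x = 0.5, tradeoff = "fixed")
#' optimal_specificity(p)   # s_p* ~ 0.48014
#' @export
optimal_specificity <- function(params, mu_d = params$mu_d) {
  stopifnot(inherits(params, "immune_params"))
  hz <- hazards_at(params, mu_d)
  if (params$i_x == 0) return(new_strategy(1, params$gamma, mu_d, FALSE))
  if (params$i_x == 1) return(new_strategy(0, params$gamma, mu_d, FALSE))
  if (mu_d <= hz$mu_id) {
    abort(paste0("degenerate trade-off: `mu_d` must exceed `mu_id` for a ",
                 "response to be beneficial (log ratio undefined)."))
  }
  g <- params$gamma
  raw <- (log(hz$mu_i / (mu_d - hz$mu_id)) +
            log((1 - params$i_x) / params$i_x) + log(1 / g)) / g + 1
  sp <- min(1, max(0, raw))
  new_strategy(sp, g, mu_d, interior = (raw > 0 && raw < 1))
}

#' Closed-form within-age optimal effector setting
#'
#' Under the exponential hazard trade-off the undetected-infection hazard
#' maximising [survival_age()] at a given specificity is
#' \deqn{\mu_d^* = \frac{1}{\eta}\left[\log\eta
#'   + \log\{(1-i_x)(1-s_p) + i_x\rho(1-e^{-\gamma(1-s_p)})\}
#'   - \log\{i_x e^{-\gamma(1-s_p)}\}\right],}
#' floored at 0 (hazards cannot be negative; the floor corresponds to the
#' maximal feasible effector response).
#'
#' @inheritParams survival_age
#' @param s_p Specificity at which the effector magnitude is optimised.
#' @return The optimal `mu_d` (a single non-negative number) with attribute
#'   `interior` indicating whether the unfloored value was positive.
#' @section Errors:
#' `s_p = 1` with `rho = 0` leaves the objective flat in the detected-infection
#' term (no response is ever engaged) and raises a degeneracy error; `i_x` on
#' the boundary `{0, 1}` is rejected for the same reason as in
#' [optimal_specificity()].
#' @examples
#' p <- immune_params(gamma = 4, eta = 0.8, rho = 0.01, i_x = 0.5)
#' optimal_mud(p, s_p = 0.5)   # ~1.376
#' @export
optimal_mud <- function(params, s_p) {
  stopifnot(inherits(params, "immune_params"))
  if (params$tradeoff != "exponential") {
    abort("`optimal_mud()` requires the exponential hazard trade-off.")
  }
  if (params$i_x <= 0 || params$i_x >= 1) {
    abort("`i_x` must lie strictly inside (0, 1) for an interior optimum.")
  }
  if (s_p >= 1 && params$rho == 0) {
    abort("degenerate objective: `s_p = 1` with `rho = 0` never engages infection.")
  }
  g <- params$gamma
  fn <- exp(-g * (1 - s_p))
  raw <- (log(params$eta) +
            log((1 - params$i_x) * (1 - s_p) + params$i_x * params$rho * (1 - fn)) -
            log(params$i_x * fn)) / params$eta
  structure(max(0, raw), interior = raw > 0)
}

new_strategy <- function(s_p, gamma, mu_d, interior) {
  out <- tibble(s_p = s_p,
                s_e = sensitivity_from_specificity(s_p, gamma),
                mu_d = mu_d, interior = interior)
  class(out) <- c("immune_strategy", class(out))
  out
}

#' Numerical within-age optimal strategy (grid scan plus refinement)
#'
#' Brute-force maximiser of [survival_age()] used as the independent check on
#' the closed-form optima, and as the only route when both axes are free
#' (where the survival surface is bimodal and a purely local optimiser could
#' climb the wrong peak). A coarse global grid locates the basin; golden
#' section search then refines the argument to `tol`.
#'
#' @inheritParams survival_age
#' @param free Which argument(s) to optimise: `"s_p"`, `"mu_d"`, or `"both"`.
#' @param s_p Fixed specificity when `free = "mu_d"`.
#' @param n_grid Number of coarse grid points per axis (at least 512).
#' @param mud_max Upper bound of the `mu_d` search interval.
#' @param tol Absolute tolerance on the argument for the refinement stage.
#' @return A one-row tibble of class `"immune_strategy"` with columns `s_p`,
#'   `s_e`, `mu_d`, `interior` and `survival`.
#' @examples
#' p <- immune_params(gamma = 4, mu_i = 0.5, mu_id = 0, mu_d = 1,
#'                    i_x = 0.5, tradeoff = "fixed")
#' optimal_strategy_numeric(p)
#' @export
optimal_strategy_numeric <- function(params, free = c("s_p", "mu_d", "both"),
                                     s_p = NULL, n_grid = 512, mud_max = 20,
                                     tol = 1e-8) {
  stopifnot(inherits(params, "immune_params"))
  free <- match.arg(free)
  n_grid <- max(512L, n_grid)
  if (free == "s_p") {
    f <- function(x) survival_age(params, x)
    sp <- grid_refine(f, 0, 1, n_grid, tol)
    out <- new_strategy(sp, params$gamma, params$mu_d,
                        interior = sp > tol && sp < 1 - tol)
  } else if (free == "mu_d") {
    if (is.null(s_p)) abort("supply `s_p` when optimising over `mu_d`.")
    f <- function(x) survival_age(params, s_p, mu_d = x)
    md <- grid_refine(f, 0, mud_max, n_grid, tol)
    out <- new_strategy(s_p, params$gamma, md, interior = md > tol)
  } else {
    # alternate coordinate-wise grid+refine sweeps from the best 2-D grid cell
    sp_ax <- seq(0, 1, length.out = n_grid)
    md_ax <- seq(0, mud_max, length.out = n_grid)
    sv <- vapply(md_ax, function(m) survival_age(params, sp_ax, mu_d = m),
                 numeric(n_grid))
    ij <- arrayInd(which.max(sv), dim(sv))
    sp <- sp_ax[ij[1]]; md <- md_ax[ij[2]]
    for (k in 1:6) {
      sp <- grid_refine(function(x) survival_age(params, x, mu_d = md),
                        0, 1, n_grid, tol)
      md <- grid_refine(function(x) survival_age(params, sp, mu_d = x),
                        0, mud_max, n_grid, tol)
    }
    out <- new_strategy(sp, params$gamma, md,
                        interior = sp > tol && sp < 1 - tol && md > tol)
  }
  out$survival <- survival_age(params, out$s_p, mu_d = out$mu_d)
  out
}

# coarse grid argmax + golden-section refinement on the bracketing cells
grid_refine <- function(f, lo, hi, n_grid, tol) {
  xs <- seq(lo, hi, length.out = n_grid)
  i <- which.max(f(xs))
  golden_section(f, xs[max(1L, i - 1L)], xs[min(n_grid, i + 1L)], tol)
}

# deterministic golden-section maximisation; fixed shrink factor so equal
# objectives produce bit-identical arguments
golden_section <- function(f, lo, hi, tol = 1e-8) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c_ <- b - gr * (b - a); d_ <- a + gr * (b - a)
  fc <- f(c_); fd <- f(d_)
  while (b - a > tol) {
    if (fc >= fd) {
      b <- d_; d_ <- c_; fd <- fc
      c_ <- b - gr * (b - a); fc <- f(c_)
    } else {
      a <- c_; c_ <- d_; fc <- fd
      d_ <- a + gr * (b - a); fd <- f(d_)
    }
  }
  (a + b) / 2
}

#' Direction of the optimal sensitivity's response to reduced effector
#' allocation
#'
#' The ratio \eqn{R = \mu_i/(\mu_d - \mu_{id})} indexes how damaging the
#' immune response is relative to the net cost of undetected infection; large
#' `R` corresponds to a large-magnitude response. At an interior optimum the
#' optimal sensitivity is \eqn{s_e^* = 1 - (1-i_x)R/(\gamma i_x)}, so
#' \eqn{d s_e^*/d R = -(1-i_x)/(\gamma i_x) < 0}: reducing allocation towards
#' `R` always selects for increased sensitivity, whatever the parameters.
#'
#' @inheritParams survival_age
#' @return A one-row tibble with columns `R`, `s_e_opt`, `dse_dR` and `sign`
#'   (`-1L` at any interior optimum). A boundary (clamped) optimum is flagged
#'   indeterminate: `sign = NA_integer_` with a warning.
#' @examples
#' p <- immune_params(gamma = 4, mu_i = 0.5, mu_id = 0, mu_d = 1,
#'                    i_x = 0.5, tradeoff = "fixed")
#' response_to_reduced_R(p)$sign
#' @export
response_to_reduced_R <- function(params) {
  stopifnot(inherits(params, "immune_params"))
  hz <- hazards_at(params, params$mu_d)
  if (params$mu_d <= hz$mu_id) abort("`mu_d` must exceed `mu_id`.")
  if (params$i_x <= 0 || params$i_x >= 1) {
    abort("`i_x` must lie strictly inside (0, 1).")
  }
  R <- hz$mu_i / (params$mu_d - hz$mu_id)
  opt <- optimal_specificity(params)
  se_opt <- 1 - (1 - params$i_x) * R / (params$gamma * params$i_x)
  dse <- -(1 - params$i_x) / (params$gamma * params$i_x)
  if (!opt$interior) {
    warn("optimum sits on the feasibility boundary; response direction indeterminate.")
    sgn <- NA_integer_
  } else {
    sgn <- as.integer(sign(dse))
  }
  tibble(R = R, s_e_opt = se_opt, dse_dR = dse, sign = sgn)
}
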