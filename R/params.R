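#' Bundle the hazard and trade-off parameters for one age class
#'
#' An `immune_params` object collects the phenomenological mortality hazards
#' and trade-off shape parameters that determine survival of one age class:
#' the discrimination power `gamma` of the sensitivity--specificity trade-off,
#' the effector trade-off shape `eta`, the infected-immunopathology fraction
#' `rho`, the baseline hazard `mu_b`, the undetected-infection hazard `mu_d`
#' (which doubles as the inverse index of effector magnitude), the
#' immunopathology hazards `mu_i` (false positive) and `mu_id` (true
#' positive), and the probability of infection `i_x` at the focal age.
#'
#' Under the `"exponential"` trade-off (the default) the immunopathology
#' hazards are tied to effector magnitude through
#' \eqn{\mu_i = \exp(-\eta \mu_d)} and \eqn{\mu_{id} = \rho \mu_i}, so they
#' are recomputed from `mu_d` wherever `mu_d` varies. `"linear"` substitutes
#' \eqn{\mu_i = \max(0, 1 - \eta \mu_d)}, a robustness variant with the same
#' negative slope. `"fixed"` treats `mu_i` and `mu_id` as free constants,
#' in which case both must be supplied.
#'
#' @param gamma Discrimination power of the ROC trade-off; positive.
#' @param eta Effector trade-off shape; positive.
#' @param rho Fraction of `mu_i` experienced as damage during detected
#'   infection; non-negative.
#' @param mu_b Baseline mortality hazard per time step; non-negative.
#' @param mu_d Mortality hazard of an undetected infection; non-negative.
#' @param i_x Probability of infection at the focal age, in `[0, 1]`.
#' @param mu_i,mu_id Immunopathology hazards outside/during infection. Ignored
#'   (derived from `mu_d`) unless `tradeoff = "fixed"`.
#' @param tradeoff Closure linking `mu_i`, `mu_id` to `mu_d`: one of
#'   `"exponential"`, `"linear"`, `"fixed"`.
#'
#' @return A list of class `"immune_params"`.
#' @seealso [effector_hazards()], [survival_age()]
#' @examples
#' p <- immune_params(gamma = 4, eta = 0.8, rho = 0.01, mu_b = 1 / 60,
#'                    mu_d = 1, i_x = 0.5)
#' survival_age(p, s_p = 0.5)
#' @export
immune_params <- function(gamma, eta = NULL, rho = 0, mu_b = 0, mu_d = 0,
                          i_x = 0.5, mu_i = NULL, mu_id = NULL,
                          tradeoff = c("exponential", "linear", "fixed")) {
  tradeoff <- match.arg(tradeoff)
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0) {
    abort("`gamma` must be a single positive number.")
  }
  if (tradeoff != "fixed") {
    if (is.null(eta) || eta <= 0) {
      abort("`eta` must be a single positive number for a hazard trade-off.")
    }
  } else {
    if (is.null(mu_i) || is.null(mu_id)) {
      abort("`mu_i` and `mu_id` must be supplied when `tradeoff = \"fixed\"`.")
    }
    eta <- eta %||% NA_real_
  }
  hz <- c(mu_b = mu_b, mu_d = mu_d,
          mu_i = mu_i %||% NA_real_, mu_id = mu_id %||% NA_real_)
  if (any(!is.na(hz) & hz < 0)) abort("hazards must be non-negative.")
  if (rho < 0) abort("`rho` must be non-negative.")
  if (i_x < 0 || i_x > 1) abort("`i_x` must lie in [0, 1].")
  p <- list(gamma = gamma, eta = eta, rho = rho, mu_b = mu_b, mu_d = mu_d,
            mu_i = mu_i, mu_id = mu_id, i_x = i_x, tradeoff = tradeoff)
  structure(p, class = "immune_params")
}

#' @export
print.immune_params <- function(x, ...) {
  hz <- hazards_at(x, x$mu_d)
  cat("<immune_params> tradeoff:", x$tradeoff, "\n")
  cat(sprintf("  gamma = %g, eta = %g, rho = %g, i_x = %g\n",
              x$gamma, x$eta %||% NA, x$rho, x$i_x))
  cat(sprintf("  mu_b = %g, mu_d = %g, mu_i = %g, mu_id = %g\n",
              x$mu_b, x$mu_d, hz$mu_i, hz$mu_id))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Immunopathology hazards implied by effector magnitude
#'
#' The strength of the effector response is indexed inversely by `mu_d`: a
#' large response controls infection well (low `mu_d`) but is autoreactive.
#' Under the exponential trade-off the false-positive immunopathology hazard
#' is \eqn{\mu_i = \exp(-\eta \mu_d)} and the damage during a detected
#' infection is the fraction \eqn{\rho} of it, \eqn{\mu_{id} = \rho \mu_i}.
#'
#' @param mu_d Undetected-infection hazard(s); non-negative, vectorised.
#' @param eta Trade-off shape; positive.
#' @param rho Infected-damage fraction; non-negative.
#' @param tradeoff `"exponential"` (default) or `"linear"`
#'   (\eqn{\mu_i = \max(0, 1 - \eta \mu_d)}).
#' @return A tibble with columns `mu_d`, `mu_i`, `mu_id`.
#' @examples
#' effector_hazards(mu_d = c(0, 1), eta = 0.8, rho = 0.01)
#' @export
effector_hazards <- function(mu_d, eta, rho,
                             tradeoff = c("exponential", "linear")) {
  tradeoff <- match.arg(tradeoff)
  if (any(mu_d < 0)) abort("`mu_d` must be non-negative.")
  if (eta <= 0) abort("`eta` must be positive.")
  mu_i <- switch(tradeoff,
                 exponential = exp(-eta * mu_d),
                 linear = pmax(0, 1 - eta * mu_d))
  tibble(mu_d = mu_d, mu_i = mu_i, mu_id = rho * mu_i)
}

# hazards mu_i, mu_id at a given mu_d, honouring the closure in `params`
hazards_at <- function(params, mu_d) {
  switch(params$tradeoff,
    exponential = {
      mu_i <- exp(-params$eta * mu_d)
      list(mu_i = mu_i, mu_id = params$rho * mu_i)
    },
    linear = {
      mu_i <- pmax(0, 1 - params$eta * mu_d)
      list(mu_i = mu_i, mu_id = params$rho * mu_i)
    },
    fixed = list(mu_i = params$mu_i, mu_id = params$mu_id)
  )
}

#' Sensitivity implied by specificity on the discrimination trade-off
#'
#' Self/non-self discrimination obeys the ROC-style link
#' \eqn{s_e = 1 - \exp(-\gamma (1 - s_p))}: sensitivity falls as specificity
#' rises, with the discrimination power \eqn{\gamma} setting how much
#' sensitivity is available at a given specificity (higher \eqn{\gamma},
#' better-separated self and non-self).
#'
#' @param s_p Specificity, in `[0, 1]`; vectorised.
#' @param gamma Discrimination power; positive.
#' @return Sensitivity in `[0, 1)`.
#' @seealso [specificity_from_sensitivity()] for the inverse.
#' @examples
#' sensitivity_from_specificity(c(0, 0.5, 1), gamma = 4)
#' @export
sensitivity_from_specificity <- function(s_p, gamma) {
  if (any(s_p < 0 | s_p > 1)) abort("`s_p` must lie in [0, 1].")
  if (any(gamma <= 0)) abort("`gamma` must be positive.")
  1 - exp(-gamma * (1 - s_p))
}

#' Specificity implied by sensitivity (inverse of the ROC link)
#'
#' Inverts the discrimination trade-off: \eqn{s_p = 1 + \log(1 - s_e)/\gamma}.
#' Sensitivities at or above the attainable ceiling \eqn{1 - e^{-\gamma}}
#' are infeasible and rejected.
#'
#' @param s_e Sensitivity, in `[0, 1 - exp(-gamma))`; vectorised.
#' @inheritParams sensitivity_from_specificity
#' @return Specificity in `(0, 1]`.
#' @export
specificity_from_sensitivity <- function(s_e, gamma) {
  if (any(gamma <= 0)) abort("`gamma` must be positive.")
  if (any(s_e < 0 | s_e >= 1 - exp(-gamma))) {
    abort(sprintf(
      "`s_e` must lie in [0, 1 - exp(-gamma)) = [0, %.6f) to be attainable.",
      1 - exp(-gamma)))
  }
  1 + log(1 - s_e) / gamma
}
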