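#' Age schedules of infection, mortality and fertility
#'
#' Builds the per-age inputs of the demographic layer as a tidy tibble:
#' infection probability `i_x`, background mortality hazard `mu_b`, fertility
#' `f` (zero before the age at maturity), and a per-age multiplier on the
#' undetected-infection hazard `mu_d` (used to localise infection-associated
#' mortality in particular life stages). Ages are 1-based and one age class
#' elapses per time step; with the default `mu_b = 1/60` the step is a year
#' of a long-lived vertebrate's life.
#'
#' The default fertility (1.272 from maturity onwards) is calibrated so that
#' the baseline schedule, evaluated at the within-age optimal strategy for
#' the default hazards, has a population growth rate of about one.
#'
#' @param n_ages Number of age classes `A` (positive integer).
#' @param maturity First reproductive age `m` (integer in `[1, A]`).
#' @param i_x Infection probability per age; scalar or length-`A` vector.
#' @param mu_b Background hazard per age; scalar or length-`A`.
#' @param fertility Fertility from maturity onwards; scalar or length-`A`
#'   (ages below `maturity` are zeroed).
#' @param mud_multiplier Per-age multiplier on `mu_d`; scalar or length-`A`.
#' @return A tibble of class `"age_schedules"` with columns `age`, `i_x`,
#'   `mu_b`, `f`, `mud_multiplier` and attributes `maturity`, `n_ages`.
#' @examples
#' age_schedules(n_ages = 30, maturity = 10)
#' @export
age_schedules <- function(n_ages = 60, maturity = 15, i_x = 0.15,
                          mu_b = 1 / 60, fertility = 1.272,
                          mud_multiplier = 1) {
  if (n_ages < 2 || n_ages != round(n_ages)) {
    abort("`n_ages` must be an integer of at least 2.")
  }
  if (maturity < 1 || maturity > n_ages) {
    abort("`maturity` must lie in [1, n_ages].")
  }
  rep_a <- function(v, nm) {
    if (length(v) == 1L) v <- rep(v, n_ages)
    if (length(v) != n_ages) {
      abort(sprintf("`%s` must have length 1 or n_ages.", nm))
    }
    v
  }
  i_x <- rep_a(i_x, "i_x"); mu_b <- rep_a(mu_b, "mu_b")
  f <- rep_a(fertility, "fertility")
  mm <- rep_a(mud_multiplier, "mud_multiplier")
  if (any(i_x < 0 | i_x > 1)) abort("`i_x` must lie in [0, 1].")
  if (any(mu_b < 0) || any(f < 0) || any(mm < 0)) {
    abort("`mu_b`, `fertility` and `mud_multiplier` must be non-negative.")
  }
  f[seq_len(maturity - 1L)] <- 0
  out <- tibble(age = seq_len(n_ages), i_x = i_x, mu_b = mu_b, f = f,
                mud_multiplier = mm)
  structure(out, class = c("age_schedules", class(out)),
            maturity = as.integer(maturity), n_ages = as.integer(n_ages))
}

# per-age survival s_x under a lifespan-constant strategy
survival_by_age <- function(schedules, params, s_p) {
  vapply(seq_len(nrow(schedules)), function(x) {
    px <- params
    px$i_x <- schedules$i_x[x]
    px$mu_b <- schedules$mu_b[x]
    survival_age(px, s_p, mu_d = params$mu_d * schedules$mud_multiplier[x])
  }, numeric(1))
}

#' Build the Leslie projection matrix for a lifespan-constant strategy
#'
#' Per-age survival is computed by [survival_age()] with each age's infection
#' probability, background hazard and `mu_d` multiplier; survival from age
#' `x` to `x + 1` occupies matrix entry `(x + 1, x)` and the fertility
#' schedule fills the first row, so the proportion surviving to the final age
#' class is the product \eqn{s_1 s_2 \cdots s_{A-1}}. When
#' `fertility_penalty > 0`, fertility is scaled by \eqn{1 - c\, s_e} with the
#' strategy's sensitivity, modelling reproduction lost to immune reactivity
#' (for example fetal loss from anti-fetal responses).
#'
#' @param schedules An [age_schedules()] tibble.
#' @param params An [immune_params()] object (its `i_x`, `mu_b` are
#'   overridden age by age from `schedules`).
#' @param s_p Lifespan-constant specificity of the strategy.
#' @param fertility_penalty Penalty coefficient `c` in `[0, 1]` coupling
#'   fertility to sensitivity.
#' @return An `A x A` Leslie matrix.
#' @examples
#' sched <- age_schedules(n_ages = 20, maturity = 5)
#' p <- immune_params(gamma = 4, eta = 0.8, rho = 0.01, mu_d = 1)
#' M <- build_leslie(sched, p, s_p = 0.9)
#' eigen_summary(M)$lambda
#' @export
build_leslie <- function(schedules, params, s_p, fertility_penalty = 0) {
  stopifnot(inherits(schedules, "age_schedules"),
            inherits(params, "immune_params"))
  A <- nrow(schedules)
  s_x <- survival_by_age(schedules, params, s_p)
  s_e <- sensitivity_from_specificity(s_p, params$gamma)
  M <- matrix(0, A, A)
  M[cbind(2:A, 1:(A - 1))] <- s_x[1:(A - 1)]
  M[1, ] <- schedules$f * (1 - fertility_penalty * s_e)
  M
}

#' Growth rate, stable structure, reproductive values and survival
#' sensitivities of a Leslie matrix
#'
#' Extracts the dominant eigenvalue \eqn{\lambda} (the population growth
#' rate, used as the fitness proxy), the right eigenvector `w` (stable age
#' structure) and left eigenvector `v` (reproductive values), scaled so that
#' the scalar product \eqn{\langle w, v\rangle = 1}. Under that scaling the
#' sensitivity of \eqn{\lambda} to survival out of age `x` is the product of
#' the reproductive value of the class entered and the stable-structure
#' fraction of the class left, \eqn{\delta\lambda/\delta s_x = v_{x+1} w_x}
#' in 1-based indexing. For reporting, `w` is also returned normalised to
#' sum to one (`w_norm`); the normalisation is cosmetic and does not enter
#' any sensitivity.
#'
#' @param M A non-negative Leslie matrix with a reproductive age class
#'   reachable from age 1.
#' @return An object of class `"demographic_summary"`: a list with `lambda`
#'   and a tibble `ages` holding `age`, `w`, `w_norm`, `v`, and
#'   `sens_survival` (`NA` for the final age class, whose onward survival is
#'   undefined).
#' @examples
#' M <- matrix(0, 2, 2); M[2, 1] <- 0.5; M[1, 2] <- 2
#' eigen_summary(M)$lambda   # 1
#' @export
eigen_summary <- function(M) {
  if (!is.matrix(M) || nrow(M) != ncol(M)) abort("`M` must be square.")
  if (any(M < 0)) abort("`M` must be non-negative.")
  A <- nrow(M)
  er <- eigen(M)
  k <- which.max(Re(er$values))
  if (abs(Im(er$values[k])) > 1e-8 * max(1, abs(Re(er$values[k])))) {
    abort("no dominant real eigenvalue; the matrix may be reducible or cyclic.")
  }
  lambda <- Re(er$values[k])
  w <- Re(er$vectors[, k])
  el <- eigen(t(M))
  kl <- which.max(Re(el$values))
  v <- Re(el$vectors[, kl])
  if (sum(w) < 0) w <- -w
  if (sum(v) < 0) v <- -v
  if (any(w < -1e-8 * max(abs(w))) || any(v < -1e-8 * max(abs(v)))) {
    abort("dominant eigenvectors are not non-negative; matrix is not primitive.")
  }
  w <- pmax(w, 0); v <- pmax(v, 0)
  v <- v / sum(v * w)  # <w, v> = 1
  sens <- c(v[-1] * w[-A], NA_real_)
  ages <- tibble(age = seq_len(A), w = w, w_norm = w / sum(w), v = v,
                 sens_survival = sens)
  structure(list(lambda = lambda, ages = ages),
            class = "demographic_summary")
}

#' @export
print.demographic_summary <- function(x, ...) {
  cat(sprintf("<demographic_summary> lambda = %.6f, %d age classes\n",
              x$lambda, nrow(x$ages)))
  invisible(x)
}

#' @rdname eigen_summary
#' @param x,object A `"demographic_summary"`.
#' @param ... Unused.
#' @export
tidy.demographic_summary <- function(x, ...) x$ages

#' @rdname eigen_summary
#' @export
glance.demographic_summary <- function(x, ...) {
  tibble(lambda = x$lambda, n_ages = nrow(x$ages))
}

#' @rdname eigen_summary
#' @export
autoplot.demographic_summary <- function(object, ...) {
  long <- pivot_longer(object$ages[, c("age", "w_norm", "v", "sens_survival")],
                       -"age", names_to = "quantity", values_to = "value")
  ggplot(long, aes(x = .data$age, y = .data$value)) +
    geom_line() +
    facet_wrap(~ .data$quantity, scales = "free_y") +
    labs(x = "age", y = NULL) +
    theme_minimal()
}

#' Sensitivity of the growth rate to age-specific survival
#'
#' Convenience accessor returning \eqn{\delta\lambda/\delta s_x =
#' v_{x+1} w_x} (under the \eqn{\langle w, v\rangle = 1} scaling) for ages
#' `1 .. A-1`, as computed by [eigen_summary()].
#'
#' @param summary A `"demographic_summary"`.
#' @return A numeric vector of length `A - 1`.
#' @export
lambda_sensitivity_survival <- function(summary) {
  stopifnot(inherits(summary, "demographic_summary"))
  s <- summary$ages$sens_survival
  s[-length(s)]
}

#' Chain-rule sensitivity of the growth rate to a shared immune parameter
#'
#' For a parameter shared across ages (specificity `s_p` or effector setting
#' `mu_d`), the growth-rate derivative is assembled by the chain rule,
#' \eqn{\delta\lambda/\delta\theta = \sum_x (\delta\lambda/\delta s_x)
#' (\delta s_x/\delta\theta)}, with the survival derivatives from
#' [dsurvival_dsp()] or [dsurvival_dmud()] evaluated with each age's
#' schedule entries. Fertility is held fixed (use
#' [optimize_lifespan_sensitivity()] when fertility is coupled to the
#' strategy).
#'
#' @inheritParams build_leslie
#' @param target `"s_p"` or `"mu_d"`.
#' @return A single numeric derivative.
#' @export
lambda_sensitivity_parameter <- function(schedules, params, s_p,
                                         target = c("s_p", "mu_d")) {
  target <- match.arg(target)
  M <- build_leslie(schedules, params, s_p)
  sens <- lambda_sensitivity_survival(eigen_summary(M))
  A <- nrow(schedules)
  dsdx <- vapply(seq_len(A - 1L), function(x) {
    px <- params
    px$i_x <- schedules$i_x[x]
    px$mu_b <- schedules$mu_b[x]
    md <- params$mu_d * schedules$mud_multiplier[x]
    if (target == "s_p") {
      dsurvival_dsp(px, s_p, mu_d = md)
    } else {
      # d s_x / d mu_d with a per-age multiplier m: m * f'(m * mu_d)
      schedules$mud_multiplier[x] * dsurvival_dmud(px, s_p, mu_d = md)
    }
  }, numeric(1))
  sum(sens * dsdx)
}

#' Lifespan-level optimal sensitivity
#'
#' Finds the single, lifespan-constant specificity (equivalently
#' sensitivity) that maximises the population growth rate \eqn{\lambda} of
#' the Leslie matrix built from the given schedules -- the whole-life
#' optimum, which coincides with the within-age optimum only when infection
#' risk is constant over age. A coarse grid scan over `[0, 1]` locates the
#' global basin (the objective can be multimodal) and golden-section search
#' refines it; both stages are deterministic.
#'
#' @inheritParams build_leslie
#' @param n_grid Number of coarse grid points (at least 256).
#' @param tol Absolute tolerance on `s_p` for the refinement stage.
#' @return A one-row tibble of class `"immune_strategy"` with columns `s_p`,
#'   `s_e`, `mu_d`, `interior` and `lambda`.
#' @examples
#' sched <- age_schedules(n_ages = 20, maturity = 5)
#' p <- immune_params(gamma = 4, eta = 0.8, rho = 0.01, mu_d = 1)
#' optimize_lifespan_sensitivity(sched, p)
#' @export
optimize_lifespan_sensitivity <- function(schedules, params,
                                          fertility_penalty = 0,
                                          n_grid = 257, tol = 1e-7) {
  n_grid <- max(256L, n_grid)
  lam <- function(sp) {
    vapply(sp, function(s) {
      M <- build_leslie(schedules, params, s, fertility_penalty)
      max(Re(eigen(M, only.values = TRUE)$values))
    }, numeric(1))
  }
  sp <- grid_refine(lam, 0, 1, n_grid, tol)
  out <- new_strategy(sp, params$gamma, params$mu_d,
                      interior = sp > tol && sp < 1 - tol)
  out$lambda <- lam(sp)
  out
}

#' Growth rate from the Euler--Lotka characteristic equation
#'
#' Independent route to the growth rate of an age-structured population:
#' solves \eqn{\sum_x f_x \ell_x \lambda^{-x} = 1} for \eqn{\lambda}, where
#' \eqn{\ell_x} is cumulative survivorship to age `x`. Useful as a
#' cross-check on the eigenvalue of [build_leslie()].
#'
#' @param s_x Per-age survival probabilities (length `A`; the last entry is
#'   unused).
#' @param f Per-age fertilities (length `A`).
#' @return The real root \eqn{\lambda > 0}.
#' @export
euler_lotka_lambda <- function(s_x, f) {
  A <- length(f)
  lx <- c(1, cumprod(s_x[seq_len(A - 1L)]))
  g <- function(lam) sum(f * lx * lam^(-seq_len(A))) - 1
  if (sum(f) == 0) return(0)
  lo <- 1e-8
  hi <- max(1, sum(f * lx))
  while (g(hi) > 0) hi <- hi * 2
  uniroot(g, c(lo, hi), tol = 1e-12)$root
}
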