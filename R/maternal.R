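#' Configure the two-generation mother--offspring simulation
#'
#' Discrimination is modelled mechanistically as a threshold `t` on a trait
#' axis along which self molecules (location `self_mean`) and pathogen
#' molecules (location `nonself_mean`) are normally distributed and overlap:
#' the host responds to any molecule whose trait exceeds `t`, so a lower
#' threshold means higher sensitivity and lower specificity. Immune memory
#' is a set of previously detected pathogen bins (the trait axis is
#' discretised into `n_bins` bins, giving memory finite specificity without
#' a full strain model); remembered pathogens elicit immunopathology
#' \eqn{\mu_{id}} discounted by `memory_discount`. Mothers transfer
#' protection: an offspring infected in its first year by a pathogen whose
#' bin is in its mother's memory has its undetected-infection hazard reduced
#' by the factor `transfer_efficacy` (and, if `transfer_spares_muid`, the
#' immunopathology of the transferred response likewise).
#'
#' First-year offspring are taken to be immunologically naive: they cannot
#' detect pathogens themselves, so maternal antibodies are their only
#' first-year protection, and their own (innate or transferred) reactivity
#' contributes immunopathology scaled by `offspring_immunopathology`.
#'
#' @param self_mean,self_sd Location and scale of the self-trait
#'   distribution.
#' @param nonself_mean,nonself_sd Location and scale of the pathogen-trait
#'   distribution; the two distributions must overlap.
#' @param n_ages,maturity Maternal age classes and age at first reproduction.
#' @param i_x Maternal infection probability per age (scalar or length
#'   `n_ages`).
#' @param mu_b Background hazard (scalar or length `n_ages`).
#' @param fertility Offspring per age from maturity on (scalar or length
#'   `n_ages`).
#' @param mu_d,mu_i,mu_id Hazards of undetected infection, false-positive
#'   immunopathology, and true-positive immune damage.
#' @param offspring_infection Probability an offspring is infected in its
#'   first year.
#' @param memory_discount Fraction in `[0, 1]` multiplying `mu_id` for
#'   remembered pathogens (1 disables memory).
#' @param transfer_efficacy Fraction in `[0, 1]` by which maternal memory of
#'   the infecting pathogen reduces the offspring's first-year `mu_d`
#'   (0 disables transfer).
#' @param transfer_spares_muid If `TRUE`, transfer also reduces the
#'   `mu_id`-type damage of the transferred response.
#' @param offspring_immunopathology Non-negative scale of `mu_i`/`mu_id` in
#'   the offspring's first age class (0 = naive offspring suffer no
#'   immunopathology).
#' @param n_bins,bin_range Discretisation of the trait axis for memory.
#' @param n_replicates Monte-Carlo replicates (mothers).
#' @param n_blocks Number of equal blocks used for block-based standard
#'   errors of derived optima.
#' @param seed Mandatory integer seed.
#' @return A list of class `"lineage_config"`.
#' @examples
#' cfg <- lineage_config(seed = 1, n_replicates = 2000)
#' roc_from_threshold(cfg, c(0, 1, 2))
#' @export
lineage_config <- function(self_mean = 0, self_sd = 1,
                           nonself_mean = 2, nonself_sd = 1,
                           n_ages = 20, maturity = 5,
                           i_x = 0.15, mu_b = 0.02, fertility = 1,
                           mu_d = 1.5, mu_i = 0.45, mu_id = 0.5,
                           offspring_infection = 0.8,
                           memory_discount = 1, transfer_efficacy = 0.9,
                           transfer_spares_muid = FALSE,
                           offspring_immunopathology = 0,
                           n_bins = 32, bin_range = c(-4, 6),
                           n_replicates = 20000, n_blocks = 10,
                           seed) {
  if (missing(seed)) abort("`seed` is mandatory for the lineage simulation.")
  if (self_sd <= 0 || nonself_sd <= 0) abort("scales must be positive.")
  frac <- c(memory_discount = memory_discount,
            transfer_efficacy = transfer_efficacy)
  if (any(frac < 0 | frac > 1)) {
    abort("`memory_discount` and `transfer_efficacy` must lie in [0, 1].")
  }
  if (any(c(mu_d, mu_i, mu_id, mu_b, offspring_immunopathology) < 0)) {
    abort("hazards and `offspring_immunopathology` must be non-negative.")
  }
  rep_a <- function(v) if (length(v) == 1L) rep(v, n_ages) else v
  i_x <- rep_a(i_x); mu_b <- rep_a(mu_b); fertility <- rep_a(fertility)
  if (any(lengths(list(i_x, mu_b, fertility)) != n_ages)) {
    abort("schedule vectors must have length 1 or `n_ages`.")
  }
  if (any(i_x < 0 | i_x > 1) || offspring_infection < 0 ||
      offspring_infection > 1) {
    abort("infection probabilities must lie in [0, 1].")
  }
  fertility[seq_len(maturity - 1L)] <- 0
  # require genuine overlap of the two trait distributions
  mid <- (self_mean + nonself_mean) / 2
  if (pnorm(mid, self_mean, self_sd, lower.tail = FALSE) < 1e-12 ||
      pnorm(mid, nonself_mean, nonself_sd) < 1e-12) {
    abort("self and non-self trait distributions must overlap.")
  }
  if (n_replicates %% n_blocks != 0) {
    abort("`n_replicates` must be a multiple of `n_blocks`.")
  }
  structure(list(self_mean = self_mean, self_sd = self_sd,
                 nonself_mean = nonself_mean, nonself_sd = nonself_sd,
                 n_ages = as.integer(n_ages), maturity = as.integer(maturity),
                 i_x = i_x, mu_b = mu_b, fertility = fertility,
                 mu_d = mu_d, mu_i = mu_i, mu_id = mu_id,
                 offspring_infection = offspring_infection,
                 memory_discount = memory_discount,
                 transfer_efficacy = transfer_efficacy,
                 transfer_spares_muid = transfer_spares_muid,
                 offspring_immunopathology = offspring_immunopathology,
                 n_bins = as.integer(n_bins), bin_range = bin_range,
                 n_replicates = as.integer(n_replicates),
                 n_blocks = as.integer(n_blocks), seed = as.integer(seed)),
            class = "lineage_config")
}

#' Sensitivity and specificity implied by a discrimination threshold
#'
#' Computed from the trait distribution functions (no sampling):
#' sensitivity is the probability that a pathogen trait falls on the
#' "respond" side of the threshold, specificity the probability that a self
#' trait falls on the "ignore" side. Sweeping the threshold traces the ROC
#' curve of the mechanistic discrimination model.
#'
#' @param config A [lineage_config()].
#' @param t Threshold(s) on the trait axis; vectorised.
#' @return A tibble with columns `threshold`, `s_e`, `s_p`.
#' @export
roc_from_threshold <- function(config, t) {
  stopifnot(inherits(config, "lineage_config"))
  tibble(threshold = t,
         s_e = pnorm(t, config$nonself_mean, config$nonself_sd,
                     lower.tail = FALSE),
         s_p = pnorm(t, config$self_mean, config$self_sd))
}

# pathogen-trait mass per memory bin, and the detected (trait > t) part
bin_masses <- function(config, t) {
  edges <- seq(config$bin_range[1], config$bin_range[2],
               length.out = config$n_bins + 1L)
  lo <- edges[-(config$n_bins + 1L)]
  hi <- edges[-1L]
  p_all <- pnorm(hi, config$nonself_mean, config$nonself_sd) -
    pnorm(lo, config$nonself_mean, config$nonself_sd)
  lo_t <- pmax(lo, t)
  p_det <- ifelse(hi > t,
                  pnorm(hi, config$nonself_mean, config$nonself_sd) -
                    pnorm(pmin(lo_t, hi), config$nonself_mean,
                          config$nonself_sd),
                  0)
  list(edges = edges, all = p_all, detected = p_det)
}

#' Simulate mother--offspring lineages at a fixed threshold
#'
#' Each replicate mother lives through the age classes. Within a year, the
#' many independent exposures are averaged: her realised mortality hazard is
#' the expectation of the competing hazards given her current memory,
#' \eqn{\mu_b + (1-i_x)\mu_i(1-s_p) + i_x[(1-s_e)\mu_d + s_e\,
#' \bar\mu_{id}]}, where \eqn{\bar\mu_{id}} discounts `mu_id` by
#' `memory_discount` over the remembered fraction of detectable pathogens.
#' Memory itself accrues stochastically: one infection event per year with
#' probability `i_x`, detected when the drawn pathogen trait exceeds the
#' threshold, adding its bin to the memory set. From maturity onwards the
#' mother reproduces at her fertility; each offspring draws a first-year
#' pathogen, and its first-year survival (by which the birth is weighted in
#' the fitness proxy) uses the naive-offspring hazard with `mu_d` reduced by
#' `transfer_efficacy` when the pathogen's bin is in the maternal memory.
#' The fitness proxy is the mean over replicates of lifetime reproduction
#' weighted by offspring first-year survival.
#'
#' Draws are made in a fixed order independent of the threshold, so calls at
#' different thresholds (or different transfer settings) with the same seed
#' share common random numbers and are directly comparable pairwise.
#'
#' @param config A [lineage_config()].
#' @param t Discrimination threshold.
#' @param transfer_efficacy,memory_discount Overrides of the config values
#'   (so arms with and without transfer or memory can share a config).
#' @param seed Override of `config$seed`.
#' @return An object of class `"lineage_sim"`: a list with
#'   \describe{
#'     \item{fitness}{one-row tibble `threshold`, `s_e`, `s_p`,
#'       `fitness_mean`, `fitness_se`,}
#'     \item{age_survival}{tibble `age`, `n_at_risk`, `mc_survival`,
#'       `closed_form` (the hazard-sum survival at the threshold's
#'       `(s_e, s_p)`, memory and transfer disabled),}
#'     \item{fits}{per-replicate fitness values (for block statistics).}
#'   }
#' @examples
#' cfg <- lineage_config(seed = 7, n_replicates = 1000)
#' simulate_lineage(cfg, t = 1.5)$fitness
#' @export
simulate_lineage <- function(config, t,
                             transfer_efficacy = config$transfer_efficacy,
                             memory_discount = config$memory_discount,
                             seed = config$seed) {
  stopifnot(inherits(config, "lineage_config"))
  if (transfer_efficacy < 0 || transfer_efficacy > 1 ||
      memory_discount < 0 || memory_discount > 1) {
    abort("`transfer_efficacy` and `memory_discount` must lie in [0, 1].")
  }
  set.seed(seed)
  n <- config$n_replicates
  A <- config$n_ages
  roc <- roc_from_threshold(config, t)
  s_e <- roc$s_e; s_p <- roc$s_p
  bm <- bin_masses(config, t)
  tot_det <- sum(bm$detected)
  kap <- config$offspring_immunopathology
  tid <- if (isTRUE(config$transfer_spares_muid)) transfer_efficacy else 0
  i1 <- config$offspring_infection

  alive <- rep(TRUE, n)
  mem <- matrix(FALSE, n, config$n_bins)
  fit <- numeric(n)
  n_at_risk <- integer(A)
  n_survive <- integer(A)
  for (x in seq_len(A)) {
    # expected hazard over the year's exposures, given the memory state
    p_mem_det <- if (tot_det > 0) {
      as.numeric(mem %*% bm$detected) / tot_det
    } else {
      numeric(n)
    }
    muid_eff <- config$mu_id * (1 - (1 - memory_discount) * p_mem_det)
    H <- config$mu_b[x] + (1 - config$i_x[x]) * config$mu_i * (1 - s_p) +
      config$i_x[x] * ((1 - s_e) * config$mu_d + s_e * muid_eff)
    # reproduction weighted by offspring first-year survival; fixed draw
    # order keeps the random-number stream threshold-independent
    tau_off <- rnorm(n, config$nonself_mean, config$nonself_sd)
    if (x >= config$maturity && config$fertility[x] > 0) {
      b_off <- findInterval(tau_off, bm$edges, all.inside = TRUE)
      covered <- mem[cbind(seq_len(n), b_off)]
      H_off <- config$mu_b[x] +
        i1 * config$mu_d * (1 - transfer_efficacy * covered) +
        kap * ((1 - i1) * config$mu_i * (1 - s_p) +
                 i1 * covered * config$mu_id * (1 - tid))
      fit <- fit + alive * config$fertility[x] * exp(-H_off)
    }
    # survive the year
    u_s <- runif(n)
    n_at_risk[x] <- sum(alive)
    alive_new <- alive & (u_s < exp(-H))
    n_survive[x] <- sum(alive_new)
    alive <- alive_new
    # one infection event per year builds memory
    u_i <- runif(n)
    tau <- rnorm(n, config$nonself_mean, config$nonself_sd)
    det <- alive & (u_i < config$i_x[x]) & (tau > t)
    b <- findInterval(tau, bm$edges, all.inside = TRUE)
    mem[cbind(which(det), b[det])] <- TRUE
  }
  H0 <- config$mu_b + (1 - config$i_x) * config$mu_i * (1 - s_p) +
    config$i_x * ((1 - s_e) * config$mu_d + s_e * config$mu_id)
  out <- list(
    fitness = tibble(threshold = t, s_e = s_e, s_p = s_p,
                     fitness_mean = mean(fit),
                     fitness_se = sd(fit) / sqrt(n)),
    age_survival = tibble(age = seq_len(A), n_at_risk = n_at_risk,
                          mc_survival = ifelse(n_at_risk > 0,
                                               n_survive / n_at_risk,
                                               NA_real_),
                          closed_form = exp(-H0)),
    fits = fit)
  class(out) <- "lineage_sim"
  out
}

#' @export
print.lineage_sim <- function(x, ...) {
  cat("<lineage_sim>\n")
  print(x$fitness)
  invisible(x)
}

#' Optimal discrimination threshold with and without maternal transfer
#'
#' Sweeps the threshold grid twice with common random numbers -- once with
#' transfer disabled and once at the configured `transfer_efficacy` -- and
#' locates the fitness-maximising threshold of each arm. Standard errors of
#' the optimal sensitivity are obtained by splitting the replicates into
#' `config$n_blocks` blocks, finding the block-wise optimum in each arm, and
#' pairing blocks across arms (the pairing removes the common Monte-Carlo
#' noise shared through the seed).
#'
#' @param config A [lineage_config()].
#' @param thresholds Threshold grid to sweep.
#' @param transfer_efficacy Transfer efficacy of the "transfer" arm.
#' @return An object of class `"threshold_comparison"`: a list with
#'   \describe{
#'     \item{sweep}{tibble `arm`, `threshold`, `s_e`, `s_p`,
#'       `fitness_mean`, `fitness_se`,}
#'     \item{optima}{tibble `arm`, `threshold`, `s_e`, `s_p`, `fitness`,}
#'     \item{delta}{one-row tibble `delta_se_mean` (mean over paired blocks
#'       of the transfer-arm optimal sensitivity minus the no-transfer
#'       arm's), `delta_se_se`, `z`.}
#'   }
#' @examples
#' cfg <- lineage_config(seed = 3, n_replicates = 2000)
#' ot <- optimal_threshold(cfg, thresholds = seq(0.5, 2.3, by = 0.3))
#' ot$optima
#' @export
optimal_threshold <- function(config, thresholds = seq(0, 2.4, by = 0.1),
                              transfer_efficacy = config$transfer_efficacy) {
  stopifnot(inherits(config, "lineage_config"))
  n <- config$n_replicates
  B <- config$n_blocks
  block <- rep(seq_len(B), each = n / B)
  arms <- c(no_transfer = 0, transfer = transfer_efficacy)
  sweep <- list(); block_opt <- list()
  for (a in names(arms)) {
    fits <- vapply(thresholds, function(tt) {
      simulate_lineage(config, tt, transfer_efficacy = arms[[a]])$fits
    }, numeric(n))
    mu <- colMeans(fits)
    roc <- roc_from_threshold(config, thresholds)
    sweep[[a]] <- tibble(arm = a, threshold = thresholds,
                         s_e = roc$s_e, s_p = roc$s_p,
                         fitness_mean = mu,
                         fitness_se = apply(fits, 2, sd) / sqrt(n))
    bo <- vapply(seq_len(B), function(b) {
      thresholds[which.max(colMeans(fits[block == b, , drop = FALSE]))]
    }, numeric(1))
    block_opt[[a]] <- roc_from_threshold(config, bo)$s_e
  }
  sweep <- list_rbind(sweep)
  optima <- sweep |>
    group_by(.data$arm) |>
    filter(.data$fitness_mean == max(.data$fitness_mean)) |>
    dplyr::slice(1) |>
    ungroup() |>
    dplyr::rename(fitness = "fitness_mean") |>
    dplyr::select("arm", "threshold", "s_e", "s_p", "fitness")
  d <- block_opt$transfer - block_opt$no_transfer
  se_d <- sd(d) / sqrt(B)
  z <- if (se_d > 0) mean(d) / se_d else if (mean(d) == 0) 0 else Inf * sign(mean(d))
  delta <- tibble(delta_se_mean = mean(d), delta_se_se = se_d, z = z)
  structure(list(sweep = sweep, optima = optima, delta = delta,
                 thresholds = thresholds, config = config),
            class = "threshold_comparison")
}

#' @export
print.threshold_comparison <- function(x, ...) {
  cat("<threshold_comparison>\n")
  print(x$optima)
  print(x$delta)
  invisible(x)
}

#' @rdname optimal_threshold
#' @param x,object A `"threshold_comparison"`.
#' @param ... Unused.
#' @export
tidy.threshold_comparison <- function(x, ...) x$sweep

#' @rdname optimal_threshold
#' @export
glance.threshold_comparison <- function(x, ...) {
  wide <- setNames(x$optima$s_e, x$optima$arm)
  tibble(se_no_transfer = wide[["no_transfer"]],
         se_transfer = wide[["transfer"]],
         delta_se_mean = x$delta$delta_se_mean,
         delta_se_se = x$delta$delta_se_se, z = x$delta$z)
}

#' @rdname optimal_threshold
#' @export
autoplot.threshold_comparison <- function(object, ...) {
  ggplot(object$sweep, aes(x = .data$threshold, y = .data$fitness_mean,
                           colour = .data$arm)) +
    geom_line() +
    geom_point(data = object$optima,
               aes(x = .data$threshold, y = .data$fitness,
                   colour = .data$arm), size = 3, shape = 4) +
    labs(x = "discrimination threshold (low = sensitive)",
         y = "fitness proxy", colour = NULL) +
    theme_minimal()
}
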