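test_that("the ROC link maps specificity to sensitivity as expected", {
  # perfect specificity leaves no scope to respond; vanishing discrimination
  # detects nothing; full reactivity attains the gamma-dependent ceiling
  expect_equal(sensitivity_from_specificity(1, gamma = 4), 0)
  expect_lt(sensitivity_from_specificity(0.3, gamma = 1e-9), 1e-8)
  expect_equal(sensitivity_from_specificity(0, gamma = 4), 1 - exp(-4),
               tolerance = 1e-12)

  sp <- seq(0, 1, length.out = 101)
  se <- sensitivity_from_specificity(sp, gamma = 4)
  expect_true(all(diff(se) < 0))                       # decreasing in s_p
  se2 <- sensitivity_from_specificity(0.4, gamma = c(1, 2, 4, 8))
  expect_true(all(diff(se2) > 0))                      # increasing in gamma

  # the (1 - s_p, s_e) ROC is concave, through (0, 0), up to 1 - e^-gamma
  fpr <- 1 - rev(sp)
  roc <- 1 - exp(-4 * fpr)
  expect_true(all(diff(roc, differences = 2) < 1e-12))
  expect_equal(roc[1], 0)
  expect_equal(roc[length(roc)], 1 - exp(-4))

  expect_error(sensitivity_from_specificity(1.2, 4), "\\[0, 1\\]")
  expect_error(sensitivity_from_specificity(0.5, 0), "positive")
})

test_that("the inverse ROC link round-trips and rejects infeasible values", {
  sp <- seq(0.05, 0.95, by = 0.1)
  se <- sensitivity_from_specificity(sp, gamma = 3)
  expect_equal(specificity_from_sensitivity(se, gamma = 3), sp,
               tolerance = 1e-12)
  expect_error(specificity_from_sensitivity(1 - exp(-3), gamma = 3),
               "attainable")
})

test_that("age-specific survival sums the competing hazards", {
  p0 <- immune_params(gamma = 4, mu_b = 0, mu_d = 0, i_x = 0.5,
                      mu_i = 0, mu_id = 0, tradeoff = "fixed")
  expect_equal(survival_age(p0, 0.3), 1)

  p1 <- immune_params(gamma = 4, mu_b = 1 / 60, mu_d = 0, i_x = 0,
                      mu_i = 1, mu_id = 0, tradeoff = "fixed")
  expect_equal(survival_age(p1, 1), exp(-1 / 60), tolerance = 1e-12)

  # hazard trade-off active: term-by-term recomputation of the exponent
  p <- fig_landscape_params()
  mu_i <- exp(-0.8 * 1); mu_id <- 0.01 * mu_i
  H <- 1 / 60 + 0.5 * mu_i * 0.5 + 0.5 * 1 * exp(-2) +
    0.5 * mu_id * (1 - exp(-2))
  expect_equal(survival_age(p, 0.5), exp(-H), tolerance = 1e-12)
  expect_equal(survival_age(p, 0.5), 0.8198703, tolerance = 1e-6)

  expect_error(survival_age(p, -0.1), "\\[0, 1\\]")
  expect_error(survival_age(p, 0.5, mu_d = -1), "non-negative")
  expect_error(immune_params(gamma = 4, eta = 0.8, mu_b = -1), "non-negative")
})

test_that("effector hazards fall with effector-implied mu_d", {
  expect_equal(effector_hazards(0, eta = 0.8, rho = 0.01),
               tibble::tibble(mu_d = 0, mu_i = 1, mu_id = 0.01))
  big <- effector_hazards(1e6, eta = 0.8, rho = 0.01)
  expect_equal(big$mu_i, 0); expect_equal(big$mu_id, 0)
  one <- effector_hazards(1, eta = 0.8, rho = 0.01)
  expect_equal(one$mu_i, 0.449329, tolerance = 1e-6)
  expect_equal(one$mu_id, 0.00449329, tolerance = 1e-6)
  tab <- effector_hazards(seq(0, 5, by = 0.25), eta = 0.8, rho = 0.01)
  expect_true(all(diff(tab$mu_i) < 0) && all(diff(tab$mu_id) < 0))
  expect_error(effector_hazards(-1, 0.8, 0.01), "non-negative")
})

test_that("analytic survival derivatives match central finite differences", {
  h <- 1e-6
  set.seed(42)
  for (k in 1:25) {
    p <- random_closure_params()
    sp <- runif(1, 0.02, 0.98)
    md <- runif(1, 0.1, 4)
    fd_sp <- (survival_age(p, sp + h, md) - survival_age(p, sp - h, md)) / (2 * h)
    expect_lt(rel_err(dsurvival_dsp(p, sp, md), fd_sp), 1e-6)
    fd_md <- (survival_age(p, sp, md + h) - survival_age(p, sp, md - h)) / (2 * h)
    expect_lt(rel_err(dsurvival_dmud(p, sp, md), fd_md), 1e-6)
  }
  # fixed hazards too (specificity derivative only)
  for (k in 1:10) {
    p <- random_fixed_params()
    sp <- runif(1, 0.02, 0.98)
    fd_sp <- (survival_age(p, sp + h) - survival_age(p, sp - h)) / (2 * h)
    expect_lt(rel_err(dsurvival_dsp(p, sp), fd_sp), 1e-6)
  }
  # with no infection only the false-positive term survives
  p0 <- immune_params(gamma = 4, mu_b = 0, mu_d = 1, i_x = 0,
                      mu_i = 0.5, mu_id = 0, tradeoff = "fixed")
  expect_gt(dsurvival_dsp(p0, 0.5), 0)
})

test_that("the closed-form optimal specificity is a certified maximum", {
  p <- fixed_params()
  opt <- optimal_specificity(p)
  expect_equal(opt$s_p, 0.4801396, tolerance = 1e-6)
  expect_true(opt$interior)
  # critical point: derivative vanishes there
  expect_lt(abs(dsurvival_dsp(p, opt$s_p)), 1e-10)
  # second derivative negative (finite differences)
  h <- 1e-4
  d2 <- (survival_age(p, opt$s_p + h) - 2 * survival_age(p, opt$s_p) +
           survival_age(p, opt$s_p - h)) / h^2
  expect_lt(d2, 0)
  # at least as good as any grid point
  grid <- seq(0, 1, length.out = 2001)
  expect_gte(survival_age(p, opt$s_p), max(survival_age(p, grid)))

  expect_error(optimal_specificity(fixed_params(mu_id = 1, mu_d = 1)),
               "degenerate")
})

test_that("the specificity optimum clamps to the boundary when pushed there", {
  # rare infection and damaging immunopathology: never respond
  p_hi <- fixed_params(mu_i = 1.5, i_x = 0.01)
  opt <- optimal_specificity(p_hi)
  expect_equal(opt$s_p, 1); expect_equal(opt$s_e, 0)
  expect_false(opt$interior)
  num <- optimal_strategy_numeric(p_hi)
  expect_equal(num$s_p, 1, tolerance = 1e-6)
  # degenerate incidence handled as explicit boundary cases
  expect_equal(optimal_specificity(fixed_params(i_x = 0))$s_p, 1)
  expect_equal(optimal_specificity(fixed_params(i_x = 1))$s_p, 0)
  expect_equal(optimal_strategy_numeric(fixed_params(i_x = 0))$s_p, 1,
               tolerance = 1e-6)
})

test_that("baseline mortality never moves the specificity optimum", {
  set.seed(7)
  for (k in 1:20) {
    p <- random_fixed_params()
    p_lo <- p; p_lo$mu_b <- 0
    p_hi <- p; p_hi$mu_b <- 2.5
    expect_identical(optimal_specificity(p_lo)$s_p,
                     optimal_specificity(p_hi)$s_p)
  }
})

test_that("the closed-form optimal effector setting matches the grid argmax", {
  p <- immune_params(gamma = 4, eta = 0.8, rho = 0.01, i_x = 0.5)
  md <- optimal_mud(p, s_p = 0.5)
  expect_equal(as.numeric(md), 1.3760676, tolerance = 1e-5)
  expect_lt(abs(dsurvival_dmud(p, 0.5, as.numeric(md))), 1e-10)
  grid <- seq(0, 20, length.out = 20001)
  expect_gte(survival_age(p, 0.5, as.numeric(md)),
             max(survival_age(p, 0.5, grid)))
  h <- 1e-4
  d2 <- (survival_age(p, 0.5, md + h) - 2 * survival_age(p, 0.5, md) +
           survival_age(p, 0.5, md - h)) / h^2
  expect_lt(d2, 0)
  # the bracket can go negative: floored at zero, argmax on the boundary
  p2 <- immune_params(gamma = 0.2, eta = 0.8, rho = 0, i_x = 0.95)
  md2 <- optimal_mud(p2, s_p = 0.9)
  expect_equal(as.numeric(md2), 0)
  expect_false(attr(md2, "interior"))
  num2 <- optimal_strategy_numeric(p2, free = "mu_d", s_p = 0.9)
  expect_lt(num2$mu_d, 1e-4)
  expect_error(optimal_mud(immune_params(gamma = 4, eta = 1, rho = 0,
                                         i_x = 0.5), s_p = 1),
               "degenerate")
})

test_that("closed-form optima agree with the numeric oracle on random draws", {
  set.seed(101)
  n_interior <- 0
  for (k in 1:40) {
    pf <- random_fixed_params()
    a <- optimal_specificity(pf)
    b <- optimal_strategy_numeric(pf)
    expect_lt(abs(a$s_p - b$s_p), 1e-5)
    pc <- random_closure_params()
    sp <- runif(1, 0.05, 0.95)
    am <- as.numeric(optimal_mud(pc, sp))
    bm <- optimal_strategy_numeric(pc, free = "mu_d", s_p = sp)$mu_d
    if (am < 19) expect_lt(abs(am - bm), 1e-4)
    n_interior <- n_interior + a$interior
  }
  expect_gt(n_interior, 5)  # the draw really exercises interior optima
})

test_that("reduced effector allocation always selects for more sensitivity", {
  for (pars in list(c(gamma = 4, i_x = 0.5, R = 0.5),
                    c(gamma = 2, i_x = 0.15, R = 0.1))) {
    p <- fixed_params(gamma = pars["gamma"], i_x = pars["i_x"],
                      mu_i = pars["R"], mu_d = 1, mu_id = 0)
    res <- response_to_reduced_R(p)
    expect_identical(res$sign, -1L)
    # numeric confirmation: shrink R by 10%, optimal sensitivity rises
    p2 <- p; p2$mu_i <- 0.9 * p$mu_i
    expect_gt(optimal_strategy_numeric(p2)$s_e,
              optimal_strategy_numeric(p)$s_e)
  }
  # interior optimum moves monotonically with incidence and with R
  se_by_ix <- sapply(c(0.2, 0.4, 0.6, 0.8), function(ix) {
    optimal_specificity(fixed_params(i_x = ix))$s_e
  })
  expect_true(all(diff(se_by_ix) > 0))
  se_by_R <- sapply(c(0.2, 0.4, 0.8), function(R) {
    optimal_specificity(fixed_params(mu_i = R))$s_e
  })
  expect_true(all(diff(se_by_R) < 0))
  # clamped optimum is flagged indeterminate
  expect_warning(res <- response_to_reduced_R(fixed_params(mu_i = 1.5,
                                                           i_x = 0.01)),
                 "indeterminate")
  expect_true(is.na(res$sign))
})
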