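test_that("age schedules enforce their contracts", {
  s <- age_schedules(n_ages = 30, maturity = 10)
  expect_s3_class(s, "age_schedules")
  expect_equal(nrow(s), 30)
  expect_true(all(s$f[1:9] == 0))
  expect_true(all(s$f[10:30] > 0))
  expect_error(age_schedules(n_ages = 30, i_x = c(0.1, 0.2)), "length")
  expect_error(age_schedules(n_ages = 30, i_x = 1.5), "\\[0, 1\\]")
  expect_error(age_schedules(n_ages = 30, maturity = 40), "maturity")
})

test_that("the Leslie matrix carries survival on the subdiagonal and fertility
           in the first row", {
  p <- fixed_params(mu_b = 0)
  # two age classes, lambda^2 = f2 * s1: choose f2 = 1/s1 so lambda = 1
  sched <- age_schedules(n_ages = 2, maturity = 2, i_x = 0, mu_b = 0.4,
                         fertility = 1)
  M <- build_leslie(sched, p, s_p = 1)
  s1 <- exp(-0.4)  # only the baseline hazard acts at s_p = 1, i_x = 0
  expect_equal(M[2, 1], s1)
  sched2 <- age_schedules(n_ages = 2, maturity = 2, i_x = 0, mu_b = 0.4,
                          fertility = 1 / s1)
  M2 <- build_leslie(sched2, p, s_p = 1)
  expect_equal(eigen_summary(M2)$lambda, 1, tolerance = 1e-12)
  # no fertility at all: the population goes extinct
  sched0 <- age_schedules(n_ages = 5, maturity = 5, fertility = 0)
  M0 <- build_leslie(sched0, p, s_p = 1)
  expect_equal(max(Re(eigen(M0, only.values = TRUE)$values)), 0)
  # cumulative survivorship is the product of the subdiagonal
  p3 <- fig_landscape_params()
  sched3 <- age_schedules(n_ages = 10, maturity = 3, i_x = 0.3)
  M3 <- build_leslie(sched3, p3, s_p = 0.8)
  sub <- M3[cbind(2:10, 1:9)]
  expect_equal(prod(sub),
               prod(immunodem:::survival_by_age(sched3, p3, 0.8)[1:9]))
})

test_that("the eigenvalue agrees with the Euler-Lotka characteristic root", {
  p <- fig_landscape_params()
  sched <- age_schedules(n_ages = 30, maturity = 8, i_x = 0.2,
                         fertility = 0.9)
  M <- build_leslie(sched, p, s_p = 0.85)
  lam_eig <- eigen_summary(M)$lambda
  s_x <- immunodem:::survival_by_age(sched, p, 0.85)
  lam_el <- euler_lotka_lambda(s_x, sched$f)
  expect_lt(abs(lam_eig - lam_el), 1e-10)
})

test_that("eigen summaries satisfy the eigen identities and scaling", {
  M <- matrix(0, 2, 2); M[2, 1] <- 0.5; M[1, 2] <- 2
  es <- eigen_summary(M)
  expect_equal(es$lambda, 1, tolerance = 1e-12)
  expect_equal(sum(es$ages$w * es$ages$v), 1, tolerance = 1e-12)
  # fertility only at age 1: lambda = f_1 and later ages are worthless
  M1 <- matrix(0, 4, 4); M1[cbind(2:4, 1:3)] <- 0.7; M1[1, 1] <- 1.3
  es1 <- eigen_summary(M1)
  expect_equal(es1$lambda, 1.3, tolerance = 1e-12)
  expect_equal(lambda_sensitivity_survival(es1), rep(0, 3),
               tolerance = 1e-12)
  set.seed(5)
  for (k in 1:5) {
    M <- random_leslie(A = 25, maturity = 6)
    es <- eigen_summary(M)
    w <- es$ages$w; v <- es$ages$v
    expect_lt(max(abs(M %*% w - es$lambda * w)), 1e-10 * max(w))
    expect_lt(max(abs(t(v) %*% M - es$lambda * t(v))), 1e-10 * max(v))
    expect_true(all(w >= 0) && all(v >= 0))
    expect_equal(sum(es$ages$w_norm), 1, tolerance = 1e-12)
  }
  expect_error(eigen_summary(matrix(-1, 2, 2)), "non-negative")
})

test_that("survival sensitivities match eigenvalue finite differences", {
  set.seed(17)
  for (k in 1:8) {
    M <- random_leslie(A = sample(20:40, 1))
    sens <- lambda_sensitivity_survival(eigen_summary(M))
    for (x in sort(sample(seq_along(sens), 5))) {
      fd <- fd_lambda_entry(M, x + 1, x)
      expect_lt(rel_err(sens[x], fd), 1e-5)
    }
    expect_true(all(sens >= -1e-12))
  }
  # constant schedules beyond maturity: impact declines with age
  p <- fig_landscape_params()
  sched <- age_schedules(n_ages = 30, maturity = 5, i_x = 0.2, fertility = 1)
  es <- eigen_summary(build_leslie(sched, p, 0.85))
  sens <- lambda_sensitivity_survival(es)
  expect_true(all(diff(sens[5:29]) < 1e-12))
})

test_that("chain-rule growth-rate derivatives match finite differences", {
  p <- fig_landscape_params()
  sched <- age_schedules(n_ages = 30, maturity = 8, i_x = 0.25,
                         fertility = 1.1)
  lam <- function(sp) eigen_summary(build_leslie(sched, p, sp))$lambda
  for (sp in c(0.5, 0.8, 0.95)) {
    h <- 1e-5
    fd <- (lam(sp + h) - lam(sp - h)) / (2 * h)
    expect_lt(rel_err(lambda_sensitivity_parameter(sched, p, sp), fd), 1e-4)
  }
  # below the within-age optimum more specificity buys growth
  expect_gt(lambda_sensitivity_parameter(sched, p, 0.5), 0)
  # mu_d route
  lam_md <- function(f) {
    p2 <- p; p2$mu_d <- f
    eigen_summary(build_leslie(sched, p2, 0.8))$lambda
  }
  h <- 1e-5
  fd_md <- (lam_md(p$mu_d + h) - lam_md(p$mu_d - h)) / (2 * h)
  expect_lt(rel_err(lambda_sensitivity_parameter(sched, p, 0.8,
                                                 target = "mu_d"), fd_md),
            1e-4)
  # nothing to gain when infection is absent and false positives harmless
  sched0 <- age_schedules(n_ages = 20, maturity = 5, i_x = 0)
  p0 <- fixed_params(mu_i = 0, mu_b = 1 / 60)
  expect_equal(lambda_sensitivity_parameter(sched0, p0, 1), 0,
               tolerance = 1e-12)
})

test_that("growth falls when any single age's survival falls", {
  p <- fig_landscape_params()
  sched <- age_schedules(n_ages = 20, maturity = 5, i_x = 0.2, fertility = 1)
  lam0 <- eigen_summary(build_leslie(sched, p, 0.85))$lambda
  for (x in c(1, 4, 10, 19)) {
    M <- build_leslie(sched, p, 0.85)
    M[x + 1, x] <- M[x + 1, x] * 0.9
    expect_lt(eigen_summary(M)$lambda, lam0)
  }
})

test_that("with constant infection the lifespan optimum is the within-age
           optimum and ignores baseline mortality", {
  p <- fig_landscape_params()
  p$i_x <- 0.15
  within <- optimal_specificity(p)$s_p
  for (mub in c(1 / 60, 1 / 6)) {
    sched <- age_schedules(n_ages = 40, maturity = 10, i_x = 0.15,
                           mu_b = mub)
    life <- optimize_lifespan_sensitivity(sched, p)
    expect_lt(abs(life$s_p - within), 1e-6)
  }
  # age-varying infection decouples the two optima
  sched_v <- age_schedules(n_ages = 40, maturity = 10,
                           i_x = c(rep(0.5, 10), rep(0.02, 30)))
  life_v <- optimize_lifespan_sensitivity(sched_v, p)
  expect_gt(abs(life_v$s_p - within), 1e-3)
})
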