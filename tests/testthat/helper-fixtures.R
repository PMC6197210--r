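# Shared fixtures: parameter sets and random generators used across tests.

# hazard parameters of the bimodal-landscape figure
fig_landscape_params <- function(tradeoff = "exponential") {
  immune_params(gamma = 4, eta = 0.8, rho = 0.01, mu_b = 1 / 60,
                mu_d = 1, i_x = 0.5, tradeoff = tradeoff)
}

# fixed-hazard parameters with a known interior specificity optimum
fixed_params <- function(mu_i = 0.5, mu_id = 0, mu_d = 1, i_x = 0.5,
                         gamma = 4, mu_b = 0) {
  immune_params(gamma = gamma, mu_b = mu_b, mu_d = mu_d, i_x = i_x,
                mu_i = mu_i, mu_id = mu_id, tradeoff = "fixed")
}

# random valid fixed-hazard parameters (mu_d > mu_id guaranteed)
random_fixed_params <- function() {
  mu_d <- runif(1, 0.3, 3)
  immune_params(gamma = runif(1, 1, 6), mu_b = runif(1, 0, 0.05),
                mu_d = mu_d, i_x = runif(1, 0.05, 0.95),
                mu_i = runif(1, 0.05, 1.5), mu_id = runif(1, 0, 0.8) * mu_d,
                tradeoff = "fixed")
}

# random valid exponential-closure parameters
random_closure_params <- function() {
  immune_params(gamma = runif(1, 1, 6), eta = runif(1, 0.3, 1.5),
                rho = runif(1, 0, 0.05), mu_b = runif(1, 0, 0.05),
                mu_d = runif(1, 0.3, 3), i_x = runif(1, 0.05, 0.95))
}

# random Leslie fixture with survival/fertility schedules of random shape
random_leslie <- function(A = sample(30:60, 1), maturity = sample(5:15, 1)) {
  s <- runif(A - 1, 0.5, 0.98)
  f <- rep(0, A)
  f[maturity:A] <- runif(A - maturity + 1, 0.2, 2)
  M <- matrix(0, A, A)
  M[cbind(2:A, 1:(A - 1))] <- s
  M[1, ] <- f
  M
}

# central finite difference of the dominant eigenvalue w.r.t. one entry
fd_lambda_entry <- function(M, i, j, h = 1e-4) {
  lam <- function(M) max(Re(eigen(M, only.values = TRUE)$values))
  Mp <- M; Mp[i, j] <- Mp[i, j] + h
  Mm <- M; Mm[i, j] <- Mm[i, j] - h
  (lam(Mp) - lam(Mm)) / (2 * h)
}

rel_err <- function(a, b) abs(a - b) / max(abs(b), 1e-12)
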