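#' Closed-form boundary of the discrimination-response map
#'
#' Differentiating the closed-form within-age optimal specificity with
#' respect to the discrimination power gives
#' \eqn{d s_p^*/d\gamma = -[\log R + \log\{(1-i_x)/i_x\} - \log\gamma + 1]/\gamma^2},
#' which changes sign on the curve
#' \deqn{R_b(\gamma) = \frac{\gamma\, i_x}{e\,(1 - i_x)}.}
#' Above the curve (damaging responses, large `R`) a reduction in
#' discrimination selects for higher specificity, i.e. lower sensitivity;
#' below it, for higher sensitivity. The curve is linear in \eqn{\gamma} and
#' passes through the origin.
#'
#' @param gamma Discrimination power(s); positive, vectorised.
#' @param i_x Probability of infection, strictly inside `(0, 1)`.
#' @return Boundary values of `R`, one per `gamma`.
#' @examples
#' boundary_R(4, i_x = 0.15)   # ~0.2597
#' @export
boundary_R <- function(gamma, i_x) {
  if (any(gamma <= 0)) abort("`gamma` must be positive.")
  if (i_x <= 0 || i_x >= 1) abort("`i_x` must lie strictly inside (0, 1).")
  gamma * i_x / (exp(1) * (1 - i_x))
}

# numerical within-age optimal specificity as a function of (gamma, R, i_x)
# alone: the optimum depends on the hazards only through R, so we fix
# mu_d = 1, mu_id = 0, mu_i = R without loss of generality.
opt_sp_of_R <- function(gamma, R, i_x, n_grid = 513, tol = 1e-10) {
  f <- function(sp) {
    fn <- exp(-gamma * (1 - sp))
    exp(-((1 - i_x) * R * (1 - sp) + i_x * fn))
  }
  grid_refine(f, 0, 1, n_grid, tol)
}

#' Map the response of the within-age optimum to reduced discrimination
#'
#' For every cell of a (`gamma`, `R`) grid, the within-age optimal strategy
#' is located numerically at `gamma` and again at `gamma_shrink * gamma`, and
#' the responses of both optimal specificity and optimal sensitivity to that
#' reduction are recorded. The sign grid classifies each cell by the response
#' of \eqn{s_p^*}: `+1` where reducing discrimination raises specificity
#' (lowers sensitivity), `-1` where it lowers specificity, `0` where the
#' optimum is clamped to the feasibility boundary in either evaluation or the
#' response is numerically zero. The independently derived closed-form
#' boundary [boundary_R()] is attached for comparison, not assumed: use
#' [estimate_boundary()] to locate the numeric sign change.
#'
#' The interior optimal sensitivity \eqn{s_e^* = 1 - (1-i_x)R/(\gamma i_x)}
#' is monotone in `gamma`, so the sign structure of the map is carried by the
#' specificity response; both are reported (`d_sp`, `d_se`).
#'
#' @param i_x Probability of infection, strictly inside `(0, 1)`.
#' @param gamma_axis Strictly increasing positive discrimination powers.
#' @param R_axis Strictly increasing positive values of
#'   \eqn{R = \mu_i/(\mu_d - \mu_{id})}.
#' @param gamma_shrink Multiplicative reduction applied to `gamma` when
#'   probing the response (default 0.99).
#' @param n_grid Grid size of the inner one-dimensional optimisations.
#' @return An object of class `"boundary_map"`: a list with `grid` (tibble
#'   `gamma`, `R`, `sp_opt`, `d_sp`, `d_se`, `sign`), `analytic` (tibble
#'   `gamma`, `R_boundary`), and the axes and `i_x`.
#' @examples
#' bm <- discrimination_response_map(0.15, c(2, 4), c(0.1, 0.3, 0.6))
#' bm$grid$sign
#' @export
discrimination_response_map <- function(i_x, gamma_axis, R_axis,
                                        gamma_shrink = 0.99, n_grid = 513) {
  if (i_x <= 0 || i_x >= 1) abort("`i_x` must lie strictly inside (0, 1).")
  if (any(gamma_axis <= 0) || any(R_axis <= 0)) {
    abort("axes must be positive.")
  }
  if (is.unsorted(gamma_axis, strictly = TRUE) ||
      is.unsorted(R_axis, strictly = TRUE)) {
    abort("axes must be strictly increasing.")
  }
  eps <- 1e-7
  grid <- expand_grid(gamma = gamma_axis, R = R_axis)
  res <- pmap(grid, function(gamma, R) {
    sp1 <- opt_sp_of_R(gamma, R, i_x, n_grid)
    sp2 <- opt_sp_of_R(gamma_shrink * gamma, R, i_x, n_grid)
    d_sp <- sp2 - sp1
    d_se <- sensitivity_from_specificity(sp2, gamma_shrink * gamma) -
      sensitivity_from_specificity(sp1, gamma)
    clamped <- sp1 < eps || sp1 > 1 - eps || sp2 < eps || sp2 > 1 - eps
    sgn <- if (clamped || abs(d_sp) < eps) 0L else as.integer(sign(d_sp))
    tibble(sp_opt = sp1, d_sp = d_sp, d_se = d_se, sign = sgn)
  })
  grid <- dplyr::bind_cols(grid, list_rbind(res))
  analytic <- tibble(gamma = gamma_axis,
                     R_boundary = boundary_R(gamma_axis, i_x))
  structure(list(grid = grid, analytic = analytic, i_x = i_x,
                 gamma_axis = gamma_axis, R_axis = R_axis,
                 gamma_shrink = gamma_shrink),
            class = "boundary_map")
}

#' Locate the numeric sign-change boundary of a discrimination-response map
#'
#' For each `gamma` of the map, returns the midpoint between the largest `R`
#' whose cell responds with increased sensitivity (`sign == -1`) and the
#' smallest `R` responding with decreased sensitivity (`sign == +1`),
#' together with the half-width of that bracketing interval and the
#' closed-form boundary for comparison. Columns where the grid does not
#' bracket a sign change are dropped.
#'
#' @param map A `"boundary_map"` from [discrimination_response_map()].
#' @return A tibble with columns `gamma`, `R_numeric`, `half_width`,
#'   `R_analytic`.
#' @export
estimate_boundary <- function(map) {
  stopifnot(inherits(map, "boundary_map"))
  out <- map$grid |>
    group_by(.data$gamma) |>
    summarise(
      below = suppressWarnings(max(.data$R[.data$sign == -1L])),
      above = suppressWarnings(min(.data$R[.data$sign == +1L])),
      .groups = "drop") |>
    filter(is.finite(.data$below), is.finite(.data$above),
           .data$below < .data$above) |>
    mutate(R_numeric = (.data$below + .data$above) / 2,
           half_width = (.data$above - .data$below) / 2)
  out$R_analytic <- boundary_R(out$gamma, map$i_x)
  out[, c("gamma", "R_numeric", "half_width", "R_analytic")]
}

#' @export
print.boundary_map <- function(x, ...) {
  cat(sprintf("<boundary_map> i_x = %g, %d x %d (gamma x R) cells\n",
              x$i_x, length(x$gamma_axis), length(x$R_axis)))
  print(estimate_boundary(x))
  invisible(x)
}

#' @rdname discrimination_response_map
#' @param x,object A `"boundary_map"`.
#' @param ... Unused.
#' @export
tidy.boundary_map <- function(x, ...) x$grid

#' @rdname discrimination_response_map
#' @export
autoplot.boundary_map <- function(object, ...) {
  ggplot(object$grid, aes(x = .data$gamma, y = .data$R,
                          fill = factor(.data$sign))) +
    geom_tile() +
    geom_line(data = object$analytic,
              aes(x = .data$gamma, y = .data$R_boundary),
              inherit.aes = FALSE, linewidth = 1) +
    scale_fill_manual(values = c("-1" = "#2166ac", "0" = "grey85",
                                 "1" = "#b2182b"),
                      name = expression(Delta ~ s[p]^"*")) +
    labs(x = expression(gamma), y = "R") +
    theme_minimal()
}
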