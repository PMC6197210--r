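#' Survival landscape over sensitivity and effector magnitude
#'
#' Evaluates age-specific survival on a grid of sensitivity (`s_e`) and
#' undetected-infection hazard (`mu_d`) with the hazard trade-off active, so
#' each `mu_d` carries its implied immunopathology hazards and each `s_e` is
#' mapped back to specificity through the inverse ROC link. Combining the two
#' trade-offs this way yields a characteristically bimodal surface: one
#' survival peak pairs low detection with a large, damaging effector response
#' (low `s_e`, low `mu_d`), the other pairs high detection with a small
#' response (high `s_e`, high `mu_d`).
#'
#' @inheritParams survival_age
#' @param se_axis Strictly increasing sensitivities, each below the
#'   attainable ceiling `1 - exp(-gamma)`.
#' @param mud_axis Strictly increasing non-negative `mu_d` values.
#' @return An object of class `"survival_landscape"`: a list with
#'   \describe{
#'     \item{grid}{tibble `(s_e, mu_d, survival)` in row-major order
#'       (`s_e` varying slowest),}
#'     \item{survival}{the matrix (rows `se_axis`, columns `mud_axis`),}
#'     \item{peaks}{tibble of strict local maxima from [local_maxima()],}
#'     \item{se_axis, mud_axis, params}{the inputs.}
#'   }
#' @examples
#' p <- immune_params(gamma = 4, eta = 0.8, rho = 0.01, mu_b = 1 / 60,
#'                    i_x = 0.5)
#' ls <- survival_landscape(p, seq(0.01, 0.97, length.out = 60),
#'                          seq(0, 5, length.out = 60))
#' nrow(ls$peaks)   # 2
#' @export
survival_landscape <- function(params, se_axis, mud_axis) {
  stopifnot(inherits(params, "immune_params"))
  if (params$tradeoff == "fixed") {
    abort("the landscape requires an active hazard trade-off (`exponential` or `linear`).")
  }
  if (is.unsorted(se_axis, strictly = TRUE) ||
      is.unsorted(mud_axis, strictly = TRUE)) {
    abort("axes must be strictly increasing.")
  }
  sp_axis <- specificity_from_sensitivity(se_axis, params$gamma)
  sv <- vapply(mud_axis, function(m) survival_age(params, sp_axis, mu_d = m),
               numeric(length(se_axis)))
  pk <- local_maxima(sv)
  pk$s_e <- se_axis[pk$row]
  pk$mu_d <- mud_axis[pk$col]
  grid <- expand_grid(s_e = se_axis, mu_d = mud_axis)
  grid$survival <- as.vector(t(sv))
  structure(list(grid = grid, survival = sv, peaks = pk,
                 se_axis = se_axis, mud_axis = mud_axis, params = params),
            class = "survival_landscape")
}

#' Strict local maxima of a matrix under 8-connectivity
#'
#' A cell is a peak when its value strictly exceeds every existing neighbour
#' (boundary cells are compared over the neighbours they have). Plateaus
#' therefore contain no peaks. Results are ordered by decreasing value, ties
#' broken by row then column, making the ordering deterministic.
#'
#' @param m A numeric matrix, or a `"survival_landscape"`.
#' @return A tibble with columns `row`, `col`, `value`.
#' @examples
#' m <- outer(1:5, 1:5, function(i, j) -(i - 3)^2 - (j - 2)^2)
#' local_maxima(m)
#' @export
local_maxima <- function(m) {
  if (inherits(m, "survival_landscape")) m <- m$survival
  if (!is.matrix(m) || length(m) == 0L) abort("`m` must be a non-empty matrix.")
  nr <- nrow(m); nc <- ncol(m)
  # pad with -Inf so boundary cells compare only over existing neighbours
  p <- matrix(-Inf, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  shifts <- expand.grid(dr = -1:1, dc = -1:1)
  shifts <- shifts[!(shifts$dr == 0 & shifts$dc == 0), ]
  nb_max <- matrix(-Inf, nr, nc)
  for (k in seq_len(nrow(shifts))) {
    nb <- p[(2:(nr + 1L)) + shifts$dr[k], (2:(nc + 1L)) + shifts$dc[k]]
    nb_max <- pmax(nb_max, nb)
  }
  idx <- which(m > nb_max, arr.ind = TRUE)
  out <- tibble(row = as.integer(idx[, 1]), col = as.integer(idx[, 2]),
                value = m[idx])
  arrange(out, desc(.data$value), .data$row, .data$col)
}

#' @export
print.survival_landscape <- function(x, ...) {
  cat(sprintf("<survival_landscape> %d x %d grid, %d peak(s)\n",
              length(x$se_axis), length(x$mud_axis), nrow(x$peaks)))
  print(x$peaks)
  invisible(x)
}

#' @rdname survival_landscape
#' @param x A `"survival_landscape"`.
#' @param ... Unused.
#' @export
tidy.survival_landscape <- function(x, ...) x$grid

#' @rdname survival_landscape
#' @export
glance.survival_landscape <- function(x, ...) {
  tibble(n_se = length(x$se_axis), n_mud = length(x$mud_axis),
         n_peaks = nrow(x$peaks),
         max_survival = max(x$survival), min_survival = min(x$survival))
}

#' @rdname survival_landscape
#' @param object A `"survival_landscape"`.
#' @export
autoplot.survival_landscape <- function(object, ...) {
  ggplot(object$grid, aes(x = .data$mu_d, y = .data$s_e,
                          fill = .data$survival)) +
    geom_raster() +
    geom_point(data = object$peaks, aes(x = .data$mu_d, y = .data$s_e),
               inherit.aes = FALSE, shape = 4, size = 3) +
    scale_fill_gradient(low = "#67000d", high = "#fff5f0") +
    labs(x = expression(mu[d]), y = expression(s[e]), fill = "survival") +
    theme_minimal()
}
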