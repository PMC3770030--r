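#' Double-well potential for distance regularization
#'
#' The potential `p(s)` penalizing deviation of `|grad phi|` from a signed
#' distance profile: `p(s) = (1/(2*pi)^2) (1 - cos(2*pi*s))` for `s <= 1` and
#' `p(s) = (s - 1)^2 / 2` for `s > 1`. It has minima at `s = 0` and `s = 1`,
#' so the level-set function is driven either flat or to unit gradient, which
#' maintains a signed distance profile near the zero level set without any
#' reinitialization.
#'
#' @param s non-negative numeric vector.
#' @return `p(s)`, same length as `s`.
#' @export
double_well <- function(s) {
  if (any(s < 0)) stop("'s' must be non-negative")
  ifelse(s <= 1,
         (1 - cos(2 * pi * s)) / (2 * pi)^2,
         0.5 * (s - 1)^2)
}

#' Diffusion-rate factor of the distance regularizer
#'
#' `d_p(s) = p'(s) / s` for the double-well potential [double_well()], with
#' the removable singularity at `s = 0` filled by its limit 1. `d_p(1) = 0`
#' (the unit-gradient well) and `d_p(s) -> 1` as `s -> Inf`, so the
#' regularizing diffusion is forward for `|grad phi| > 1`, vanishes at 1, and
#' can be backward below 1 — this is what flattens or sharpens `phi` toward a
#' signed distance profile.
#'
#' @param s non-negative numeric vector.
#' @return `d_p(s)`, same length as `s`.
#' @export
d_p <- function(s) {
  if (any(s < 0)) stop("'s' must be non-negative")
  out <- ifelse(s <= 1,
                sinc(2 * s),        # sin(2 pi s) / (2 pi s)
                1 - 1 / s)          # (s - 1) / s
  out[s == 0] <- 1
  out
}

# sin(pi x) / (pi x), the normalized sinc (finite at 0 handled by caller)
sinc <- function(x) sin(pi * x) / (pi * x)

#' Smoothed Dirac delta
#'
#' Compactly supported smooth delta used in level-set evolution:
#' `(1/(2 eps)) (1 + cos(pi x / eps))` on `|x| <= eps`, 0 outside. Integrates
#' to 1 and is the derivative of [smooth_heaviside()].
#'
#' @param x numeric vector.
#' @param epsilon positive smoothing half-width. Default 1.5.
#' @return delta values, same length as `x`.
#' @export
smooth_delta <- function(x, epsilon = 1.5) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0) {
    stop("'epsilon' must be a single positive number")
  }
  ifelse(abs(x) <= epsilon,
         (1 + cos(pi * x / epsilon)) / (2 * epsilon),
         0)
}

#' Smoothed Heaviside step
#'
#' `H(x) = (1/2)(1 + x/eps + sin(pi x / eps)/pi)` on `|x| <= eps`, 1 above,
#' 0 below; its derivative is [smooth_delta()].
#'
#' @inheritParams smooth_delta
#' @return step values in `[0, 1]`.
#' @export
smooth_heaviside <- function(x, epsilon = 1.5) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0) {
    stop("'epsilon' must be a single positive number")
  }
  ifelse(x > epsilon, 1,
         ifelse(x < -epsilon, 0,
                0.5 * (1 + x / epsilon + sin(pi * x / epsilon) / pi)))
}

#' Binary-step initial level-set function
#'
#' Builds the initial level-set function from the initial region as a binary
#' step: `-c` inside the region, `+c` outside (negative inside by
#' convention). The distance-regularization term then relaxes it toward a
#' signed distance profile during evolution.
#'
#' @param r0 nonempty logical mask of the initial region.
#' @param c positive step height. Default 2.
#' @return numeric matrix `phi0`.
#' @export
init_lsf <- function(r0, c = 2) {
  r0 <- as_mask(r0)
  if (!any(r0)) stop("initial region is empty")
  if (!is.numeric(c) || length(c) != 1L || c <= 0) {
    stop("'c' must be a single positive number")
  }
  phi <- matrix(c, nrow(r0), ncol(r0))
  phi[r0] <- -c
  phi
}

#' Parameters of the modified distance-regularized level-set evolution
#'
#' Bundles and validates the evolution parameters. `mu` weights the distance
#' regularization (diffusion-like, so `mu * time_step < 0.25` is required for
#' explicit-Euler stability), `lam` weights the edge term that pulls the zero
#' level set to boundaries, `area_alpha` weights the area term that drives
#' expansion (negative expands the inside-negative region) and is used in
#' phase 1 only, `epsilon` is the smoothing half-width of the delta/Heaviside
#' pair, and `inner_iters`/`outer_iters` are the step counts of the
#' fast-expansion and refinement phases.
#'
#' @param mu distance-regularization weight (> 0). Default 0.2.
#' @param lam edge-term weight (> 0). Default 5.
#' @param area_alpha phase-1 area-term weight. Default -1.
#' @param epsilon delta/Heaviside half-width (> 0). Default 1.5.
#' @param time_step explicit-Euler step (> 0). Default 1.
#' @param inner_iters phase-1 step count. Default 40.
#' @param outer_iters phase-2 step count. Default 15.
#' @param c binary-step height of the initial level-set function. Default 2.
#' @return a list of class `mdrls_params`.
#' @export
mdrls_params <- function(mu = 0.2, lam = 5, area_alpha = -1, epsilon = 1.5,
                         time_step = 1, inner_iters = 40L, outer_iters = 15L,
                         c = 2) {
  stopifnot(mu > 0, lam > 0, epsilon > 0, time_step > 0, c > 0,
            inner_iters >= 0, outer_iters >= 0)
  if (mu * time_step >= 0.25) {
    stop("unstable parameters: need mu * time_step < 0.25")
  }
  structure(list(mu = mu, lam = lam, area_alpha = area_alpha,
                 epsilon = epsilon, time_step = time_step,
                 inner_iters = as.integer(inner_iters),
                 outer_iters = as.integer(outer_iters), c = c),
            class = "mdrls_params")
}

#' One explicit-Euler step of the modified DRLSE
#'
#' Updates the level-set function by
#' `phi <- phi + tau * ( mu * div(d_p(|grad phi|) grad phi)
#'   + lam * delta_eps(phi) * div(Et grad phi / |grad phi|)
#'   + alpha * Et * delta_eps(phi) )`,
#' with the area term dropped when `include_area_term` is `FALSE` (the
#' refinement-phase equation, identical to `alpha = 0`). Central differences,
#' replicate boundaries; `|grad phi|` in the curvature term is regularized by
#' `1e-10` under the square root.
#'
#' @param phi level-set matrix (negative inside the object).
#' @param et energy/edge map in `[0, 1]`, same shape as `phi`.
#' @param params an [mdrls_params()] object.
#' @param include_area_term include the `alpha * Et * delta` expansion term.
#' @return the updated level-set matrix.
#' @export
evolve_step <- function(phi, et, params = mdrls_params(),
                        include_area_term = TRUE) {
  if (!identical(dim(phi), dim(et))) stop("'phi' and 'et' shapes differ")

  px <- (shift_rep(phi, 0, 1) - shift_rep(phi, 0, -1)) / 2
  py <- (shift_rep(phi, 1, 0) - shift_rep(phi, -1, 0)) / 2
  s <- sqrt(px^2 + py^2)
  s_reg <- sqrt(px^2 + py^2 + 1e-10)

  dp <- matrix(d_p(as.numeric(s)), nrow(phi), ncol(phi))
  reg <- divergence(dp * px, dp * py)

  nx <- px / s_reg
  ny <- py / s_reg
  delta <- smooth_delta(phi, params$epsilon)
  edge <- delta * divergence(et * nx, et * ny)

  upd <- params$mu * reg + params$lam * edge
  if (isTRUE(include_area_term)) {
    upd <- upd + params$area_alpha * et * delta
  }
  out <- phi + params$time_step * upd
  if (!all(is.finite(out))) {
    stop("level-set evolution produced non-finite values; ",
         "check parameter stability (mu * time_step < 0.25)")
  }
  out
}

#' Two-phase modified DRLSE segmentation
#'
#' Phase 1 runs `inner_iters` steps with the area term active
#' (`area_alpha = -1` by default: the inside-negative region expands quickly
#' toward the organ boundary while the edge term restrains it). Phase 2 runs
#' `outer_iters` steps with the area term abolished, so evolution is dominated
#' by the edge force and the contour settles accurately on the boundary. No
#' reinitialization is ever performed between steps.
#'
#' @param phi0 initial level-set matrix (see [init_lsf()]).
#' @param et energy-tuned edge map in `[0, 1]`.
#' @param params an [mdrls_params()] object.
#' @return the final level-set matrix.
#' @export
segment_two_phase <- function(phi0, et, params = mdrls_params()) {
  phi <- phi0
  for (i in seq_len(params$inner_iters)) {
    phi <- evolve_step(phi, et, params, include_area_term = TRUE)
  }
  for (i in seq_len(params$outer_iters)) {
    phi <- evolve_step(phi, et, params, include_area_term = FALSE)
  }
  phi
}

# divergence of a vector field (fx, fy) by central differences,
# replicate boundary
divergence <- function(fx, fy) {
  (shift_rep(fx, 0, 1) - shift_rep(fx, 0, -1)) / 2 +
    (shift_rep(fy, 1, 0) - shift_rep(fy, -1, 0)) / 2
}
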