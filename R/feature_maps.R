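#' Sigmoid speed map for front propagation
#'
#' Maps a gradient-magnitude map to a contour-propagation speed map by the
#' sigmoid intensity transformation
#' `(Max - Min) / (1 + exp(-(gm - beta)/alpha)) + Min`.
#' With negative `alpha` the speed decreases with gradient magnitude, so the
#' front runs fast through homogeneous tissue and stalls at edges. `beta`
#' centres the transition; `|alpha|` sets its width.
#'
#' @param gm non-negative numeric matrix (gradient magnitude).
#' @param alpha nonzero sigmoid width; negative makes the map decreasing in
#'   `gm`. Default -0.5.
#' @param beta gradient magnitude at which the output is halfway. Default 3.
#' @param out_min,out_max output range, `out_min < out_max`. Defaults 0, 1.
#' @return numeric matrix with values in `[out_min, out_max]`.
#' @export
sigmoid_speed <- function(gm, alpha = -0.5, beta = 3, out_min = 0, out_max = 1) {
  if (!is.matrix(gm) || !is.numeric(gm)) stop("gm must be a numeric matrix")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha == 0) {
    stop("'alpha' must be a single nonzero number")
  }
  if (out_min >= out_max) stop("'out_min' must be smaller than 'out_max'")
  v <- (out_max - out_min) / (1 + exp(-(gm - beta) / alpha)) + out_min
  matrix(pmin(pmax(v, out_min), out_max), nrow(gm), ncol(gm))
}

#' Edge indicator map
#'
#' The stopping function `g = 1 / (1 + gm^2)` of edge-based level-set methods:
#' close to 1 in homogeneous regions (gradient magnitude near 0) and small at
#' strong edges, so the evolving contour slows and stops at object boundaries.
#' Values lie in `(0, 1]`, equal to 1 exactly where `gm = 0`.
#'
#' @param gm non-negative numeric matrix (gradient magnitude).
#' @return numeric matrix in `(0, 1]`, same shape as `gm`.
#' @export
edge_indicator <- function(gm) {
  if (!is.matrix(gm) || !is.numeric(gm)) stop("gm must be a numeric matrix")
  if (any(gm < 0)) stop("gradient magnitude must be non-negative")
  1 / (1 + gm^2)
}
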