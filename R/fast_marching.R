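#' Front-arrival time map by fast marching
#'
#' Solves the eikonal equation `|grad T| * F = 1` on the pixel grid with front
#' speed `F` given by the energy map and `T = 0` at the seed pixels, using the
#' first-order Godunov upwind scheme with a 4-connected stencil and the
#' one-pass heap-ordered fast-marching algorithm. Pixels with zero speed are
#' hard barriers: the front never arrives (`T = Inf`) unless they are seeded.
#'
#' @param energy non-negative numeric matrix of front speeds (typically the
#'   energy-decremented speed map, or the raw sigmoid speed map when no
#'   standard line is available).
#' @param seeds integer matrix (>= 1 row, 2 columns) of 1-based `(row, col)`
#'   seed pixels; duplicates are dropped.
#' @return numeric matrix of non-negative arrival times, `0` exactly at seeds.
#' @export
solve_eikonal <- function(energy, seeds) {
  if (!is.matrix(energy) || !is.numeric(energy)) {
    stop("energy must be a numeric matrix")
  }
  if (any(!is.finite(energy)) || any(energy < 0)) {
    stop("energy must be finite and non-negative")
  }
  seeds <- validate_seeds(seeds, dim(energy))
  fast_march_cpp(energy, seeds)
}

#' Extract the initial region from a time map
#'
#' Takes a snapshot of the propagating front at time `t_star`: the initial
#' organ region is the set of pixels the front has reached by then,
#' `{T <= t_star}`. Larger thresholds give monotonically larger regions.
#'
#' @param time_map arrival-time matrix from [solve_eikonal()].
#' @param t_star non-negative time threshold; `0` yields the seeds only.
#' @return logical mask of the initial region.
#' @export
extract_initial_region <- function(time_map, t_star = 100) {
  if (!is.matrix(time_map) || !is.numeric(time_map)) {
    stop("time_map must be a numeric matrix")
  }
  if (!is.numeric(t_star) || length(t_star) != 1L || t_star < 0) {
    stop("'t_star' must be a single non-negative number")
  }
  time_map <= t_star
}

validate_seeds <- function(seeds, shape) {
  if (is.data.frame(seeds)) seeds <- as.matrix(seeds)
  if (is.null(dim(seeds)) && length(seeds) == 2L) seeds <- rbind(seeds)
  if (!is.matrix(seeds) || ncol(seeds) != 2L || nrow(seeds) < 1L) {
    stop("seeds must be a >=1 x 2 matrix of (row, col) pixels")
  }
  storage.mode(seeds) <- "integer"
  if (any(is.na(seeds))) stop("seeds contain missing values")
  if (any(seeds[, 1] < 1L | seeds[, 1] > shape[1] |
          seeds[, 2] < 1L | seeds[, 2] > shape[2])) {
    stop("seed outside the image")
  }
  unique(seeds)
}
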