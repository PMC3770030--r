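#' Rasterize a standard line onto the pixel grid
#'
#' The standard line is a physician-drawn polyline separating the target organ
#' from an adjacent organ of similar intensity. Each segment is rasterized
#' with Bresenham's algorithm; the result is the set of grid pixels the
#' polyline passes through, as a logical mask.
#'
#' Vertices are 1-based `(row, col)` pixel coordinates inside the grid. The
#' on-disk JSON interchange format ([read_annotation()]) uses 0-based
#' coordinates; conversion happens at that boundary.
#'
#' @param vertices numeric matrix with >= 2 rows and 2 columns `(row, col)`.
#' @param shape integer vector `c(nrow, ncol)` of the target grid.
#' @return logical matrix marking rasterized line pixels.
#' @export
rasterize_line <- function(vertices, shape) {
  vertices <- validate_line(vertices, shape)
  mask <- matrix(FALSE, shape[1], shape[2])
  vr <- round(vertices[, 1]); vc <- round(vertices[, 2])
  for (k in seq_len(nrow(vertices) - 1L)) {
    px <- bresenham(vr[k], vc[k], vr[k + 1L], vc[k + 1L])
    mask[cbind(px[, 1], px[, 2])] <- TRUE
  }
  mask
}

#' Euclidean distance field to a standard line
#'
#' Exact Euclidean distance transform of the rasterized polyline: each pixel
#' carries the shortest distance (pixel units) to any pixel of the line, zero
#' on the line itself.
#'
#' @inheritParams rasterize_line
#' @return non-negative numeric matrix of shape `shape`.
#' @export
distance_to_line <- function(vertices, shape) {
  distance_to_mask(rasterize_line(vertices, shape))
}

#' Euclidean distance field to a binary region
#'
#' Exact Euclidean distance of every pixel to the nearest pixel of `mask`
#' (zero inside the region). Used for the distance to the energy source
#' region in the energy-tune rules.
#'
#' @param mask logical (or 0/1) matrix; must contain at least one TRUE pixel.
#' @return non-negative numeric matrix, 0 exactly on `mask`.
#' @export
distance_to_mask <- function(mask) {
  mask <- as_mask(mask)
  if (!any(mask)) stop("mask is empty: distance field undefined")
  d <- EBImage::distmap(1 - mask, metric = "euclidean")
  matrix(as.numeric(d), nrow(mask), ncol(mask))
}

#' Energy decrement of a speed map along the standard line
#'
#' Stalls the fast-marching front in the coupling area between two organs:
#' every pixel closer than `t_d` to the standard line has its propagation
#' speed replaced by the minimum of the speed map, so the front cannot leak
#' across the line even where the image gradient is weak.
#'
#' @param speed numeric speed-map matrix.
#' @param d_line distance field to the standard line ([distance_to_line()]),
#'   same shape as `speed`.
#' @param t_d non-negative distance threshold in pixels. Default 1.5: the
#'   thinnest band that is still an impenetrable 4-connected barrier around
#'   the rasterized line; wider bands carve organ pixels out of the initial
#'   region when the line is drawn on the boundary itself.
#' @return numeric matrix: `min(speed)` within the band `d_line < t_d`,
#'   the original speed elsewhere.
#' @export
energy_decrement <- function(speed, d_line, t_d = 1.5) {
  if (!identical(dim(speed), dim(d_line))) {
    stop("'speed' and 'd_line' must have the same shape")
  }
  if (!is.numeric(t_d) || length(t_d) != 1L || t_d < 0) {
    stop("'t_d' must be a single non-negative number")
  }
  out <- speed
  out[d_line < t_d] <- min(speed)
  out
}

#' Source energy radiated by the initial region
#'
#' Every pixel of the energy source region contributes
#' `exp(-D/sigma) * g(source pixel)` to every pixel of the grid, with `D` the
#' Euclidean distance between the two pixels: pixels close to the source
#' absorb more energy. The sum runs over all source pixels (exact, O(N |R0|));
#' `boundary_only = TRUE` restricts the source to its 4-connected boundary
#' pixels as a faster approximation.
#'
#' @param r0 logical matrix, the energy source region (nonempty).
#' @param g edge-indicator matrix ([edge_indicator()]), same shape.
#' @param sigma positive decay length in pixels. Default 10.
#' @param boundary_only restrict the sum to boundary pixels of `r0`
#'   (approximation, off by default).
#' @return non-negative numeric matrix; strictly positive everywhere.
#' @export
source_energy <- function(r0, g, sigma = 10, boundary_only = FALSE) {
  r0 <- as_mask(r0)
  if (!any(r0)) stop("energy source region is empty")
  if (!identical(dim(r0), dim(g))) stop("'r0' and 'g' must have the same shape")
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("'sigma' must be a single positive number")
  }
  src <- if (isTRUE(boundary_only)) mask_boundary(r0) else r0
  source_energy_cpp(g, src, sigma)
}

#' Energy tune of the edge map using the standard line
#'
#' Re-weights the edge-indicator map before level-set evolution, treating the
#' initial region as an energy source. Inside the source the energy is
#' enhanced; pixels at least as close to the standard line as to the source
#' (the coupling area, where leaked energy accumulates) are decayed by
#' `beta * E / D_l`; everything else keeps its edge value. At `D_l = 0` the
#' decay branch takes its continuous limit: 0 where the source energy is
#' positive, `g` where it vanishes.
#'
#' @param g edge-indicator matrix.
#' @param e_src source-energy field ([source_energy()]).
#' @param r0 logical matrix, the energy source region.
#' @param d_line distance field to the standard line.
#' @param d_src distance field to `r0` ([distance_to_mask()]).
#' @param tune_alpha enhancement weight inside the source. Default 1.
#' @param tune_beta decay weight in the coupling area. Default 1.
#' @return numeric matrix in `[0, 1]`.
#' @export
energy_tune_line <- function(g, e_src, r0, d_line, d_src,
                             tune_alpha = 1, tune_beta = 1) {
  r0 <- as_mask(r0)
  check_aligned(g, e_src, r0, d_line, d_src)
  n <- sum(r0)
  if (n == 0L) stop("energy source region is empty")

  out <- g
  # coupling area: at least as close to the line as to the source
  cpl <- !r0 & (d_line <= d_src)
  pos <- cpl & (d_line > 0)
  out[pos] <- pmax(0, g[pos] - tune_beta * e_src[pos] / d_line[pos])
  zero <- cpl & (d_line == 0)
  out[zero] <- ifelse(e_src[zero] > 0, 0, g[zero])
  out[r0] <- pmin(1, (tune_alpha / n) * e_src[r0] + g[r0])
  matrix(pmin(pmax(out, 0), 1), nrow(g), ncol(g))
}

#' Automatic energy tune of the edge map (no standard line)
#'
#' Same idea as [energy_tune_line()] but driven only by the distance to the
#' energy source: pixels farther than `d_t` from the source are decayed by
#' `beta * E / (D_r - d_t)`, pixels within the band `0 < D_r <= d_t` are
#' attenuated smoothly by `g / (1 + D_r / d_t)`, and source pixels are
#' enhanced. The band edge `D_r = d_t` belongs to the attenuation branch.
#'
#' @inheritParams energy_tune_line
#' @param d_t positive distance threshold partitioning the tune area
#'   (pixels). Default 2: the typical boundary-position uncertainty of the
#'   fast-marching initial region, so that energy beyond the plausible
#'   refill band is decayed while genuine boundary refinement is not.
#' @return numeric matrix in `[0, 1]`.
#' @export
energy_tune_auto <- function(g, e_src, r0, d_src, d_t = 2,
                             tune_alpha = 1, tune_beta = 1) {
  r0 <- as_mask(r0)
  check_aligned(g, e_src, r0, d_src)
  if (!is.numeric(d_t) || length(d_t) != 1L || d_t <= 0) {
    stop("'d_t' must be a single positive number")
  }
  n <- sum(r0)
  if (n == 0L) stop("energy source region is empty")

  out <- g
  far <- !r0 & (d_src > d_t)
  out[far] <- pmax(0, g[far] - tune_beta * e_src[far] / (d_src[far] - d_t))
  band <- !r0 & (d_src > 0) & (d_src <= d_t)
  out[band] <- g[band] / (1 + d_src[band] / d_t)
  out[r0] <- pmin(1, g[r0] + (tune_alpha / n) * e_src[r0])
  matrix(pmin(pmax(out, 0), 1), nrow(g), ncol(g))
}

# ---- internal helpers -------------------------------------------------------

validate_line <- function(vertices, shape) {
  if (is.data.frame(vertices)) vertices <- as.matrix(vertices)
  if (!is.matrix(vertices) || ncol(vertices) != 2L || nrow(vertices) < 2L) {
    stop("a standard line needs a >=2 x 2 matrix of (row, col) vertices")
  }
  if (any(vertices[, 1] < 1 | vertices[, 1] > shape[1] |
          vertices[, 2] < 1 | vertices[, 2] > shape[2])) {
    stop("standard-line vertices fall outside the image")
  }
  storage.mode(vertices) <- "double"
  vertices
}

bresenham <- function(r0, c0, r1, c1) {
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- sign(r1 - r0); sc <- sign(c1 - c0)
  n <- max(dr, dc) + 1L
  out <- matrix(0L, n, 2L)
  err <- dr - dc
  r <- r0; c <- c0
  for (i in seq_len(n)) {
    out[i, ] <- c(r, c)
    if (r == r1 && c == c1) return(out[seq_len(i), , drop = FALSE])
    e2 <- 2L * err
    if (e2 > -dc) { err <- err - dc; r <- r + sr }
    if (e2 < dr)  { err <- err + dr; c <- c + sc }
  }
  out
}

as_mask <- function(mask) {
  if (is.numeric(mask)) {
    if (!all(mask %in% c(0, 1))) stop("mask values must be 0/1 or logical")
    mask <- matrix(mask != 0, nrow(mask), ncol(mask))
  }
  if (!is.matrix(mask) || !is.logical(mask)) {
    stop("mask must be a logical matrix")
  }
  mask
}

# 4-connected inner boundary of a mask
mask_boundary <- function(mask) {
  interior <- mask &
    shift_rep(mask, 1, 0) & shift_rep(mask, -1, 0) &
    shift_rep(mask, 0, 1) & shift_rep(mask, 0, -1)
  mask & !interior
}

check_aligned <- function(...) {
  dims <- lapply(list(...), dim)
  if (length(unique(dims)) != 1L) stop("input fields have mismatched shapes")
  invisible(TRUE)
}
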