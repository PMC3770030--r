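#' Specification of the two-organ synthetic phantom
#'
#' Describes a synthetic 2-D slice emulating the structure that makes organ
#' extraction hard in abdominal CT: a target organ (A) directly adjacent to a
#' second organ (B) of similar mean intensity, the two sharing an interface
#' whose edge contrast is suppressed (fractured) along a stated fraction of
#' its length, on a darker background, with additive Gaussian noise. Organ A
#' is an ellipse; organ B is an ellipse carved back against organ A so the
#' two regions are overlap-free and share a long interface (two disjoint
#' plain ellipses could only touch at a point).
#'
#' @param shape grid dimensions `c(nrow, ncol)`. Default `c(256, 256)`.
#' @param organ_a,organ_b ellipse parameter lists
#'   `list(center = c(row, col), semi_axes = c(row_axis, col_axis))`.
#' @param intensity_a,intensity_b,background mean intensities (arbitrary
#'   units). Defaults 120, 110, 40: organs similar, background distant.
#' @param boundary_gap_fraction fraction of the shared interface with
#'   suppressed edge contrast, in `[0, 1]`. Default 0.3.
#' @param noise_sigma additive Gaussian noise scale. Default 5.
#' @param rng_seed integer seed making generation deterministic. Default 1.
#' @return a list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(256L, 256L),
                         organ_a = list(center = c(128, 92),
                                        semi_axes = c(58, 38)),
                         organ_b = list(center = c(128, 176),
                                        semi_axes = c(60, 52)),
                         intensity_a = 120, intensity_b = 110,
                         background = 40,
                         boundary_gap_fraction = 0.3,
                         noise_sigma = 5, rng_seed = 1L) {
  stopifnot(length(shape) == 2L, all(shape >= 32),
            boundary_gap_fraction >= 0, boundary_gap_fraction <= 1,
            noise_sigma >= 0)
  structure(list(shape = as.integer(shape), organ_a = organ_a,
                 organ_b = organ_b, intensity_a = intensity_a,
                 intensity_b = intensity_b, background = background,
                 boundary_gap_fraction = boundary_gap_fraction,
                 noise_sigma = noise_sigma, rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

#' Generate the two-organ phantom
#'
#' Builds the phantom image together with everything the pipeline needs:
#' the ground-truth mask of organ A, at least three seed pixels strictly
#' inside organ A, and the standard line — a polyline tracing the inter-organ
#' interface (offset one pixel into organ B, vertices at roughly 5-px
#' spacing). Within the stated gap fraction of the interface (a contiguous
#' arc centred on the interface midpoint) the intensity transition between
#' the organs is smoothed over a ramp, so the local gradient magnitude falls
#' below a quarter of the intact-interface gradient — the weak, fractured
#' boundary through which naive front propagation leaks.
#'
#' Deterministic given `rng_seed`; the caller's RNG state is left untouched.
#'
#' @param spec a [phantom_spec()].
#' @return a list with elements `image` (numeric matrix), `truth` (logical
#'   mask of organ A), `seeds` (integer matrix of 1-based `(row, col)`),
#'   `line` (numeric matrix of standard-line vertices), and `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(shape = c(128, 128),
#'   organ_a = list(center = c(64, 46), semi_axes = c(29, 19)),
#'   organ_b = list(center = c(64, 88), semi_axes = c(30, 26))))
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  nr <- spec$shape[1]; nc <- spec$shape[2]
  a <- spec$organ_a; b <- spec$organ_b

  mask_a <- ellipse_mask(spec$shape, a$center, a$semi_axes)
  ell_b <- ellipse_mask(spec$shape, b$center, b$semi_axes)
  if (mask_a[round(b$center[1]), round(b$center[2])] ||
      ell_b[round(a$center[1]), round(a$center[2])]) {
    stop("organ ellipses overlap degenerately (one centre inside the other)")
  }
  mask_b <- ell_b & !mask_a
  if (!any(mask_b)) stop("organ B is empty after carving against organ A")

  img <- matrix(spec$background, nr, nc)
  img[mask_b] <- spec$intensity_b
  img[mask_a] <- spec$intensity_a

  # interface arc of organ A's boundary facing organ B, parametrized by angle
  arc <- interface_arc(spec$shape, a, b)
  if (nrow(arc$points) < 2L) stop("organs are not adjacent: no interface")
  line <- resample_polyline(arc$points, spacing = 5)

  # fractured part of the interface: a contiguous central angular window of
  # the stated fraction. Within it (sharp tangential feather, wide gentle
  # radial ramp) the intensity transition between the organs is replaced by a
  # slow blend, so the local gradient collapses far below the intact-edge
  # crest while the window length stays the stated fraction of the interface.
  if (spec$boundary_gap_fraction > 0) {
    t_rng <- range(arc$t)
    half <- spec$boundary_gap_fraction * diff(t_rng) / 2
    t_mid <- mean(t_rng)
    sd_a <- ellipse_signed_distance(spec$shape, a$center, a$semi_axes)
    theta <- pixel_ellipse_angle(spec$shape, a$center, a$semi_axes)
    w_ramp <- 20  # blend half-width: gap gradient ~ (Ia-Ib)/(2*w_ramp)
    w_infl <- 40  # radial influence of the blend
    feather <- 0.04 # tangential feather, radians, centred on the window edge
    w_t <- pmin(pmax((half - abs(theta - t_mid)) / feather + 0.5, 0), 1)
    w_r <- pmin(pmax(1 - abs(sd_a) / w_infl, 0), 1)
    w_a <- pmin(pmax(0.5 - sd_a / (2 * w_ramp), 0), 1)
    blend <- spec$intensity_b + (spec$intensity_a - spec$intensity_b) * w_a
    lam <- w_t * w_r
    organs <- mask_a | mask_b
    img[organs] <- (lam * blend + (1 - lam) * img)[organs]
  }

  if (spec$noise_sigma > 0) {
    img <- img + with_local_seed(spec$rng_seed,
      matrix(stats::rnorm(nr * nc, 0, spec$noise_sigma), nr, nc))
  }

  seeds <- phantom_seeds(mask_a, a)
  list(image = img, truth = mask_a, seeds = seeds, line = line, spec = spec)
}

#' Write phantom artifacts to a directory
#'
#' Writes `image.png` (8-bit grayscale), `truth.png` (binary mask) and
#' `annotation.json` (seeds and standard line, 0-based coordinates, the
#' interchange format of [read_annotation()]).
#'
#' @param phantom result of [generate_phantom()].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_image_png(phantom$image, file.path(dir, "image.png"))
  write_mask_png(phantom$truth, file.path(dir, "truth.png"))
  write_annotation(phantom$seeds, phantom$line,
                   file.path(dir, "annotation.json"))
  invisible(dir)
}

# ---- internal helpers -------------------------------------------------------

ellipse_mask <- function(shape, center, semi_axes) {
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  c_ <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  ((r - center[1]) / semi_axes[1])^2 + ((c_ - center[2]) / semi_axes[2])^2 <= 1
}

# smooth first-order signed distance to an ellipse boundary (negative inside):
# (sqrt(q) - 1) / |grad sqrt(q)| with q the implicit quadratic form. Exact on
# circles, accurate near the boundary, and free of pixel-grid steps.
ellipse_signed_distance <- function(shape, center, semi_axes) {
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  c_ <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  u <- (r - center[1]) / semi_axes[1]
  v <- (c_ - center[2]) / semi_axes[2]
  q <- sqrt(pmax(u^2 + v^2, 1e-12))
  grad <- sqrt((u / semi_axes[1])^2 + (v / semi_axes[2])^2) / q
  (q - 1) / pmax(grad, 1e-12)
}

# arc of organ A's boundary facing organ B: boundary points whose small
# outward offset lands inside organ B's ellipse, ordered along the arc;
# the standard line is drawn on the interface itself
interface_arc <- function(shape, a, b, probe = 2.5) {
  t <- seq(-pi, pi, length.out = 2048L)[-1L]
  pr <- a$center[1] + a$semi_axes[1] * sin(t)
  pc <- a$center[2] + a$semi_axes[2] * cos(t)
  # outward normal of an axis-aligned ellipse
  nr_ <- sin(t) / a$semi_axes[1]
  nc_ <- cos(t) / a$semi_axes[2]
  nn <- sqrt(nr_^2 + nc_^2)
  or_ <- pr + probe * nr_ / nn
  oc <- pc + probe * nc_ / nn
  inside_b <- ((or_ - b$center[1]) / b$semi_axes[1])^2 +
    ((oc - b$center[2]) / b$semi_axes[2])^2 <= 1
  in_img <- pr >= 1 & pr <= shape[1] & pc >= 1 & pc <= shape[2]
  keep <- inside_b & in_img
  list(points = cbind(pr[keep], pc[keep]), t = t[keep])
}

# per-pixel elliptical angle matching the interface parametrization
# (row, col) = center + (a_r sin t, a_c cos t)
pixel_ellipse_angle <- function(shape, center, semi_axes) {
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  c_ <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  atan2((r - center[1]) / semi_axes[1], (c_ - center[2]) / semi_axes[2])
}

# pick vertices along a dense polyline at roughly the requested arc spacing
resample_polyline <- function(points, spacing = 5) {
  if (nrow(points) < 2L) return(points)
  seg <- sqrt(diff(points[, 1])^2 + diff(points[, 2])^2)
  arc <- c(0, cumsum(seg))
  targets <- seq(0, arc[length(arc)], by = spacing)
  idx <- unique(vapply(targets, function(s) which.min(abs(arc - s)), 1L))
  if (idx[length(idx)] != nrow(points)) idx <- c(idx, nrow(points))
  points[idx, , drop = FALSE]
}

phantom_seeds <- function(mask_a, a) {
  cand <- rbind(
    c(a$center[1], a$center[2]),
    c(a$center[1] - 0.45 * a$semi_axes[1], a$center[2]),
    c(a$center[1] + 0.45 * a$semi_axes[1], a$center[2]),
    c(a$center[1], a$center[2] - 0.45 * a$semi_axes[2]),
    c(a$center[1], a$center[2] + 0.45 * a$semi_axes[2]))
  cand <- round(cand)
  inside <- mask_a[cand]
  seeds <- cand[inside, , drop = FALSE]
  if (nrow(seeds) < 3L) stop("could not place 3 seeds inside organ A")
  storage.mode(seeds) <- "integer"
  seeds
}

# evaluate expr under a fixed seed without disturbing the caller's RNG
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
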