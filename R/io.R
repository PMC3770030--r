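#' Read a 2-D grayscale image
#'
#' Dispatches on file extension: PNG (8/16-bit gray; RGB is converted by
#' channel averaging), NIfTI (a named slice index along the third dimension
#' of a volume), or a plain-text CSV matrix. All images are returned as
#' numeric matrices in floating point, rows indexing the image rows.
#'
#' @param path input file (`.png`, `.nii`/`.nii.gz`, `.csv`).
#' @param slice 1-based slice index for NIfTI volumes. Default 1.
#' @return numeric matrix of intensities.
#' @export
read_image <- function(path, slice = 1L) {
  if (!file.exists(path)) stop("input image not found: ", path)
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (tolower(tools::file_ext(path)) == "gz") ext <- "nii"
  img <- switch(ext,
    png = {
      a <- png::readPNG(path)
      if (length(dim(a)) == 3L) a <- apply(a[, , 1:min(3, dim(a)[3])], c(1, 2), mean)
      a * 255
    },
    nii = {
      v <- RNifti::readNifti(path)
      v <- as.array(v)
      if (length(dim(v)) == 2L) v
      else {
        if (slice < 1L || slice > dim(v)[3]) stop("slice index out of range")
        v[, , slice]
      }
    },
    csv = as.matrix(utils::read.csv(path, header = FALSE)),
    stop("unsupported image format: .", ext,
         " (supported: png, nii/nii.gz, csv)")
  )
  img <- matrix(as.numeric(img), nrow(img), ncol(img))
  as_image_matrix(img)
}

#' Write a numeric image as an 8-bit grayscale PNG
#'
#' Intensities are clamped to `[0, 255]` and scaled to `[0, 1]` for the PNG
#' encoder (images already in `[0, 1]` are written as-is).
#'
#' @param image numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  m <- image
  if (max(m) > 1) m <- m / 255
  png::writePNG(pmin(pmax(m, 0), 1), path)
  invisible(path)
}

#' Write a binary mask as an 8-bit PNG (0/255)
#'
#' @param mask logical (or 0/1) matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  mask <- as_mask(mask)
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read a binary mask from a PNG
#'
#' Any pixel above half intensity is foreground.
#'
#' @param path PNG path.
#' @return logical matrix.
#' @export
read_mask_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  a > 0.5
}

#' Read seeds and an optional standard line from JSON
#'
#' The interchange document is
#' `{"seeds": [[r, c], ...], "standard_line": [[r, c], ...]}` with 0-based
#' row/col pixel coordinates; `standard_line` may be absent, which switches
#' the pipeline to the automatic (line-free) energy variants. Coordinates are
#' converted to the package's 1-based convention on read.
#'
#' @param path JSON path.
#' @return list with `seeds` (integer matrix) and `line` (numeric matrix or
#'   `NULL`), 1-based.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  doc <- jsonlite::fromJSON(path)
  if (is.null(doc$seeds)) stop("annotation must contain a 'seeds' array")
  seeds <- matrix(as.integer(round(doc$seeds)), ncol = 2L) + 1L
  line <- NULL
  if (!is.null(doc$standard_line)) {
    line <- matrix(as.numeric(doc$standard_line), ncol = 2L) + 1
  }
  list(seeds = seeds, line = line)
}

#' Write seeds and an optional standard line to JSON (0-based)
#'
#' @param seeds integer matrix of 1-based `(row, col)` seeds.
#' @param line numeric matrix of 1-based standard-line vertices, or `NULL`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(seeds, line, path) {
  doc <- list(seeds = unname(as.matrix(seeds)) - 1L)
  if (!is.null(line)) doc$standard_line <- unname(as.matrix(line)) - 1
  jsonlite::write_json(doc, path, digits = NA)
  invisible(path)
}
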