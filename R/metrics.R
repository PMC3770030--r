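#' Segmentation evaluation metrics: FPE, FNE and SI
#'
#' Compares an extracted region `O` against a gold-standard region `G`:
#' \describe{
#'   \item{FPE}{false-positive error, `N(O \ G) / N(G)` — extracted pixels
#'     outside the gold standard, normalized by the gold-standard size. Can
#'     exceed 1 under severe oversegmentation and is deliberately not
#'     clamped.}
#'   \item{FNE}{false-negative error, `(N(G) - N(O & G)) / N(G)` — the missed
#'     fraction of the gold standard, in `[0, 1]`.}
#'   \item{SI}{similarity index, `2 N(O & G) / (N(O) + N(G))` — the Dice
#'     coefficient, in `[0, 1]`.}
#' }
#'
#' @param o logical (or 0/1) matrix, the extracted region.
#' @param g logical (or 0/1) matrix, the nonempty gold standard; same shape.
#' @return a one-row `data.frame` with columns `n_o`, `n_g`, `n_og`, `n_ob`,
#'   `fpe`, `fne`, `si` and the percentage forms `fpe_pct`, `fne_pct`,
#'   `si_pct`.
#' @examples
#' o <- matrix(FALSE, 10, 10); o[1:2, 1:3] <- TRUE
#' g <- matrix(FALSE, 10, 10); g[1:2, 2:5] <- TRUE
#' compute_metrics(o, g)
#' @export
compute_metrics <- function(o, g) {
  o <- as_mask(o); g <- as_mask(g)
  if (!identical(dim(o), dim(g))) stop("'o' and 'g' shapes differ")
  n_g <- sum(g)
  if (n_g == 0L) stop("gold standard is empty: FPE/FNE undefined")
  n_o <- sum(o)
  n_og <- sum(o & g)
  n_ob <- n_o - n_og # extracted pixels in the complement of G
  fpe <- n_ob / n_g
  fne <- (n_g - n_og) / n_g
  si <- if (n_o + n_g > 0) 2 * n_og / (n_o + n_g) else 0
  data.frame(n_o = n_o, n_g = n_g, n_og = n_og, n_ob = n_ob,
             fpe = fpe, fne = fne, si = si,
             fpe_pct = 100 * fpe, fne_pct = 100 * fne, si_pct = 100 * si)
}

#' Write a metrics report to JSON and append to a CSV log
#'
#' @param metrics a one-row data frame from [compute_metrics()].
#' @param json_path optional path for a JSON report.
#' @param csv_path optional path of an appendable CSV log (one row per slice;
#'   a header is written if the file does not exist yet).
#' @param id slice identifier recorded in the CSV row. Default `"slice"`.
#' @return `metrics`, invisibly.
#' @export
write_metrics <- function(metrics, json_path = NULL, csv_path = NULL,
                          id = "slice") {
  if (!is.null(json_path)) {
    jsonlite::write_json(as.list(metrics), json_path,
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) {
    row <- cbind(data.frame(id = id),
                 metrics[, c("n_o", "n_g", "n_og", "fpe", "fne", "si")])
    utils::write.table(row, csv_path, sep = ",", row.names = FALSE,
                       col.names = !file.exists(csv_path), append = file.exists(csv_path))
  }
  invisible(metrics)
}
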