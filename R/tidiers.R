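#' Tidy a place-cell scan
#'
#' Per-cell metric table without the nested field tibbles.
#'
#' @param x A [classify_place_cells()] result.
#' @param ... Unused.
#' @return A tibble, one row per cell.
#' @export
tidy.place_cell_scan <- function(x, ...) {
  out <- as_tibble(x)
  out$fields <- NULL
  class(out) <- class(tibble())
  out
}

#' Summarize a place-cell scan
#'
#' @param x A [classify_place_cells()] result.
#' @param ... Unused.
#' @return One-row tibble: `n_cells`, `n_place_cells`,
#'   `proportion_place_cells`, `mean_sensitivity`, `mean_specificity`,
#'   `mean_spatial_info` (place cells only).
#' @export
glance.place_cell_scan <- function(x, ...) {
  pc <- x$is_place_cell
  tibble(
    n_cells = nrow(x),
    n_place_cells = sum(pc),
    proportion_place_cells = mean(pc),
    mean_sensitivity = mean(x$sensitivity[pc]),
    mean_specificity = mean(x$specificity[pc]),
    mean_spatial_info = mean(x$spatial_info[pc])
  )
}

#' Tidy a cross-validated decoding result
#'
#' @param x A [crossval_decode()] result.
#' @param ... Unused.
#' @return Per-repeat tibble of mean absolute errors.
#' @export
tidy.decoder_cv <- function(x, ...) x$by_repeat

#' Summarize a cross-validated decoding result
#'
#' @param x A [crossval_decode()] result.
#' @param ... Unused.
#' @return One-row tibble: mean and SD error, chance level, cells, laps.
#' @export
glance.decoder_cv <- function(x, ...) {
  tibble(
    mean_error_cm = x$mean_error_cm,
    sd_error_cm = x$sd_error_cm,
    chance_cm = x$chance_cm,
    n_cells = x$n_cells,
    n_laps = x$n_laps
  )
}

#' @export
print.decoder_cv <- function(x, ...) {
  cat(sprintf(
    "<decoder_cv> %d cells, %d laps (leave-one-out): %.2f +/- %.2f cm (chance %.1f cm)\n",
    x$n_cells, x$n_laps, x$mean_error_cm, x$sd_error_cm, x$chance_cm))
  invisible(x)
}
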