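# Regression metrics (MAE, RMSE) and the BDI-II score -> severity band
# mapping. Bands: 0-13 "None or minimal", 14-19 "Mild", 20-28 "Moderate",
# 29-63 "Severe" (inclusive integer ranges partitioning 0..63).

severity_labels <- c("None or minimal", "Mild", "Moderate", "Severe")

#' BDI-II severity bands
#'
#' The four severity bands with their inclusive integer score ranges. The
#' ranges partition 0..63: every integer score belongs to exactly one band.
#'
#' @return A tibble with columns `band` (factor, ordered by severity),
#'   `lower`, `upper`.
#' @examples
#' severity_bands()
#' @export
severity_bands <- function() {
  tibble(band = factor(severity_labels, levels = severity_labels),
         lower = c(0L, 14L, 20L, 29L),
         upper = c(13L, 19L, 28L, 63L))
}

# round half away from zero (scores are non-negative here, so half-up)
round_half_up <- function(x) floor(x + 0.5)

#' Map BDI-II scores to severity bands
#'
#' Clamps each score to \[0, 63\], rounds half-up to an integer, and
#' returns its severity band.
#'
#' @param score Numeric vector of (possibly non-integer) BDI-II scores.
#' @return Factor of band labels with levels ordered by severity.
#' @examples
#' severity_from_score(c(3, 16, 44))
#' @export
severity_from_score <- function(score) {
  if (!is.numeric(score)) abort("score must be numeric")
  if (any(!is.finite(score))) abort("score must be finite")
  s <- round_half_up(pmin(pmax(score, 0), 63))
  bands <- severity_bands()
  idx <- findInterval(s, bands$lower)
  factor(severity_labels[idx], levels = severity_labels)
}

check_metric_inputs <- function(truth, estimate) {
  if (length(truth) != length(estimate))
    abort(sprintf("truth and estimate lengths differ (%d vs %d)",
                  length(truth), length(estimate)))
  if (length(truth) < 1) abort("at least one sample is required")
  invisible(NULL)
}

#' Mean absolute error
#'
#' @param truth,estimate Numeric vectors of equal length.
#' @return `mean(abs(estimate - truth))`.
#' @examples
#' bdi_mae(c(10, 20, 30), c(12, 18, 33))  # 7/3
#' @export
bdi_mae <- function(truth, estimate) {
  check_metric_inputs(truth, estimate)
  mean(abs(estimate - truth))
}

#' Root mean square error
#'
#' @param truth,estimate Numeric vectors of equal length.
#' @return `sqrt(mean((estimate - truth)^2))`.
#' @examples
#' bdi_rmse(c(10, 20, 30), c(12, 18, 33))  # sqrt(17/3)
#' @export
bdi_rmse <- function(truth, estimate) {
  check_metric_inputs(truth, estimate)
  sqrt(mean((estimate - truth)^2))
}

#' Evaluate predictions against true scores
#'
#' Computes MAE and RMSE and a per-band confusion summary (true band vs
#' predicted band after clamping and rounding).
#'
#' @param truth,estimate Numeric vectors of equal length.
#' @return A list with `metrics` (one-row tibble: `n`, `mae`, `rmse`) and
#'   `confusion` (tibble: `truth_band`, `estimate_band`, `n`).
#' @examples
#' evaluate_scores(c(3, 16, 44), c(5, 21, 40))
#' @export
evaluate_scores <- function(truth, estimate) {
  check_metric_inputs(truth, estimate)
  confusion <- tibble(truth_band = severity_from_score(truth),
                      estimate_band = severity_from_score(estimate)) |>
    dplyr::count(.data$truth_band, .data$estimate_band, name = "n")
  list(metrics = tibble(n = length(truth),
                        mae = bdi_mae(truth, estimate),
                        rmse = bdi_rmse(truth, estimate)),
       confusion = confusion)
}
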