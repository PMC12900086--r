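#' Agreement statistics between estimated and observed tiller numbers
#'
#' Computes the accuracy metrics used to validate image-based tiller
#' estimates against manual counts:
#' \itemize{
#'   \item RMSE: \eqn{\sqrt{\mathrm{mean}((e-o)^2)}}
#'   \item MAE: \eqn{\mathrm{mean}(|e-o|)}
#'   \item mean bias: \eqn{\mathrm{mean}(e-o)} — negative values mean the
#'     image-based method systematically underestimates
#'   \item R^2: coefficient of determination of the OLS regression of
#'     estimated on observed (with intercept; equals squared Pearson r)
#'   \item Lin's concordance correlation coefficient:
#'     \deqn{\rho_c = \frac{2 s_{eo}}{s_e^2 + s_o^2 + (\bar e - \bar o)^2}}
#'     with population (1/n) moment denominators, penalizing both poor
#'     correlation and location/scale shifts.
#' }
#' The identity \eqn{\mathrm{RMSE}^2 = \mathrm{bias}^2 + s^2_{e-o}} (with
#' the population variance of the error series) holds exactly.
#'
#' @param estimated,observed Equal-length numeric vectors (tillers m^-2),
#'   all finite, length >= 2. `observed` must not be constant (R^2 and CCC
#'   are undefined for zero variance).
#' @return A list of class `accuracy_report` with `rmse`, `mae`, `bias`,
#'   `r_squared`, `ccc` and `n`.
#' @examples
#' obs <- c(300, 350, 400)
#' accuracy_report(obs + 10, obs)  # bias 10, rmse 10, r^2 1, ccc ~ 0.971
#' @export
accuracy_report <- function(estimated, observed) {
  e <- as.numeric(estimated)
  o <- as.numeric(observed)
  if (length(e) != length(o)) {
    stop("estimated and observed must have equal length", call. = FALSE)
  }
  n <- length(e)
  if (n < 2L) stop("need at least 2 paired observations", call. = FALSE)
  if (anyNA(e) || anyNA(o) || any(!is.finite(e)) || any(!is.finite(o))) {
    stop("paired observations must all be finite", call. = FALSE)
  }
  err <- e - o
  rmse <- sqrt(mean(err^2))
  mae <- mean(abs(err))
  bias <- mean(err)
  # population (1/n) moments, per Lin's original estimator
  me <- mean(e); mo <- mean(o)
  s_e2 <- mean((e - me)^2)
  s_o2 <- mean((o - mo)^2)
  s_eo <- mean((e - me) * (o - mo))
  if (s_o2 == 0) {
    stop("observed values are constant: R^2 and CCC are undefined",
         call. = FALSE)
  }
  ccc <- 2 * s_eo / (s_e2 + s_o2 + (me - mo)^2)
  r_squared <- if (s_e2 == 0) 0 else s_eo^2 / (s_e2 * s_o2)
  structure(
    list(rmse = rmse, mae = mae, bias = bias,
         r_squared = r_squared, ccc = ccc, n = n),
    class = "accuracy_report"
  )
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf(paste0(
    "Agreement over n = %d pairs (tillers m-2):\n",
    "  RMSE %.1f | MAE %.1f | bias %+.1f | R^2 %.4f | CCC %.3f\n"),
    x$n, x$rmse, x$mae, x$bias, x$r_squared, x$ccc))
  invisible(x)
}

#' Convert an error magnitude to days of growth progression
#'
#' Divides a tiller-count error by a daily tiller increase rate, expressing
#' estimation error as the number of days of growth it corresponds to.
#' Around the optimal timing of mid-season drainage, reported increase
#' rates are roughly 12.0-24.3 tillers m^-2 day^-1, so e.g. a 34.6
#' tillers m^-2 bias corresponds to about 1.4-2.9 days.
#'
#' @param error_magnitude Non-negative error in tillers m^-2.
#' @param daily_rate Positive tiller increase rate in tillers m^-2 day^-1.
#' @return Days of growth progression, `error_magnitude / daily_rate`.
#' @export
error_in_days <- function(error_magnitude, daily_rate) {
  if (!is.numeric(error_magnitude) || anyNA(error_magnitude) ||
      any(error_magnitude < 0)) {
    stop("error_magnitude must be non-negative", call. = FALSE)
  }
  if (!is.numeric(daily_rate) || anyNA(daily_rate) || any(daily_rate <= 0)) {
    stop("daily_rate must be positive", call. = FALSE)
  }
  error_magnitude / daily_rate
}

#' Read paired estimated/observed values from CSV
#'
#' Expects columns `estimated` and `observed`. If `group` and/or
#' `replicate` columns are present, replicates are averaged within each
#' group before comparison (the convention when each survey point is the
#' mean of several replicate images and counts); without a `group` column
#' rows are taken as-is.
#'
#' @param path CSV file path.
#' @return Data frame with columns `estimated` and `observed` (plus
#'   `group` when grouping was applied).
#' @export
read_paired_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("estimated", "observed")
  if (!all(need %in% names(df))) {
    stop("paired CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if ("group" %in% names(df)) {
    est <- tapply(df$estimated, df$group, mean)
    obs <- tapply(df$observed, df$group, mean)
    data.frame(group = names(est),
               estimated = as.numeric(est),
               observed = as.numeric(obs),
               stringsAsFactors = FALSE)
  } else {
    df[need]
  }
}

#' Serialize an accuracy report to JSON
#'
#' @param report An [accuracy_report()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "accuracy_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
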