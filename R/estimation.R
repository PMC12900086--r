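#' Quadratic cover-to-tiller model
#'
#' Container for the regression mapping canopy cover (percent) to tiller
#' density (tillers per square metre):
#' \deqn{T = a C^2 + b C + c}
#' with C in percent (0-100). The optional `calibration_domain` records the
#' cover range of the data the model was fitted on; estimates outside it
#' are flagged as extrapolated.
#'
#' @param a,b,c Finite coefficients: `a` in tillers m^-2 per (%)^2, `b` in
#'   tillers m^-2 per %, `c` in tillers m^-2 (the zero-cover intercept).
#' @param calibration_domain Optional length-2 numeric, the closed cover
#'   interval (percent) spanned by the calibration data, or `NULL`.
#' @param note Optional free-text provenance metadata.
#' @return An object of class `quadratic_model`.
#' @export
quadratic_model <- function(a, b, c, calibration_domain = NULL, note = NULL) {
  for (co in list(a, b, c)) {
    if (!is.numeric(co) || length(co) != 1L || !is.finite(co)) {
      stop("model coefficients must be single finite numbers", call. = FALSE)
    }
  }
  if (!is.null(calibration_domain)) {
    cd <- as.numeric(calibration_domain)
    if (length(cd) != 2L || anyNA(cd) || cd[1] > cd[2] ||
        cd[1] < 0 || cd[2] > 100) {
      stop("calibration_domain must be an ordered interval within [0, 100]",
           call. = FALSE)
    }
    calibration_domain <- cd
  }
  structure(
    list(a = a, b = b, c = c,
         calibration_domain = calibration_domain, note = note),
    class = "quadratic_model"
  )
}

#' The built-in cover-to-tiller model
#'
#' Returns the operational quadratic
#' \deqn{T = -0.0548\,C^2 + 9.13\,C + 77.7}
#' (T in tillers m^-2, C canopy cover in percent), derived from field
#' calibration of 'Koshihikari' stands at planting densities of
#' 11.0-18.3 hills m^-2 and applied unchanged to all cultivars. The cover
#' range of the original calibration data is not published, so
#' `calibration_domain` is unset; extrapolation is instead flagged past the
#' parabola's vertex (about 83.3% cover), beyond which the model is
#' non-monotone.
#'
#' @return A [quadratic_model()] with coefficients (-0.0548, 9.13, 77.7).
#' @examples
#' m <- default_model()
#' estimate_tillers(m, 50)  # 397.2 tillers m^-2
#' @export
default_model <- function() {
  quadratic_model(
    a = -0.0548, b = 9.13, c = 77.7,
    note = "calibrated on 'Koshihikari' at planting densities 11.0-18.3 hills m-2"
  )
}

#' @export
print.quadratic_model <- function(x, ...) {
  cat(sprintf("Tillers m-2 = %g * C^2 + %g * C + %g  (C = canopy cover %%)\n",
              x$a, x$b, x$c))
  if (!is.null(x$calibration_domain)) {
    cat(sprintf("  calibrated on cover %.1f-%.1f%%\n",
                x$calibration_domain[1], x$calibration_domain[2]))
  }
  if (!is.null(x$note)) cat("  ", x$note, "\n", sep = "")
  invisible(x)
}

#' Cover at the model's vertex
#'
#' For a downward-opening quadratic the vertex `-b / 2a` is the cover at
#' which the predicted tiller number peaks; past it the model predicts
#' fewer tillers for denser canopies and should not be trusted.
#'
#' @param model A [quadratic_model()].
#' @return The vertex cover in percent.
#' @export
vertex_cover <- function(model) {
  stopifnot(inherits(model, "quadratic_model"))
  if (model$a == 0) {
    stop("model is degenerate (a = 0): no vertex", call. = FALSE)
  }
  -model$b / (2 * model$a)
}

#' Estimate tiller density from canopy cover
#'
#' Evaluates the quadratic model at the given cover. Estimates are never
#' clamped; instead the `extrapolated` flag is set when the cover lies
#' beyond the model's vertex (for a < 0) or outside its recorded
#' calibration domain, so the caller can see when the model is being used
#' outside the region where it is monotone and supported by data.
#'
#' @param model A [quadratic_model()].
#' @param cover_percent Canopy cover in percent, in \[0, 100\].
#' @return A list of class `tiller_estimate` with `cover_percent`,
#'   `tillers_per_m2` and `extrapolated`.
#' @export
estimate_tillers <- function(model, cover_percent) {
  stopifnot(inherits(model, "quadratic_model"))
  if (!is.numeric(cover_percent) || length(cover_percent) != 1L ||
      !is.finite(cover_percent)) {
    stop("cover_percent must be a single finite number", call. = FALSE)
  }
  if (cover_percent < 0 || cover_percent > 100) {
    stop("cover_percent must lie in [0, 100]", call. = FALSE)
  }
  t <- model$a * cover_percent^2 + model$b * cover_percent + model$c
  extra <- FALSE
  if (model$a < 0 && cover_percent > vertex_cover(model)) extra <- TRUE
  if (!is.null(model$calibration_domain) &&
      (cover_percent < model$calibration_domain[1] ||
       cover_percent > model$calibration_domain[2])) {
    extra <- TRUE
  }
  structure(
    list(cover_percent = cover_percent, tillers_per_m2 = t,
         extrapolated = extra),
    class = "tiller_estimate"
  )
}

#' @export
print.tiller_estimate <- function(x, ...) {
  cat(sprintf("%.1f tillers m-2 at %.1f%% cover%s\n",
              x$tillers_per_m2, x$cover_percent,
              if (x$extrapolated) " (extrapolated)" else ""))
  invisible(x)
}

#' Fit a quadratic cover-to-tiller model by least squares
#'
#' Ordinary least squares fit of tillers on cover and cover squared.
#' Requires at least three distinct cover values; the fitted model records
#' the cover range of the input as its calibration domain.
#'
#' @param cover_percent Canopy cover values in percent.
#' @param tillers_per_m2 Matching tiller densities.
#' @return A [quadratic_model()] with `calibration_domain` set to the
#'   input's cover range.
#' @export
fit_model <- function(cover_percent, tillers_per_m2) {
  cov <- as.numeric(cover_percent)
  til <- as.numeric(tillers_per_m2)
  if (length(cov) != length(til)) {
    stop("cover and tiller vectors must have equal length", call. = FALSE)
  }
  if (anyNA(cov) || anyNA(til) || any(!is.finite(cov)) || any(!is.finite(til))) {
    stop("calibration data contain missing or non-finite values", call. = FALSE)
  }
  if (length(unique(cov)) < 3L) {
    stop("underdetermined fit: need at least 3 distinct cover values",
         call. = FALSE)
  }
  fit <- stats::lm(til ~ cov + I(cov^2))
  cf <- stats::coef(fit)
  quadratic_model(
    a = unname(cf[["I(cov^2)"]]),
    b = unname(cf[["cov"]]),
    c = unname(cf[["(Intercept)"]]),
    calibration_domain = c(max(0, min(cov)), min(100, max(cov)))
  )
}

#' Read calibration pairs from CSV
#'
#' Expects a header with columns `cover_percent` and `tillers_per_m2`.
#'
#' @param path CSV file path.
#' @return Data frame with columns `cover_percent`, `tillers_per_m2`.
#' @export
read_calibration_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cover_percent", "tillers_per_m2")
  if (!all(need %in% names(df))) {
    stop("calibration CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df <- df[need]
  df[] <- lapply(df, as.numeric)
  df
}

#' Serialize a quadratic model to JSON
#'
#' @param model A [quadratic_model()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "quadratic_model"))
  obj <- list(a = model$a, b = model$b, c = model$c)
  if (!is.null(model$calibration_domain)) {
    obj$calibration_domain <- model$calibration_domain
  }
  if (!is.null(model$note)) obj$note <- model$note
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a quadratic model from JSON
#'
#' @param path JSON file with keys `a`, `b`, `c` and optional
#'   `calibration_domain`.
#' @return A [quadratic_model()].
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!all(c("a", "b", "c") %in% names(obj))) {
    stop("model JSON must contain keys a, b, c", call. = FALSE)
  }
  quadratic_model(obj$a, obj$b, obj$c,
                  calibration_domain = obj$calibration_domain,
                  note = obj$note)
}
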