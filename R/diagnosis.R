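#' Cultivar profile: a drainage-timing target
#'
#' @param name Cultivar name (non-empty string; matched case-sensitively).
#' @param target_tillers_per_m2 Positive tiller density at which mid-season
#'   drainage is considered optimally timed.
#' @return An object of class `cultivar_profile`.
#' @export
cultivar_profile <- function(name, target_tillers_per_m2) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("cultivar name must be a non-empty string", call. = FALSE)
  }
  t <- target_tillers_per_m2
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t <= 0) {
    stop("target tiller number must be a positive number", call. = FALSE)
  }
  structure(list(name = name, target_tillers_per_m2 = as.numeric(t)),
            class = "cultivar_profile")
}

#' Built-in cultivar target registry
#'
#' The three cultivars with published target tiller numbers for mid-season
#' drainage, from the Chiba Prefecture cultivation guidelines:
#' 'Fusaotome' 400, 'Fusakogane' 360 and 'Koshihikari' 320 tillers m^-2.
#' Targets are cultivar-level scalars; any soil-type dependence in the
#' underlying guidelines is not resolved here.
#'
#' @return Named list of [cultivar_profile()] objects.
#' @export
builtin_registry <- function() {
  profiles <- list(
    cultivar_profile("Fusaotome",   400),
    cultivar_profile("Fusakogane",  360),
    cultivar_profile("Koshihikari", 320)
  )
  stats::setNames(profiles, vapply(profiles, `[[`, "", "name"))
}

#' Look up a cultivar in a registry
#'
#' Case-sensitive exact match: cultivar names are treated as identifiers,
#' not free text.
#'
#' @param name Cultivar name.
#' @param registry Named list of profiles; defaults to [builtin_registry()].
#' @return The matching [cultivar_profile()].
#' @export
lookup_cultivar <- function(name, registry = builtin_registry()) {
  if (!is.character(name) || length(name) != 1L) {
    stop("cultivar name must be a single string", call. = FALSE)
  }
  p <- registry[[name]]
  if (is.null(p)) {
    stop("unknown cultivar '", name, "'; known: ",
         paste(names(registry), collapse = ", "), call. = FALSE)
  }
  p
}

#' Read a cultivar registry from JSON
#'
#' Accepts a JSON array of `{name, target_tillers_per_m2}` records. By
#' default the entries extend/override the built-in registry, so a config
#' file need only list additions or changed targets.
#'
#' @param path JSON file path.
#' @param extend_builtin Start from [builtin_registry()] (default) or from
#'   an empty registry.
#' @return Named list of [cultivar_profile()] objects.
#' @export
read_registry_json <- function(path, extend_builtin = TRUE) {
  entries <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!is.list(entries)) {
    stop("registry JSON must be an array of {name, target_tillers_per_m2}",
         call. = FALSE)
  }
  registry <- if (extend_builtin) builtin_registry() else list()
  for (e in entries) {
    if (is.null(e$name) || is.null(e$target_tillers_per_m2)) {
      stop("registry entries need keys 'name' and 'target_tillers_per_m2'",
           call. = FALSE)
    }
    registry[[e$name]] <- cultivar_profile(e$name, e$target_tillers_per_m2)
  }
  registry
}

#' Diagnose mid-season drainage timing from an estimated tiller number
#'
#' Compares the estimated tiller density against the cultivar's target.
#' The rule is inclusive: an estimate equal to or higher than the target
#' diagnoses the field as at the optimal timing for mid-season drainage;
#' otherwise the tiller number is still insufficient. The real-valued
#' estimate is compared unrounded; rounding is a display concern only.
#'
#' @param estimated_tillers Estimated tiller density, finite and >= 0.
#' @param profile A [cultivar_profile()].
#' @return A list of class `diagnosis_result` with `status` (one of
#'   `"OPTIMAL_DRAINAGE_TIMING"`, `"INSUFFICIENT_TILLER_NUMBER"`),
#'   `estimated_tillers`, `target_tillers`, `margin` (estimated - target)
#'   and `cultivar`.
#' @examples
#' diagnose(400, cultivar_profile("Fusaotome", 400))  # optimal (inclusive)
#' @export
diagnose <- function(estimated_tillers, profile) {
  stopifnot(inherits(profile, "cultivar_profile"))
  e <- estimated_tillers
  if (!is.numeric(e) || length(e) != 1L || !is.finite(e) || e < 0) {
    stop("estimated tiller number must be a single finite value >= 0",
         call. = FALSE)
  }
  margin <- e - profile$target_tillers_per_m2
  structure(
    list(
      status = if (margin >= 0) "OPTIMAL_DRAINAGE_TIMING"
               else "INSUFFICIENT_TILLER_NUMBER",
      estimated_tillers = e,
      target_tillers = profile$target_tillers_per_m2,
      margin = margin,
      cultivar = profile$name
    ),
    class = "diagnosis_result"
  )
}

#' @export
print.diagnosis_result <- function(x, ...) {
  cat(sprintf("%s: %s\n  estimated %.1f vs target %.0f tillers m-2 (margin %+.1f)\n",
              x$cultivar,
              if (x$status == "OPTIMAL_DRAINAGE_TIMING")
                "optimal timing for mid-season drainage"
              else "tiller number still insufficient",
              x$estimated_tillers, x$target_tillers, x$margin))
  invisible(x)
}

#' Full image-to-decision diagnostic pipeline
#'
#' Chains the four stages of the diagnostic workflow with no hidden state:
#' segment the canopy image, compute cover, convert cover to a tiller
#' estimate with the quadratic model, and compare against the cultivar's
#' target.
#'
#' @param image An [rgb_image()] object.
#' @param cultivar Cultivar name resolvable in `registry`.
#' @param model A [quadratic_model()]; default [default_model()].
#' @param registry Cultivar registry; default [builtin_registry()].
#' @param threshold Segmentation threshold; default 134.
#' @return A list of class `canopy_diagnosis` with elements `cover`
#'   (`cover_result`), `estimate` (`tiller_estimate`) and `diagnosis`
#'   (`diagnosis_result`).
#' @examples
#' img <- rgb_image(array(rep(c(120L, 120L, 120L), each = 4), c(2, 2, 3)))
#' diagnose_image(img, "Koshihikari")  # 0% cover -> 77.7 -> insufficient
#' @export
diagnose_image <- function(image, cultivar, model = default_model(),
                           registry = builtin_registry(), threshold = 134) {
  profile <- lookup_cultivar(cultivar, registry)
  mask <- segment_canopy(image, threshold = threshold)
  cov <- cover_ratio(mask)
  est <- estimate_tillers(model, cov$cover_percent)
  dx <- diagnose(est$tillers_per_m2, profile)
  structure(list(cover = cov, estimate = est, diagnosis = dx),
            class = "canopy_diagnosis")
}

#' @export
print.canopy_diagnosis <- function(x, ...) {
  print(x$cover)
  print(x$estimate)
  print(x$diagnosis)
  invisible(x)
}

#' Flatten a diagnosis record for JSON export
#'
#' @param x A `canopy_diagnosis` from [diagnose_image()].
#' @return A plain named list mirroring the full record.
#' @export
diagnosis_record <- function(x) {
  stopifnot(inherits(x, "canopy_diagnosis"))
  list(
    cover_percent = x$cover$cover_percent,
    vegetation_pixels = x$cover$vegetation_pixels,
    total_pixels = x$cover$total_pixels,
    estimated_tillers_per_m2 = x$estimate$tillers_per_m2,
    extrapolated = x$estimate$extrapolated,
    cultivar = x$diagnosis$cultivar,
    target_tillers_per_m2 = x$diagnosis$target_tillers,
    margin = x$diagnosis$margin,
    status = x$diagnosis$status
  )
}
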