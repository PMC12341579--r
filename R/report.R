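#' Aggregate stage outputs into a run report
#'
#' Collects the outputs of the pipeline stages into a single serializable
#' report with provenance (package version, seed, configuration hash).
#' Stages not supplied are marked absent. Calibration attributes carried by
#' the inputs are cross-checked; conflicting pixel sizes or frame intervals
#' raise an error.
#'
#' @param diameters a [diameter_series()] tibble.
#' @param velocity a [closure_velocity()] tibble.
#' @param cluster_summary a [summarize_ring()] tibble.
#' @param ablation a tibble/data frame of recoil fits (e.g. bound
#'   [glance()] rows) or a [tension_ratio()] tibble.
#' @param fret_timing a [peak_lag()] tibble.
#' @param cohort a cohort tibble with `radial_fraction` and
#'   `closure_velocity_um_min` (its Pearson correlation is added).
#' @param seed the seed used for the run, recorded as provenance.
#' @return A list of class `ring_report`; serialize with [write_report()].
#' @export
build_report <- function(diameters = NULL, velocity = NULL,
                         cluster_summary = NULL, ablation = NULL,
                         fret_timing = NULL, cohort = NULL, seed = NULL) {
  stages <- list(diameters = diameters, velocity = velocity,
                 cluster_summary = cluster_summary, ablation = ablation,
                 fret_timing = fret_timing, cohort = cohort)
  if (all(vapply(stages, is.null, logical(1)))) {
    abort("at least one stage output is required.")
  }
  calib <- purrr::compact(purrr::map(stages, function(s) {
    ps <- attr(s, "pixel_size_um")
    fi <- attr(s, "frame_interval_s")
    if (is.null(ps) && is.null(fi)) NULL else list(ps = ps, fi = fi)
  }))
  if (length(calib) > 1L) {
    pss <- unique(unlist(purrr::map(calib, "ps")))
    fis <- unique(unlist(purrr::map(calib, "fi")))
    if (length(pss) > 1L || length(fis) > 1L) {
      abort("conflicting calibrations across stage inputs.")
    }
  }
  blocks <- purrr::map(stages, function(s) {
    if (is.null(s)) list(absent = TRUE)
    else as.data.frame(s)
  })
  if (!is.null(cohort)) {
    blocks$cohort_correlation <- list(
      pearson_r = pearson_r(cohort$radial_fraction,
                            cohort$closure_velocity_um_min),
      n = nrow(cohort))
  }
  structure(list(
    meta = list(
      package = "woundring",
      version = as.character(utils::packageVersion("woundring")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = seed,
      config_hash = rlang::hash(stages),
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ),
    blocks = blocks
  ), class = "ring_report")
}

#' Write a run report to JSON (and optionally a text summary)
#'
#' @param report a [build_report()] object.
#' @param path output path for the JSON document.
#' @param text_path optional path for a short human-readable summary.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, text_path = NULL) {
  if (!inherits(report, "ring_report")) abort("`report` required.")
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  if (!is.null(text_path)) {
    lines <- c(
      sprintf("woundring run report (%s)", report$meta$created),
      sprintf("  seed: %s  config: %s", report$meta$seed %||% "none",
              report$meta$config_hash),
      purrr::imap_chr(report$blocks, function(b, nm) {
        if (isTRUE(b$absent)) sprintf("  %s: absent", nm)
        else sprintf("  %s: present", nm)
      })
    )
    writeLines(lines, text_path)
  }
  invisible(path)
}

#' @export
print.ring_report <- function(x, ...) {
  cat("woundring run report\n")
  cat("  created:", x$meta$created, "\n")
  for (nm in names(x$blocks)) {
    b <- x$blocks[[nm]]
    cat(sprintf("  %-18s %s\n", nm,
                if (isTRUE(b$absent)) "absent" else "present"))
  }
  invisible(x)
}
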