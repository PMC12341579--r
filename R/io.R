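#' Write a synthetic movie as multi-page TIFF plus sidecar JSON
#'
#' One 32-bit float TIFF per channel (intensities rescaled to [0, 1] by the
#' global maximum, which is recorded) and a JSON sidecar carrying the
#' calibration, seed, intensity scale and ground truth.
#'
#' @param movie a `ring_movie` from [simulate_ring_movie()].
#' @param dir output directory (created if needed).
#' @param name file stem; writes `<name>.tif` and `<name>.json`.
#' @return Named character vector with the written paths, invisibly.
#' @export
write_movie <- function(movie, dir, name = "ring") {
  if (!inherits(movie, "ring_movie")) abort("`movie` must be a ring_movie.")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tif <- file.path(dir, paste0(name, ".tif"))
  json <- file.path(dir, paste0(name, ".json"))
  scale <- max(movie$frames)
  pages <- purrr::map(seq_len(dim(movie$frames)[3]),
                      function(t) movie$frames[, , t] / scale)
  tiff::writeTIFF(pages, tif, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(
    pixel_size_um = movie$config$pixel_size_um,
    frame_interval_s = movie$config$frame_interval_s,
    seed = movie$config$seed,
    intensity_scale = scale,
    truth = list(
      geometry = as.data.frame(movie$truth$geometry),
      clusters = as.data.frame(movie$truth$clusters),
      closure_time_min = movie$truth$closure_time_min
    )
  )
  jsonlite::write_json(meta, json, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(tif = tif, json = json))
}

#' Read a movie written by [write_movie()]
#'
#' @param tif_path path to the multi-page TIFF.
#' @param json_path path to the sidecar JSON (defaults to the TIFF path
#'   with extension `.json`).
#' @return A list of class `ring_movie_file`: `frames` array, `meta` list
#'   (with `pixel_size_um`, `frame_interval_s`, `seed`, `truth`).
#' @export
read_movie <- function(tif_path, json_path = NULL) {
  json_path <- json_path %||% sub("\\.tiff?$", ".json", tif_path)
  pages <- tiff::readTIFF(tif_path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  scale <- meta$intensity_scale %||% 1
  frames <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (t in seq_along(pages)) {
    p <- pages[[t]]
    if (length(dim(p)) == 3L) p <- p[, , 1]
    frames[, , t] <- p * scale
  }
  structure(list(frames = frames, meta = meta), class = "ring_movie_file")
}
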