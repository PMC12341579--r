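#' Detect myosin clusters in kymograph columns
#'
#' Finds local maxima of each frame's circumferential profile after
#' circular Gaussian smoothing (sigma 0.5 um of arc by default). A maximum
#' is kept when its contrast -- peak intensity divided by the mean
#' intensity of the whole ring perimeter in that frame -- reaches
#' `min_contrast`. Peak positions are refined to sub-bin precision by
#' parabolic interpolation; wrap-around maxima are handled circularly.
#'
#' @param kymograph a [build_kymograph()] object.
#' @param frames frame indices to process (default: all tracked frames).
#' @param min_contrast detection threshold on the contrast ratio.
#' @param smooth_sigma_um sd of the circular Gaussian smoothing, in um of
#'   arc.
#' @return A tibble with `frame`, `time_min`, `bin` (fractional),
#'   `angle_rad`, `arc_um`, `intensity`, `contrast`; zero rows when no
#'   cluster is found.
#' @export
detect_clusters <- function(kymograph, frames = NULL, min_contrast = 1.3,
                            smooth_sigma_um = 0.5) {
  if (!inherits(kymograph, "kymograph")) abort("`kymograph` required.")
  geom <- kymograph$geometry
  dt_min <- kymograph$frame_interval_s / 60
  n <- kymograph$n_angle_bins
  all_frames <- which(colSums(is.na(kymograph$values)) < n)
  frames <- frames %||% all_frames
  frames <- intersect(frames, all_frames)

  out <- purrr::map_dfr(frames, function(t) {
    col <- kymograph$values[, t]
    if (!all(is.finite(col))) return(tibble())
    R <- geom$radius_um[match(t, geom$frame)]
    arc_per_bin <- 2 * pi * R / n
    s <- circular_gaussian_smooth(col, smooth_sigma_um / arc_per_bin)
    ring_mean <- mean(col)
    left <- c(s[n], s[-n])
    right <- c(s[-1], s[1])
    is_peak <- s > left & s >= right
    idx <- which(is_peak & s / ring_mean >= min_contrast)
    if (length(idx) == 0L) return(tibble())
    offs <- vapply(idx, function(i) {
      im1 <- if (i == 1L) n else i - 1L
      ip1 <- if (i == n) 1L else i + 1L
      parabolic_offset(s[im1], s[i], s[ip1])
    }, numeric(1))
    bin_f <- idx + offs
    theta <- wrap_angle((bin_f - 0.5) * 2 * pi / n)
    tibble(frame = t, time_min = (t - 1) * dt_min,
           bin = bin_f, angle_rad = theta, arc_um = R * theta,
           intensity = s[idx], contrast = s[idx] / ring_mean)
  })
  if (nrow(out) == 0L) {
    out <- tibble(frame = integer(), time_min = numeric(), bin = numeric(),
                  angle_rad = numeric(), arc_um = numeric(),
                  intensity = numeric(), contrast = numeric())
  }
  out
}

#' Link per-frame cluster detections into tracks
#'
#' Greedy nearest-neighbour assignment in circular arc distance: within
#' each frame, candidate (track, detection) pairs are assigned in order of
#' increasing arc distance, gated at `max_step_um` per elapsed frame; ties
#' resolve deterministically to the lower track id. Tracks missing for up
#' to `max_gap_frames` frames are bridged; unmatched detections start new
#' tracks. When two tracks converge on a single detection, a fusion event
#' is recorded on the dimmer track (by mean intensity), which is marked
#' `fused_into` the brighter one and terminated.
#'
#' @param detections tibble from [detect_clusters()].
#' @param geometry geometry tibble with `frame` and `radius_um` (a
#'   [diameter_series()] works).
#' @param max_step_um linking gate, um of arc per frame.
#' @param max_gap_frames longest bridgeable gap, in frames.
#' @return The detections tibble with a `track_id` column, class
#'   `cluster_tracks`; attribute `fusions` is a tibble
#'   (`frame`, `track_id`, `fused_into`).
#' @export
link_tracks <- function(detections, geometry, max_step_um = 1.0,
                        max_gap_frames = 2L) {
  det <- as_tibble(detections)
  if (nrow(det) == 0L) {
    out <- dplyr::mutate(det, track_id = integer())
    return(structure(out, class = c("cluster_tracks", class(out)),
                     fusions = tibble(frame = integer(), track_id = integer(),
                                      fused_into = integer())))
  }
  geom <- as_tibble(geometry)
  det <- dplyr::arrange(det, .data$frame, .data$bin)
  det$track_id <- NA_integer_
  det$.row <- seq_len(nrow(det))

  # active track state
  active <- list() # id -> list(last_frame, last_angle, sum_int, n_det)
  next_id <- 1L
  fusions <- list()
  mean_int <- function(tr) tr$sum_int / tr$n_det

  for (f in sort(unique(det$frame))) {
    R <- geom$radius_um[match(f, geom$frame)]
    rows <- which(det$frame == f)
    # retire stale tracks
    if (length(active)) {
      keep <- vapply(active, function(tr) f - tr$last_frame <= max_gap_frames + 1L,
                     logical(1))
      active <- active[keep]
    }
    assigned_det <- rep(NA_integer_, length(rows)) # track id per detection row
    if (length(active) && length(rows)) {
      ids <- as.integer(names(active))
      cand <- tidyr::expand_grid(ti = seq_along(ids), di = seq_along(rows))
      cand$gap <- vapply(cand$ti, function(i) f - active[[i]]$last_frame, numeric(1))
      cand$dist <- R * abs(angle_diff(det$angle_rad[rows[cand$di]],
                                      vapply(cand$ti, function(i) active[[i]]$last_angle,
                                             numeric(1))))
      cand <- cand[cand$dist <= max_step_um * cand$gap, , drop = FALSE]
      cand <- cand[order(cand$dist, ids[cand$ti]), , drop = FALSE]
      used_t <- logical(length(ids))
      used_d <- logical(length(rows))
      for (k in seq_len(nrow(cand))) {
        ti <- cand$ti[k]; di <- cand$di[k]
        if (used_t[ti] || used_d[di]) next
        used_t[ti] <- TRUE
        used_d[di] <- TRUE
        assigned_det[di] <- ids[ti]
      }
      # fusion: an unmatched track whose nearest in-gate detection was taken
      for (ti in which(!used_t)) {
        sub <- cand[cand$ti == ti, , drop = FALSE]
        if (nrow(sub) == 0L) next
        di <- sub$di[which.min(sub$dist)]
        winner <- assigned_det[di]
        if (is.na(winner)) next
        loser_id <- ids[ti]
        tr_l <- active[[as.character(loser_id)]]
        tr_w <- active[[as.character(winner)]]
        if (mean_int(tr_l) > mean_int(tr_w)) {
          # brighter loser takes over the detection; dimmer fuses into it
          assigned_det[di] <- loser_id
          fusions[[length(fusions) + 1L]] <-
            tibble(frame = f, track_id = winner, fused_into = loser_id)
          active[[as.character(winner)]] <- NULL
        } else {
          fusions[[length(fusions) + 1L]] <-
            tibble(frame = f, track_id = loser_id, fused_into = winner)
          active[[as.character(loser_id)]] <- NULL
        }
      }
    }
    # write assignments / new tracks
    for (di in seq_along(rows)) {
      r <- rows[di]
      id <- assigned_det[di]
      if (is.na(id)) {
        id <- next_id
        next_id <- next_id + 1L
        active[[as.character(id)]] <- list(last_frame = f,
                                           last_angle = det$angle_rad[r],
                                           sum_int = det$intensity[r], n_det = 1L)
      } else {
        tr <- active[[as.character(id)]]
        tr$last_frame <- f
        tr$last_angle <- det$angle_rad[r]
        tr$sum_int <- tr$sum_int + det$intensity[r]
        tr$n_det <- tr$n_det + 1L
        active[[as.character(id)]] <- tr
      }
      det$track_id[r] <- id
    }
  }
  det$.row <- NULL
  fus <- if (length(fusions)) dplyr::bind_rows(fusions) else
    tibble(frame = integer(), track_id = integer(), fused_into = integer())
  structure(det, class = c("cluster_tracks", class(det)), fusions = fus)
}

#' Mean nearest-neighbour arc spacing of detected clusters
#'
#' For each frame with at least two detections, computes every detection's
#' circular arc distance to its nearest neighbour on the ring and averages;
#' frames are then averaged with equal weight.
#'
#' @param detections tibble from [detect_clusters()] (a linked or
#'   classified track table also works).
#' @param geometry geometry tibble with `frame` and `radius_um`.
#' @return Mean spacing in um (`NA` when no frame has two detections).
#' @export
cluster_spacing <- function(detections, geometry) {
  det <- as_tibble(detections)
  geom <- as_tibble(geometry)
  if (nrow(det) == 0L) return(NA_real_)
  sp <- det |>
    dplyr::group_by(.data$frame) |>
    dplyr::filter(dplyr::n() >= 2L) |>
    dplyr::summarise(
      s = {
        R <- geom$radius_um[match(.data$frame[1], geom$frame)]
        th <- .data$angle_rad
        mean(vapply(seq_along(th), function(i) {
          min(R * abs(angle_diff(th[-i], th[i])))
        }, numeric(1)))
      }, .groups = "drop")
  if (nrow(sp) == 0L) NA_real_ else mean(sp$s)
}

#' Apply the lifetime filter and classify tracks as radial or tangential
#'
#' Drops tracks shorter than `min_lifetime_min` (6 min by default) or with
#' a single detection (speed undefined), then computes each track's mean
#' tangential arc speed -- the mean over consecutive detection pairs of
#' `|R * dtheta| / dt` with circular `dtheta` and `R` the mean ring radius
#' of the pair -- and classifies the track `radial` when the speed is below
#' `speed_threshold_um_per_min`, else `tangential`. Filtering is
#' idempotent.
#'
#' @param tracks a [link_tracks()] tibble.
#' @param geometry geometry tibble with `frame` and `radius_um`.
#' @param min_lifetime_min minimum track lifetime (min).
#' @param speed_threshold_um_per_min radial/tangential decision boundary
#'   (um/min); the default 0.1 sits between the two reported class speeds.
#' @return A tibble of class `classified_tracks`: the surviving detections
#'   with `lifetime_min`, `speed_um_min` and `class` columns; attribute
#'   `track_summary` is a per-track tibble, attribute `fusions` is carried
#'   over (events among surviving tracks).
#' @export
filter_and_classify <- function(tracks, geometry, min_lifetime_min = 6,
                                speed_threshold_um_per_min = 0.1) {
  det <- as_tibble(tracks)
  fus <- attr(tracks, "fusions") %||%
    tibble(frame = integer(), track_id = integer(), fused_into = integer())
  if (nrow(det) == 0L) {
    out <- dplyr::mutate(det, lifetime_min = numeric(), speed_um_min = numeric(),
                         class = character())
    empty_summ <- tibble(track_id = integer(), n_det = integer(),
                         lifetime_min = numeric(), mean_intensity = numeric(),
                         speed_um_min = numeric(), class = character())
    return(structure(out, class = c("classified_tracks", class(out)),
                     track_summary = empty_summ, fusions = fus))
  }
  geom <- as_tibble(geometry)
  radius_of <- function(f) geom$radius_um[match(f, geom$frame)]

  summ <- det |>
    dplyr::group_by(.data$track_id) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::summarise(
      n_det = dplyr::n(),
      lifetime_min = max(.data$time_min) - min(.data$time_min),
      mean_intensity = mean(.data$intensity),
      speed_um_min = {
        if (dplyr::n() < 2L) NA_real_ else {
          dth <- abs(angle_diff(.data$angle_rad[-1],
                                .data$angle_rad[-dplyr::n()]))
          dtm <- diff(.data$time_min)
          Rbar <- (radius_of(.data$frame[-1]) +
                     radius_of(.data$frame[-dplyr::n()])) / 2
          mean(Rbar * dth / dtm)
        }
      },
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_det >= 2L, .data$lifetime_min >= min_lifetime_min) |>
    dplyr::mutate(class = ifelse(.data$speed_um_min < speed_threshold_um_per_min,
                                 "radial", "tangential"))

  out <- det |>
    dplyr::semi_join(summ, by = "track_id") |>
    dplyr::select(-dplyr::any_of(c("lifetime_min", "speed_um_min", "class"))) |>
    dplyr::left_join(
      dplyr::select(summ, "track_id", "lifetime_min", "speed_um_min", "class"),
      by = "track_id"
    )
  fus_kept <- dplyr::filter(fus, .data$fused_into %in% summ$track_id)
  structure(out, class = c("classified_tracks", class(out)),
            track_summary = summ, fusions = fus_kept)
}

#' Per-ring cluster summary
#'
#' Aggregates classified tracks into the ring-level quantities used for
#' cohort analysis: track count, radial fraction, time-averaged cluster
#' density per um of perimeter, mean nearest-neighbour arc spacing and
#' fusion count.
#'
#' @param tracks a [filter_and_classify()] tibble.
#' @param geometry geometry tibble with `frame`, `radius_um`.
#' @return One-row tibble: `n_tracks`, `n_radial`, `n_tangential`,
#'   `radial_fraction` (`NA` and a message when no track is classified),
#'   `cluster_density_per_um`, `mean_spacing_um`, `fusion_count`.
#' @export
summarize_ring <- function(tracks, geometry) {
  summ <- attr(tracks, "track_summary")
  if (is.null(summ)) abort("`tracks` must come from filter_and_classify().")
  geom <- as_tibble(geometry)
  fus <- attr(tracks, "fusions")
  n_radial <- sum(summ$class == "radial")
  n_tangential <- sum(summ$class == "tangential")
  radial_fraction <- if (nrow(summ) == 0L) {
    inform("no classified tracks; radial_fraction undefined.")
    NA_real_
  } else n_radial / (n_radial + n_tangential)

  det <- as_tibble(tracks)
  tracked <- geom[is.finite(geom$radius_um) & geom$radius_um > 0, ]
  density <- if (nrow(det) == 0L) 0 else {
    per_frame <- det |>
      dplyr::count(.data$frame) |>
      dplyr::left_join(tracked[, c("frame", "radius_um")], by = "frame") |>
      dplyr::mutate(density = .data$n / (2 * pi * .data$radius_um))
    # frames tracked but without any detection contribute zero density
    mean(c(per_frame$density,
           rep(0, max(0L, nrow(tracked) - nrow(per_frame)))))
  }
  spacing <- cluster_spacing(det, tracked)
  tibble(
    n_tracks = nrow(summ),
    n_radial = n_radial,
    n_tangential = n_tangential,
    radial_fraction = radial_fraction,
    cluster_density_per_um = density,
    mean_spacing_um = spacing,
    fusion_count = nrow(fus)
  )
}
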