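#' Synthetic pseudo-ultrasound master texture
#'
#' A feature-rich grayscale field for exercising correlation-based
#' stitching: smoothed uniform speckle plus two bright condyle-like arcs
#' whose centres serve as the medial and lateral landmarks.
#'
#' @param width_px,height_px Image size, px.
#' @param landmarks List with `medial` and `lateral` `(x, y)` pixel
#'   coordinates of the arc centres; defaults to symmetric positions.
#' @param seed Integer seed.
#' @return A list with `image` (height x width matrix in `[0, 1]`) and
#'   `landmarks`.
#' @export
make_pseudo_ultrasound <- function(width_px = 900, height_px = 220,
                                   landmarks = NULL, seed = 1L) {
  set.seed(seed)
  if (is.null(landmarks)) {
    landmarks <- list(medial = c(round(width_px * 0.28), round(height_px * 0.55)),
                      lateral = c(round(width_px * 0.72), round(height_px * 0.55)))
  }
  img <- matrix(runif(width_px * height_px), nrow = height_px)
  k <- rep(1 / 7, 7)
  img <- t(apply(img, 1, function(r) stats::filter(r, k, circular = TRUE)))
  img <- apply(img, 2, function(cl) stats::filter(cl, k, circular = TRUE))
  img <- matrix(as.numeric(img), nrow = height_px)

  xs <- matrix(rep(seq_len(width_px), each = height_px), nrow = height_px)
  ys <- matrix(rep(seq_len(height_px), times = width_px), nrow = height_px)
  for (lm in landmarks) {
    r <- sqrt((xs - lm[1])^2 + ((ys - lm[2]) * 1.6)^2)
    img <- img + 0.9 * exp(-(r - 28)^2 / (2 * 4^2)) * (ys < lm[2] + 12)
  }
  img <- (img - min(img)) / (max(img) - min(img))
  list(image = img, landmarks = landmarks)
}

#' Specification for a synthetic ultrasound tile set
#'
#' Tiles are exact vertical-strip crops of a master image at stated
#' horizontal offsets (emulating a probe sliding across the knee), with the
#' planted landmark pair defining the true calibrated distance.
#'
#' @param master_image Height x width grayscale matrix.
#' @param tile_width_px Tile width, px.
#' @param offsets_px Ordered 0-based horizontal offsets of each tile.
#' @param landmark_pair_px List with `medial` and `lateral` `(x, y)` pixel
#'   coordinates inside the master image.
#' @param px_per_cm Pixel-to-centimetre calibration factor.
#' @return A list of class `tile_set_spec`.
#' @export
tile_set_spec <- function(master_image, tile_width_px, offsets_px,
                          landmark_pair_px, px_per_cm) {
  if (any(diff(offsets_px) <= 0)) abort("offsets must be monotone increasing")
  if (any(diff(offsets_px) > 0.8 * tile_width_px)) {
    abort("consecutive tiles must overlap by at least 20% of the tile width")
  }
  w <- ncol(master_image); h <- nrow(master_image)
  if (max(offsets_px) + tile_width_px > w) abort("tiles exceed master image width")
  for (lm in landmark_pair_px) {
    if (lm[1] < 1 || lm[1] > w || lm[2] < 1 || lm[2] > h) {
      abort("landmarks must lie inside the master image")
    }
  }
  if (px_per_cm <= 0) abort("px_per_cm must be positive")
  structure(list(master_image = master_image, tile_width_px = as.integer(tile_width_px),
                 offsets_px = as.integer(offsets_px),
                 landmark_pair_px = landmark_pair_px, px_per_cm = px_per_cm),
            class = "tile_set_spec")
}

#' Generate an ordered tile set with known true distance
#'
#' @param spec A [tile_set_spec()].
#' @return A list of class `tile_set`: `tiles` (list of matrices),
#'   `true_offsets_px`, `true_distance_cm`, `px_per_cm`, `landmarks`.
#' @export
generate_tile_set <- function(spec) {
  stopifnot(inherits(spec, "tile_set_spec"))
  tiles <- lapply(spec$offsets_px, function(off) {
    spec$master_image[, (off + 1):(off + spec$tile_width_px), drop = FALSE]
  })
  lm <- spec$landmark_pair_px
  d_px <- sqrt(sum((lm[[1]] - lm[[2]])^2))
  structure(list(tiles = tiles, true_offsets_px = spec$offsets_px,
                 true_distance_cm = d_px / spec$px_per_cm,
                 px_per_cm = spec$px_per_cm, landmarks = lm),
            class = "tile_set")
}

#' Load an ordered frame sequence from a directory of images
#'
#' Reads grayscale PNG frames (sorted by file name, which preserves the
#' source timestamp order) and optionally subsamples them to a target frame
#' rate.
#'
#' @param source Directory containing PNG frames, or a list of matrices.
#' @param rate_fps Target frame rate after subsampling, frames/s.
#' @param source_fps Source frame rate; when given, every
#'   `round(source_fps / rate_fps)`-th frame is kept.
#' @return A list of grayscale matrices (class `tile_sequence`).
#' @export
extract_frames <- function(source, rate_fps = 10, source_fps = NULL) {
  if (is.character(source)) {
    if (!dir.exists(source)) abort(paste0("unreadable source: ", source))
    files <- sort(list.files(source, pattern = "\\.png$", full.names = TRUE))
    frames <- lapply(files, read_gray_png)
  } else {
    frames <- source
  }
  if (!length(frames)) abort("no frames found in source")
  if (!is.null(source_fps)) {
    step <- max(1L, round(source_fps / rate_fps))
    frames <- frames[seq(1, length(frames), by = step)]
  }
  structure(frames, class = "tile_sequence")
}

read_gray_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- apply(a[, , 1:min(3, dim(a)[3]), drop = FALSE], c(1, 2), mean)
  a
}

#' Write tiles as 8-bit grayscale PNGs
#' @param tiles List of matrices in `[0, 1]`.
#' @param dir Output directory (created if needed).
#' @return The written file paths, invisibly.
#' @export
write_tiles_png <- function(tiles, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_along(tiles), function(i) {
    p <- file.path(dir, sprintf("tile_%03d.png", i))
    png::writePNG(tiles[[i]], p)
    p
  }, character(1))
  invisible(paths)
}

# normalized cross-correlation of the overlap for one candidate shift
ncc_at_shift <- function(a, b, s) {
  w <- ncol(a) - s
  va <- as.vector(a[, (s + 1):ncol(a), drop = FALSE])
  vb <- as.vector(b[, 1:w, drop = FALSE])
  if (sd(va) == 0 || sd(vb) == 0) return(0)
  cor(va, vb)
}

#' Stitch overlapping tiles into a panorama
#'
#' Translation-only (horizontal) registration: for each consecutive tile
#' pair the shift maximising the normalized cross-correlation (NCC) of the
#' overlap is selected, subject to a minimum 20% overlap. The panorama
#' places tiles at the recovered cumulative offsets, averaging overlapping
#' pixels. The probe slides laterally in contact with the skin, so
#' perspective distortion is negligible and NCC registration is
#' deterministic; feature-based stitching is out of scope here.
#'
#' @param tiles A `tile_sequence`, `tile_set`, or list of equally sized
#'   grayscale matrices.
#' @param min_overlap_frac Minimum overlap fraction considered.
#' @param corr_floor NCC below this raises a stitch failure naming the pair.
#' @return A list of class `stitch_result`: `panorama` (matrix) and
#'   `offsets_px` (0-based per-tile offsets).
#' @export
stitch_tiles <- function(tiles, min_overlap_frac = 0.2, corr_floor = 0.5) {
  if (inherits(tiles, "tile_set")) tiles <- tiles$tiles
  if (!length(tiles)) abort("need at least one tile")
  h <- nrow(tiles[[1]])
  w <- ncol(tiles[[1]])
  offsets <- integer(length(tiles))
  if (length(tiles) > 1) {
    smax <- floor((1 - min_overlap_frac) * w)
    for (i in seq_len(length(tiles) - 1)) {
      ncc <- vapply(0:smax, function(s) ncc_at_shift(tiles[[i]], tiles[[i + 1]], s),
                    numeric(1))
      best <- which.max(ncc) - 1L
      if (ncc[best + 1L] < corr_floor) {
        abort(paste0("stitch failure between tiles ", i, " and ", i + 1,
                     " (best NCC ", round(ncc[best + 1L], 3), ")"))
      }
      offsets[i + 1] <- offsets[i] + best
    }
  }
  width_pan <- offsets[length(offsets)] + w
  acc <- matrix(0, h, width_pan)
  cnt <- matrix(0, h, width_pan)
  for (i in seq_along(tiles)) {
    cols <- (offsets[i] + 1):(offsets[i] + w)
    acc[, cols] <- acc[, cols] + tiles[[i]]
    cnt[, cols] <- cnt[, cols] + 1
  }
  structure(list(panorama = acc / pmax(cnt, 1), offsets_px = offsets),
            class = "stitch_result")
}

#' Calibrated distance between two annotated landmarks
#'
#' Euclidean pixel distance between the medial and lateral condyle centres,
#' converted to centimetres with the probe calibration factor. Landmarks are
#' supplied by the rater (annotation), not auto-detected.
#'
#' @param panorama A `stitch_result` or grayscale matrix.
#' @param landmarks List with two `(x, y)` pixel coordinates (e.g. `medial`,
#'   `lateral`).
#' @param px_per_cm Calibration factor, px/cm.
#' @param rater,session,repeat_index Optional measurement metadata.
#' @return A one-row tibble (class `calibrated_measurement`) with
#'   `distance_px`, `px_per_cm`, `distance_cm` and the metadata.
#' @export
measure_distance <- function(panorama, landmarks, px_per_cm,
                             rater = NA_character_, session = NA_character_,
                             repeat_index = NA_integer_) {
  img <- if (inherits(panorama, "stitch_result")) panorama$panorama else panorama
  if (px_per_cm <= 0) abort("px_per_cm must be positive")
  for (lm in landmarks) {
    if (lm[1] < 1 || lm[1] > ncol(img) || lm[2] < 1 || lm[2] > nrow(img)) {
      abort("landmark outside panorama bounds")
    }
  }
  d_px <- sqrt(sum((landmarks[[1]] - landmarks[[2]])^2))
  out <- tibble(distance_px = d_px, px_per_cm = px_per_cm,
                distance_cm = d_px / px_per_cm,
                rater = rater, session = session, repeat_index = repeat_index)
  class(out) <- c("calibrated_measurement", class(out))
  out
}

#' Scale a measured intercondylar distance to the midcondylar distance
#'
#' The ultrasound measurement is taken superior to the patella with the knee
#' flexed, which underestimates the distance between the midpoints of the
#' condyles; it is scaled by a gender-specific cadaver-derived ratio of
#' midcondylar to intercondylar distance.
#'
#' @param d_cm Measured intercondylar distance, cm.
#' @param gender `"female"` or `"male"`.
#' @param model A `moment_arm_model` (supplies `condylar_ratio`).
#' @return Estimated midcondylar distance, cm.
#' @export
to_midcondylar <- function(d_cm, gender = c("female", "male"),
                           model = load_model_config()) {
  gender <- match.arg(gender)
  if (any(d_cm <= 0)) abort("measured distance must be positive")
  d_cm * model$condylar_ratio[[gender]]
}

#' Aggregate repeated calibrated measurements to a per-subject mean
#'
#' The per-subject value is the grand mean over raters x repeats. If a rater
#' present elsewhere in the table is missing for some subject, the mean of
#' the available measurements is used and a warning is logged.
#'
#' @param measurements Tibble with columns `subject`, `rater`, `distance_cm`
#'   (other columns ignored).
#' @return Tibble with `subject`, `n`, `distance_cm` (mean).
#' @export
aggregate_measurements <- function(measurements) {
  all_raters <- unique(measurements$rater)
  per <- measurements |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(n = dplyr::n(),
                     n_raters = dplyr::n_distinct(.data$rater),
                     distance_cm = mean(.data$distance_cm), .groups = "drop")
  if (any(per$n_raters < length(all_raters))) {
    warn("some subjects are missing raters; using the mean of available measurements")
  }
  dplyr::select(per, "subject", "n", "distance_cm")
}
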