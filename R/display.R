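#' Layout of a 3 x 3 search display
#'
#' Describes the raster, the nine nominal patch rectangles (slots numbered
#' 1..9 in row-major order), the jitter amplitude applied to patch centers
#' when a display is rendered, and which slot holds the target.
#'
#' @param raster_size raster side length in pixels (square displays).
#' @param patch_size side length of each face patch in pixels; must leave
#'   room for the jitter (`patch_size + 2*jitter <= raster_size/3`)
#'   if overlap-free placement is to be guaranteed.
#' @param jitter maximal absolute perturbation of each patch center, pixels.
#' @param target_slot slot index 1..9, or `NA` for a target-absent display.
#' @return object of class `"grid_layout"` with a `rects` data.frame
#'   (`slot, row0, col0, row1, col1`, 1-based inclusive pixel bounds).
#' @export
grid_layout <- function(raster_size = 384L, patch_size = 96L, jitter = 8L,
                        target_slot = NA_integer_) {
  raster_size <- as.integer(raster_size); patch_size <- as.integer(patch_size)
  stopifnot(raster_size >= 3 * patch_size, patch_size >= 8, jitter >= 0)
  if (!is.na(target_slot)) stopifnot(target_slot %in% 1:9)
  tile <- raster_size / 3
  centers <- expand.grid(col = 1:3, row = 1:3)  # row-major slot order
  centers <- data.frame(slot = 1:9,
                        row = (centers$row - 0.5) * tile,
                        col = (centers$col - 0.5) * tile)
  rects <- rects_from_centers(centers$row, centers$col, patch_size)
  rects$slot <- 1:9
  structure(list(raster_size = raster_size, patch_size = patch_size,
                 jitter = as.integer(jitter), target_slot = target_slot,
                 centers = centers, rects = rects),
            class = "grid_layout")
}

rects_from_centers <- function(row, col, patch) {
  half <- patch / 2
  data.frame(row0 = as.integer(round(row - half)) + 1L,
             col0 = as.integer(round(col - half)) + 1L,
             row1 = as.integer(round(row - half)) + patch,
             col1 = as.integer(round(col - half)) + patch)
}

#' Parametric face-like patch
#'
#' Renders a synthetic face-like image patch: an oval "skin" region on a
#' mid-gray background carrying two eye blobs, two brows whose tilt conveys
#' anger, a mouth whose curvature conveys valence, and an oriented
#' sinusoidal texture that controls orientation energy.  These patches
#' stand in for photographic face stimuli (which are license-restricted)
#' in the saliency and motion computations; they are synthetic by design
#' and make the low-level feature content fully controllable.
#'
#' @param size patch side length in pixels.
#' @param contrast multiplier on all feature contrasts (>= 0).
#' @param mouth_curve curvature of the mouth in `[-1, 1]`: positive curves
#'   upward (smile), negative downward (frown), 0 is neutral.
#' @param brow_tilt brow rotation in radians; negative values slant the
#'   brows inward-down (anger cue).
#' @param texture_orientation orientation of the carrier texture, radians.
#' @param texture_freq texture spatial frequency, cycles per pixel.
#' @param texture_amp texture amplitude before the contrast multiplier.
#' @return `size` x `size` matrix with values in `[0, 1]`.
#' @export
face_patch <- function(size = 96L, contrast = 1, mouth_curve = 0,
                       brow_tilt = 0, texture_orientation = 0,
                       texture_freq = 0.08, texture_amp = 0.08) {
  stopifnot(size >= 8, contrast >= 0)
  # normalized coordinates in [-1, 1], y positive downward
  v <- seq(-1, 1, length.out = size)
  x <- matrix(v, size, size, byrow = TRUE)
  y <- matrix(v, size, size)
  face <- exp(-((x / 0.80)^2 + (y / 0.92)^2)^3)  # soft oval mask
  img <- 0.5 + face * 0.18                        # skin lighter than background

  blob <- function(cx, cy, sx, sy, theta = 0) {
    xr <- (x - cx) * cos(theta) + (y - cy) * sin(theta)
    yr <- -(x - cx) * sin(theta) + (y - cy) * cos(theta)
    exp(-((xr / sx)^2 + (yr / sy)^2))
  }
  eyes <- blob(-0.33, -0.22, 0.13, 0.09) + blob(0.33, -0.22, 0.13, 0.09)
  brows <- blob(-0.33, -0.45, 0.22, 0.05, -brow_tilt) +
           blob(0.33, -0.45, 0.22, 0.05, brow_tilt)
  # mouth: tube around a parabolic arc, curvature sign = valence
  mouth_y <- 0.42 - mouth_curve * 0.22 * (1 - (x / 0.38)^2)
  mouth <- exp(-((x / 0.38)^10)) * exp(-((y - mouth_y) / 0.07)^2)
  tex <- texture_amp *
    cos(2 * pi * texture_freq * size / 2 *
        (x * cos(texture_orientation) + y * sin(texture_orientation)))
  img <- img + contrast * face * (tex - 0.35 * eyes - 0.30 * brows - 0.30 * mouth)
  pmin(pmax(img, 0), 1)
}

#' Build a set of face-patch parameter lists for one emotion
#'
#' Returns `n` parameter lists ("identities") for [face_patch()], varying
#' texture orientation and frequency deterministically across identities
#' while keeping the emotion-defining mouth/brow settings fixed.
#'
#' @param n number of identities.
#' @param emotion `"angry"`, `"happy"` or `"neutral"`.
#' @param contrast feature contrast passed to every identity.
#' @param seed integer controlling the identity-to-identity variation.
#' @return list of `n` parameter lists.
#' @export
patch_set <- function(n, emotion = c("neutral", "angry", "happy"),
                      contrast = 1, seed = 1L) {
  emotion <- match.arg(emotion)
  base <- switch(emotion,
    neutral = list(mouth_curve = 0, brow_tilt = 0),
    angry = list(mouth_curve = -0.7, brow_tilt = -0.5),
    happy = list(mouth_curve = 0.7, brow_tilt = 0.15))
  old <- .Random.seed_safe()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    c(base, list(contrast = contrast,
                 texture_orientation = runif(1, 0, pi),
                 texture_freq = runif(1, 0.06, 0.10),
                 texture_amp = runif(1, 0.06, 0.10)))
  })
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Render a 3 x 3 display of face patches
#'
#' Places nine patches at jittered grid positions on a mid-gray raster.
#' Jittered rectangles are re-drawn (up to `max_retries`) until they are
#' pairwise disjoint and inside the raster, then the patches are rendered
#' into them.
#'
#' @param layout a [grid_layout()].
#' @param patch_params list of nine parameter lists for [face_patch()]
#'   (slot order, row-major).
#' @param rng_seed integer seed, or `NULL` to consume the current RNG
#'   stream (used when a caller manages reproducibility itself).
#' @param max_retries placement attempts before giving up.
#' @return object of class `"synthetic_display"`: `image` (matrix in
#'   `[0, 1]`), `layout` (with the realized, jittered `rects`) and
#'   `target_slot`.
#' @export
generate_display <- function(layout, patch_params, rng_seed = NULL,
                             max_retries = 100L) {
  stopifnot(inherits(layout, "grid_layout"), length(patch_params) == 9)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  n <- layout$raster_size; p <- layout$patch_size; j <- layout$jitter
  rects <- NULL
  for (try in seq_len(max_retries)) {
    dr <- if (j > 0) sample.int(2L * j + 1L, 9, replace = TRUE) - j - 1L else integer(9)
    dc <- if (j > 0) sample.int(2L * j + 1L, 9, replace = TRUE) - j - 1L else integer(9)
    r <- rects_from_centers(layout$centers$row + dr, layout$centers$col + dc, p)
    r$slot <- 1:9
    inside <- all(r$row0 >= 1 & r$col0 >= 1 & r$row1 <= n & r$col1 <= n)
    if (inside && !any_rect_overlap(r)) { rects <- r; break }
  }
  if (is.null(rects))
    stop("could not place 9 non-overlapping patches after ", max_retries,
         " attempts; reduce jitter or patch_size")
  img <- matrix(0.5, n, n)
  for (s in 1:9) {
    patch <- do.call(face_patch, c(list(size = p), patch_params[[s]]))
    img[rects$row0[s]:rects$row1[s], rects$col0[s]:rects$col1[s]] <- patch
  }
  layout$rects <- rects
  structure(list(image = img, layout = layout,
                 target_slot = layout$target_slot),
            class = "synthetic_display")
}

any_rect_overlap <- function(r) {
  for (a in 1:8) for (b in (a + 1):9) {
    if (r$row0[a] <= r$row1[b] && r$row0[b] <= r$row1[a] &&
        r$col0[a] <= r$col1[b] && r$col0[b] <= r$col1[a]) return(TRUE)
  }
  FALSE
}

#' Write a display to PNG with a JSON layout sidecar
#'
#' @param display a `"synthetic_display"`.
#' @param png_path output PNG path; the sidecar is written next to it with
#'   extension `.json`.
#' @return invisibly, the PNG path.
#' @export
write_display <- function(display, png_path) {
  EBImage::writeImage(EBImage::Image(t(display$image)), png_path)
  sidecar <- sub("\\.png$", ".json", png_path)
  jsonlite::write_json(list(raster_size = display$layout$raster_size,
                            patch_size = display$layout$patch_size,
                            target_slot = display$target_slot,
                            rects = display$layout$rects),
                       sidecar, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(png_path)
}
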