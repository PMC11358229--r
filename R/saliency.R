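# Bottom-up saliency: multi-scale center-surround conspicuity in the style
# of the classic Itti-Koch architecture.  All filtering uses a circular
# (wrap-around) boundary so that the map of a spatially periodic display is
# itself periodic -- which is what makes the saliency index of a display of
# nine identical patches exactly 1.

# Gaussian blur with circular boundary; kernel shrinks on tiny maps
gauss_blur_circ <- function(x, sigma = 1) {
  r <- min(2L * ceiling(2 * sigma), (min(dim(x)) - 1L) %/% 2L)
  if (r < 1) return(x)
  k <- dnorm(seq(-r, r), sd = sigma)
  K <- outer(k, k); K <- K / sum(K)
  EBImage::filter2(x, K, boundary = "circular")
}

# halve each dimension by block averaging (odd trailing row/col averaged alone)
downsample2 <- function(x) {
  ri <- rep(seq_len(ceiling(nrow(x) / 2)), each = 2)[seq_len(nrow(x))]
  ci <- rep(seq_len(ceiling(ncol(x) / 2)), each = 2)[seq_len(ncol(x))]
  m <- rowsum(x, ri, reorder = FALSE)
  m <- t(rowsum(t(m), ci, reorder = FALSE))
  m / outer(tabulate(ri), tabulate(ci))
}

resize_nn <- function(x, nr, nc) {
  x[floor((seq_len(nr) - 1) * nrow(x) / nr) + 1L,
    floor((seq_len(nc) - 1) * ncol(x) / nc) + 1L, drop = FALSE]
}

gaussian_pyramid <- function(x, n_levels = 9L) {
  pyr <- vector("list", n_levels)
  pyr[[1]] <- x
  for (l in 2:n_levels) pyr[[l]] <- downsample2(gauss_blur_circ(pyr[[l - 1]]))
  pyr
}

# quadrature-pair Gabor kernels (zero-DC even part)
gabor_pair <- function(theta, size = 9L, wavelength = 7, sigma = 2.8,
                       gamma = 0.8) {
  r <- (size - 1L) %/% 2L
  g <- expand.grid(y = seq(-r, r), x = seq(-r, r))
  xr <- g$x * cos(theta) + g$y * sin(theta)
  yr <- -g$x * sin(theta) + g$y * cos(theta)
  env <- exp(-(xr^2 + gamma^2 * yr^2) / (2 * sigma^2))
  even <- env * cos(2 * pi * xr / wavelength)
  odd <- env * sin(2 * pi * xr / wavelength)
  even <- even - env * sum(even) / sum(env)   # zero response to uniform input
  list(even = matrix(even, 2 * r + 1), odd = matrix(odd, 2 * r + 1))
}

gabor_energy <- function(x, theta) {
  size <- min(9L, if (min(dim(x)) %% 2L == 1L) min(dim(x)) else min(dim(x)) - 1L)
  if (size < 5) return(matrix(0, nrow(x), ncol(x)))
  gp <- gabor_pair(theta, size = size)
  e <- EBImage::filter2(x, gp$even, boundary = "circular")
  o <- EBImage::filter2(x, gp$odd, boundary = "circular")
  sqrt(e^2 + o^2)
}

# Itti-Koch max-normalization: promote maps with few dominant peaks.
# Maps whose peak activation is numerically indistinguishable from zero
# (floating-point residue of featureless input) are nulled rather than
# rescaled.
normalize_map <- function(m) {
  mx <- max(m)
  if (!is.finite(mx) || mx <= 1e-9) return(m * 0)
  m <- m / mx
  locmax <- local_maxima(m, threshold = 0.05)
  others <- locmax[locmax < 1 - 1e-12]
  mbar <- if (length(others) > 0) mean(others) else 0
  m * (1 - mbar)^2
}

# values of strict 8-neighborhood local maxima (wrap-around neighborhood)
local_maxima <- function(m, threshold = 0) {
  if (min(dim(m)) < 3) return(max(m))
  sh <- function(dr, dc) {
    ri <- ((seq_len(nrow(m)) - 1 + dr) %% nrow(m)) + 1
    ci <- ((seq_len(ncol(m)) - 1 + dc) %% ncol(m)) + 1
    m[ri, ci, drop = FALSE]
  }
  is_max <- m > threshold
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & (m > sh(dr, dc))
  }
  m[is_max]
}

center_surround_set <- function(pyr, centers = 3:5, deltas = 3:4) {
  # centers/deltas in 1-based list indices: centers 3:5 are pyramid levels
  # 2..4, surrounds are center + delta (levels 5..8)
  maps <- list()
  for (cl in centers) for (d in deltas) {
    ctr <- pyr[[cl]]
    srd <- resize_nn(pyr[[cl + d]], nrow(ctr), ncol(ctr))
    maps[[length(maps) + 1]] <- abs(ctr - srd)
  }
  maps
}

sum_at_scale <- function(maps, nr, nc) {
  out <- matrix(0, nr, nc)
  for (m in maps) out <- out + resize_nn(normalize_map(m), nr, nc)
  out
}

#' Bottom-up saliency map of an image
#'
#' Computes a conspicuity-based saliency map: a 9-level Gaussian pyramid is
#' built for each low-level feature channel (intensity; red-green and
#' blue-yellow color opponency for color images; four orientation-energy
#' channels at 0, 45, 90 and 135 degrees from quadrature Gabor pairs);
#' center-surround feature maps are formed as absolute differences between
#' center scales 2-4 and surround scales 3 or 4 levels coarser; each map is
#' passed through the max-normalization operator that promotes maps with a
#' few dominant peaks; maps are summed into per-channel conspicuity maps at
#' a common scale (pyramid level 4), normalized again, and averaged into
#' the final map, which is returned upsampled to the input resolution.
#'
#' @param image numeric matrix (grayscale) or array with 3 channels (RGB),
#'   intensities in `[0, 1]`.
#' @return object of class `"saliency_map"`: `map` (nonnegative matrix at
#'   input resolution), `map_scale_dim`, and `channels` used.
#' @export
compute_saliency_map <- function(image) {
  is_color <- length(dim(image)) == 3
  if (is_color) stopifnot(dim(image)[3] == 3)
  if (anyNA(image)) stop("image contains NA pixels")
  if (min(image) < -1e-9 || max(image) > 1 + 1e-9)
    stop("image intensities must lie in [0, 1]")
  dims <- dim(image)[1:2]
  if (min(dims) < 64)
    stop("image too small for the 9-level center-surround pyramid (min dim 64)")

  if (is_color) {
    r <- image[, , 1]; g <- image[, , 2]; b <- image[, , 3]
    intensity <- (r + g + b) / 3
  } else intensity <- image

  # level-4 saliency scale
  sc_dim <- dims
  for (i in 1:4) sc_dim <- ceiling(sc_dim / 2)

  channels <- list()
  ipyr <- gaussian_pyramid(intensity)
  channels$intensity <- sum_at_scale(center_surround_set(ipyr),
                                     sc_dim[1], sc_dim[2])

  if (is_color && max(abs(r - g), abs(b - (r + g) / 2)) > 1e-9) {
    rg <- (r - g)
    by <- b - (r + g) / 2
    cmaps <- c(center_surround_set(gaussian_pyramid(rg)),
               center_surround_set(gaussian_pyramid(by)))
    channels$color <- sum_at_scale(cmaps, sc_dim[1], sc_dim[2])
  }

  omaps <- list()
  for (theta in c(0, pi / 4, pi / 2, 3 * pi / 4)) {
    # orientation energy is only needed at the center/surround levels (2..8)
    epyr <- vector("list", length(ipyr))
    for (l in 3:length(ipyr)) epyr[[l]] <- gabor_energy(ipyr[[l]], theta)
    omaps <- c(omaps, center_surround_set(epyr))
  }
  channels$orientation <- sum_at_scale(omaps, sc_dim[1], sc_dim[2])

  smap <- Reduce(`+`, lapply(channels, normalize_map)) / length(channels)
  smap <- resize_nn(smap, dims[1], dims[2])
  dimnames(smap) <- NULL
  structure(list(map = smap,
                 map_scale_dim = sc_dim, channels = names(channels)),
            class = "saliency_map")
}

#' Saliency index of a target in a 3 x 3 display
#'
#' Sums the saliency map inside each of the nine patch rectangles and
#' returns the ratio of the target region's total activation to the mean
#' total activation of the eight distractor regions.  An index of 1 means
#' the target is no more salient than the average distractor.
#'
#' @param map a `"saliency_map"` (or a plain matrix at display resolution).
#' @param layout a [grid_layout()] with realized `rects` and a target slot
#'   (e.g. the `layout` element of a [generate_display()] result).
#' @return object of class `"salience_result"`: `activations` (length 9),
#'   `saliency_index`, `target_slot`.
#' @export
saliency_index <- function(map, layout) {
  m <- if (inherits(map, "saliency_map")) map$map else map
  stopifnot(inherits(layout, "grid_layout"))
  ts <- layout$target_slot
  if (is.na(ts)) stop("layout has no target slot; the saliency index is undefined")
  r <- layout$rects
  act <- vapply(1:9, function(s)
    sum(m[r$row0[s]:r$row1[s], r$col0[s]:r$col1[s]]), 0)
  distr <- mean(act[-ts])
  if (distr <= 0) stop("zero mean distractor activation; degenerate display")
  structure(list(activations = act, saliency_index = act[ts] / distr,
                 target_slot = ts),
            class = "salience_result")
}

#' Monte-Carlo saliency-index simulation over 3 x 3 displays
#'
#' For each target emotion and each replicate, a target slot is drawn
#' uniformly from the nine positions, a target identity is drawn from that
#' emotion's patch set, eight distinct distractor identities fill the
#' remaining slots, the display is rendered with jittered positions, its
#' saliency map is computed, and the saliency index recorded.  The summary
#' contrasts the two emotions' index distributions: mean difference, its
#' standard error, and a 95% percentile bootstrap interval.
#'
#' @param target_patches named list of two patch sets (e.g.
#'   `list(angry = ..., happy = ...)`), each a list of [face_patch()]
#'   parameter lists (identities).
#' @param distractor_patches patch set of at least 8 distractor identities.
#' @param n_reps_per_emotion replicates per emotion (the validation
#'   simulations of this paradigm conventionally use 504 per emotion).
#' @param layout a [grid_layout()] (its `target_slot` is overridden per
#'   replicate).
#' @param rng_seed integer seed; the whole simulation is deterministic
#'   given it.
#' @param n_boot bootstrap resamples for the interval.
#' @return list with `results` (data.frame `replicate, emotion,
#'   target_slot, index`) and `summary` (`mean_index` per emotion,
#'   `mean_difference`, `se`, `ci`).
#' @export
run_salience_simulation <- function(target_patches, distractor_patches,
                                    n_reps_per_emotion = 504L,
                                    layout = grid_layout(), rng_seed = 1L,
                                    n_boot = 2000L) {
  stopifnot(is.list(target_patches), length(target_patches) == 2,
            !is.null(names(target_patches)), n_reps_per_emotion >= 1)
  if (length(distractor_patches) < 8)
    stop("need at least 8 distractor identities")
  set.seed(rng_seed)
  emotions <- names(target_patches)
  rows <- vector("list", 2L * n_reps_per_emotion)
  i <- 1L
  for (em in emotions) {
    tp <- target_patches[[em]]
    for (rep in seq_len(n_reps_per_emotion)) {
      slot <- sample.int(9L, 1L)
      tid <- sample.int(length(tp), 1L)
      did <- sample.int(length(distractor_patches), 8L)
      params <- vector("list", 9L)
      params[setdiff(1:9, slot)] <- distractor_patches[did]
      params[[slot]] <- tp[[tid]]
      lay <- layout; lay$target_slot <- slot
      res <- tryCatch({
        disp <- generate_display(lay, params, rng_seed = NULL)
        smap <- compute_saliency_map(disp$image)
        saliency_index(smap, disp$layout)
      }, error = function(e)
        stop("salience simulation failed at emotion '", em, "', replicate ",
             rep, ": ", conditionMessage(e), call. = FALSE))
      rows[[i]] <- data.frame(replicate = rep, emotion = em,
                              target_slot = slot,
                              index = res$saliency_index,
                              stringsAsFactors = FALSE)
      i <- i + 1L
    }
  }
  results <- do.call(rbind, rows)
  ia <- results$index[results$emotion == emotions[1]]
  ib <- results$index[results$emotion == emotions[2]]
  diff_mean <- mean(ia) - mean(ib)
  se <- sqrt(var(ia) / length(ia) + var(ib) / length(ib))
  boot <- replicate(n_boot, mean(sample(ia, replace = TRUE)) -
                            mean(sample(ib, replace = TRUE)))
  ci <- unname(quantile(boot, c(0.025, 0.975)))
  list(results = results,
       summary = list(mean_index = setNames(c(mean(ia), mean(ib)), emotions),
                      mean_difference = diff_mean, se = se, ci = ci))
}
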