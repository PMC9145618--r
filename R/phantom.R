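#' Configuration for the synthetic CTA phantom
#'
#' Defines a desk-scale stand-in for a lower-limb CT angiography series: an
#' elliptical soft-tissue body cross-section that tapers toward the distal
#' end, a small set of bright, slice-continuous vessel tubes inside it, an
#' air background, and additive Gaussian noise whose standard deviation
#' decreases from the proximal (abdominal, noisier) to the distal end.
#' Intensities are stored values on the unsigned 16-bit CT scale; the
#' defaults mimic the contrast ordering air << soft tissue << contrast agent
#' (with intercept -1024, body 1080 is approximately +56 HU and vessels 1600
#' approximately +576 HU, a typical strong arterial enhancement).
#'
#' @param n_slices number of slices (proximal first).
#' @param slice_shape integer length-2 `(rows, cols)`.
#' @param body_intensity stored value of soft tissue.
#' @param vessel_intensity stored value of contrast-filled vessel lumen;
#'   must exceed `body_intensity`.
#' @param air_intensity stored value of the air background; must be below
#'   `body_intensity`.
#' @param noise_sigma_proximal,noise_sigma_distal additive Gaussian noise
#'   standard deviations at the first and last slice (stored-value units,
#'   linearly interpolated along the slice axis). Proximal must be >= distal.
#' @param vessel_count number of vessel trees (0 allowed, for noise-free /
#'   geometry-only fixtures).
#' @param taper in `(0, 1]`: linear shrink factor of the body ellipse axes at
#'   the last slice relative to the first.
#' @param branch_prob probability that a vessel spawns one branch at a random
#'   depth in the middle third of the volume. Set to 0 for single unbranched
#'   tubes.
#' @param seed integer RNG seed; the generator is bit-reproducible for a
#'   fixed configuration.
#'
#' @return a `phantom_config` list.
#' @seealso [generate_phantom()]
#' @export
phantom_config <- function(n_slices = 64L,
                           slice_shape = c(256L, 256L),
                           body_intensity = 1080L,
                           vessel_intensity = 1600L,
                           air_intensity = 50L,
                           noise_sigma_proximal = 20,
                           noise_sigma_distal = 5,
                           vessel_count = 3L,
                           taper = 0.8,
                           branch_prob = 0.5,
                           seed = 42L) {
  cfg <- list(n_slices = as.integer(n_slices),
              slice_shape = as.integer(slice_shape),
              body_intensity = as.integer(body_intensity),
              vessel_intensity = as.integer(vessel_intensity),
              air_intensity = as.integer(air_intensity),
              noise_sigma_proximal = as.numeric(noise_sigma_proximal),
              noise_sigma_distal = as.numeric(noise_sigma_distal),
              vessel_count = as.integer(vessel_count),
              taper = as.numeric(taper),
              branch_prob = as.numeric(branch_prob),
              seed = as.integer(seed))
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  assert_that(cfg$n_slices >= 1L, "n_slices must be a positive integer")
  assert_that(length(cfg$slice_shape) == 2L && all(cfg$slice_shape >= 16L),
              "slice_shape must be (rows, cols), each at least 16")
  assert_that(cfg$air_intensity < cfg$body_intensity &&
                cfg$body_intensity < cfg$vessel_intensity,
              "intensity ordering must be air < body < vessel")
  assert_that(cfg$air_intensity >= 0L && cfg$vessel_intensity <= 65535L,
              "intensities must lie in the unsigned 16-bit range")
  assert_that(cfg$noise_sigma_proximal >= 0 && cfg$noise_sigma_distal >= 0,
              "noise sigmas must be non-negative")
  assert_that(cfg$noise_sigma_proximal >= cfg$noise_sigma_distal,
              "proximal noise sigma must be >= distal noise sigma")
  assert_that(cfg$vessel_count >= 0L, "vessel_count must be >= 0")
  assert_that(cfg$taper > 0 && cfg$taper <= 1, "taper must lie in (0, 1]")
  assert_that(cfg$branch_prob >= 0 && cfg$branch_prob <= 1,
              "branch_prob must lie in [0, 1]")
  invisible(cfg)
}

# Body ellipse semi-axes at full (proximal) scale. The constants put the
# proximal body fraction near 0.53 of the frame, so that after the default
# 0.8 taper the distal fraction stays above 0.3 -- the secondary ROI then
# occupies roughly a third to a half of the image, as in abdominal-to-calf
# CTA cross-sections.
phantom_axes <- function(shape) c(a = 0.40 * shape[1], b = 0.42 * shape[2])

# Per-slice ellipse shrink factor: linear from 1 (slice 1) to taper (slice n).
phantom_scale <- function(i, n, taper) {
  if (n == 1L) 1 else 1 + (taper - 1) * (i - 1) / (n - 1)
}

#' Generate a synthetic CTA-like volume with ground truth
#'
#' Builds the phantom described by [phantom_config()]: per slice, an
#' elliptical body at `body_intensity` over an `air_intensity` background,
#' vessel tubes rendered as discs of 2--5 px radius along piecewise-linear
#' 3D centerlines (optionally branching once), depth-interpolated Gaussian
#' noise, and clipping to `[0, 65535]`. Vessel discs are clipped to the body
#' so the ground-truth containment `vessel_mask` in `body_mask` holds on
#' every slice. Under the default configuration the vessel mask occupies
#' well under 5% of each slice, matching the anatomy the compression scheme
#' is designed around.
#'
#' @param config a [phantom_config()].
#' @return a list with elements `volume` (an [aroi_volume()]) and `truth`
#'   (list of logical arrays `vessel_mask`, `body_mask`, same dimensions as
#'   the volume).
#' @examples
#' ph <- generate_phantom(phantom_config(n_slices = 4, slice_shape = c(64, 64)))
#' mean(ph$truth$vessel_mask)  # vessel fraction, well under 0.05
#' @export
generate_phantom <- function(config = phantom_config()) {
  validate_phantom_config(config)
  # keep the caller's RNG stream untouched
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  n <- config$n_slices
  rows <- config$slice_shape[1]; cols <- config$slice_shape[2]
  ax <- phantom_axes(config$slice_shape)
  cy <- (rows + 1) / 2; cx <- (cols + 1) / 2

  centerlines <- phantom_centerlines(config)

  px <- array(0L, dim = c(rows, cols, n))
  vessel_mask <- array(FALSE, dim = c(rows, cols, n))
  body_mask <- array(FALSE, dim = c(rows, cols, n))

  rr <- matrix(seq_len(rows), rows, cols)
  cc <- matrix(seq_len(cols), rows, cols, byrow = TRUE)

  sig <- if (n == 1L) config$noise_sigma_proximal else
    config$noise_sigma_proximal +
      (config$noise_sigma_distal - config$noise_sigma_proximal) *
        (seq_len(n) - 1) / (n - 1)

  for (i in seq_len(n)) {
    s <- phantom_scale(i, n, config$taper)
    body <- ((rr - cy) / (ax["a"] * s))^2 + ((cc - cx) / (ax["b"] * s))^2 <= 1
    slice <- matrix(config$air_intensity, rows, cols)
    slice[body] <- config$body_intensity

    vmask <- matrix(FALSE, rows, cols)
    for (cl in centerlines) {
      yc <- cy + cl$ny[i] * ax["a"] * s
      xc <- cx + cl$nx[i] * ax["b"] * s
      if (cl$alive[i]) {
        disc <- (rr - yc)^2 + (cc - xc)^2 <= cl$radius^2
        vmask <- vmask | disc
      }
    }
    vmask <- vmask & body  # ground-truth containment, by construction
    slice[vmask] <- config$vessel_intensity

    if (sig[i] > 0) {
      slice <- slice + matrix(stats::rnorm(rows * cols, sd = sig[i]), rows, cols)
    }
    slice <- round(slice)
    slice[slice < 0] <- 0
    slice[slice > 65535] <- 65535

    px[, , i] <- as.integer(slice)
    vessel_mask[, , i] <- vmask
    body_mask[, , i] <- body
  }

  list(volume = aroi_volume(px),
       truth = list(vessel_mask = vessel_mask, body_mask = body_mask))
}

# Piecewise-linear centerlines in body-normalised coordinates (so vessels
# ride the taper and stay inside the shrinking ellipse). Each element has
# per-slice normalised offsets nx, ny, a constant disc radius, and an
# `alive` flag (FALSE before a branch starts).
phantom_centerlines <- function(config) {
  n <- config$n_slices
  out <- list()
  if (config$vessel_count == 0L) return(out)
  waypoint_every <- 8L

  make_track <- function(start_slice, ny0, nx0) {
    wp_idx <- unique(c(seq(start_slice, n, by = waypoint_every), n))
    m <- length(wp_idx)
    ny <- numeric(m); nx <- numeric(m)
    ny[1] <- ny0; nx[1] <- nx0
    if (m > 1) for (k in 2:m) {
      ny[k] <- ny[k - 1] + stats::rnorm(1, sd = 0.05)
      nx[k] <- nx[k - 1] + stats::rnorm(1, sd = 0.05)
      nrm <- sqrt(ny[k]^2 + nx[k]^2)
      if (nrm > 0.75) { ny[k] <- ny[k] * 0.75 / nrm; nx[k] <- nx[k] * 0.75 / nrm }
    }
    full_ny <- rep(NA_real_, n); full_nx <- rep(NA_real_, n)
    if (m == 1) {
      full_ny[wp_idx] <- ny; full_nx[wp_idx] <- nx
    } else {
      full_ny[start_slice:n] <- stats::approx(wp_idx, ny, xout = start_slice:n)$y
      full_nx[start_slice:n] <- stats::approx(wp_idx, nx, xout = start_slice:n)$y
    }
    alive <- seq_len(n) >= start_slice
    full_ny[!alive] <- 0; full_nx[!alive] <- 0
    list(ny = full_ny, nx = full_nx, alive = alive)
  }

  for (v in seq_len(config$vessel_count)) {
    ang <- stats::runif(1, 0, 2 * pi)
    rad0 <- stats::runif(1, 0, 0.55)
    trunk <- make_track(1L, rad0 * sin(ang), rad0 * cos(ang))
    trunk$radius <- sample(2:5, 1)
    out[[length(out) + 1L]] <- trunk
    if (n >= 9L && stats::runif(1) < config$branch_prob) {
      b0 <- sample(seq(max(2L, floor(n / 3)), max(2L, floor(2 * n / 3))), 1)
      child <- make_track(as.integer(b0), trunk$ny[b0], trunk$nx[b0])
      child$radius <- max(2L, trunk$radius - 1L)
      out[[length(out) + 1L]] <- child
    }
  }
  out
}

#' Write phantom ground-truth masks as raw binary
#'
#' Masks are written as packed 0/1 bytes with a JSON sidecar describing the
#' shape, next to the given prefix (`<prefix>_vessel.raw`, `<prefix>_body.raw`,
#' `<prefix>_masks.json`).
#'
#' @param truth the `truth` element returned by [generate_phantom()].
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
write_truth_masks <- function(truth, prefix) {
  vp <- paste0(prefix, "_vessel.raw"); bp <- paste0(prefix, "_body.raw")
  writeBin(as.raw(as.integer(truth$vessel_mask)), vp)
  writeBin(as.raw(as.integer(truth$body_mask)), bp)
  jp <- paste0(prefix, "_masks.json")
  jsonlite::write_json(list(shape = dim(truth$vessel_mask), dtype = "uint8 0/1"),
                       jp, auto_unbox = TRUE)
  invisible(c(vessel = vp, body = bp, json = jp))
}
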