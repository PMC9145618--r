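# Encode one slice's three regions and return regions plus the composed
# reconstruction (used both by the controllers, which need per-slice PSNR,
# and to avoid decoding twice).
encode_slice_regions <- function(slice, pslice, sroi_bpp, bpp_background,
                                 bpp_min, bpp_max) {
  shape <- dim(slice)
  r_proi <- encode_lossless(slice, pslice$proi, region_id = "PROI")
  r_sroi <- encode_lossy(slice, pslice$sroi, sroi_bpp,
                         bpp_min = bpp_min, bpp_max = bpp_max,
                         region_id = "SROI")
  r_bg <- encode_lossy(slice, pslice$background, bpp_background,
                       bpp_min = bpp_min, bpp_max = bpp_max,
                       region_id = "BACKGROUND")
  recon <- compose_slice(pslice,
                         decode_region(r_proi, shape),
                         decode_region(r_sroi, shape),
                         decode_region(r_bg, shape))
  list(regions = list(proi = r_proi, sroi = r_sroi, background = r_bg),
       recon = recon)
}

default_window <- function(volume) {
  w <- range(volume$pixels)
  if (w[2] == w[1]) w[2] <- w[1] + 1
  w
}

slice_psnr_windowed <- function(a, b, window, max_val = 255) {
  sc <- max_val / (window[2] - window[1])
  psnr_from_mse(mean(((as.double(a) - as.double(b)) * sc)^2), max_val)
}

new_compressed <- function(volume, partition, mode, threshold_db, window,
                           sroi_bpp, bpp_background, slices) {
  d <- dim(volume$pixels)
  structure(list(mode = mode,
                 threshold_db = threshold_db,
                 window = window,
                 n_slices = d[3], rows = d[1], cols = d[2],
                 bit_depth = 16L,
                 pixel_spacing = volume$pixel_spacing,
                 slice_thickness = volume$slice_thickness,
                 codec_ids = c(lossless = "rle-gzip16", lossy = "haar-gzip"),
                 sroi_bpp = sroi_bpp,
                 bpp_background = bpp_background,
                 has_partition = !is.null(partition),
                 slices = slices),
            class = "aroi_compressed")
}

#' @export
print.aroi_compressed <- function(x, ...) {
  cat(sprintf("<aroi_compressed> mode %s, %d slice(s) of %d x %d\n",
              x$mode, x$n_slices, x$rows, x$cols))
  if (x$has_partition)
    cat(sprintf("  SROI bpp: %s\n",
                paste(sprintf("%.3g", range(x$sroi_bpp)), collapse = " .. ")))
  invisible(x)
}

new_schedule <- function(sroi_bpp, threshold_db, mode, trace) {
  structure(list(sroi_bpp = sroi_bpp, threshold_db = threshold_db,
                 mode = mode, trace = trace),
            class = "aroi_schedule")
}

#' @export
print.aroi_schedule <- function(x, ...) {
  cat(sprintf("<aroi_schedule> mode %s, %d slice(s), threshold %g dB\n",
              x$mode, length(x$sroi_bpp), x$threshold_db))
  cat(sprintf("  rates %.3g .. %.3g bpp, %d drop-back(s)\n",
              min(x$sroi_bpp), max(x$sroi_bpp), sum(x$trace$retries)))
  invisible(x)
}

#' Variable-bit-rate ROI compression with a PSNR floor
#'
#' The adaptive controller behind the scheme's quality guarantee. For each
#' slice, the primary ROI is encoded losslessly, the background at
#' `bpp_background`, and the secondary ROI at a candidate rate equal to the
#' previous slice's final rate reduced by `step_down` (the controller always
#' tries to compress a little harder than it last succeeded at). The slice is
#' then reconstructed and its full-frame PSNR against the original computed;
#' while it falls below `threshold_db`, the SROI rate is doubled (capped at
#' `bpp_max`) and the slice re-encoded -- the "drop back". The resulting rate
#' trajectory is serrated: steady decay punctuated by jumps wherever image
#' content (e.g. noisy proximal anatomy) makes the floor bind. On return,
#' every slice's achieved PSNR is at least `threshold_db`; if even `bpp_max`
#' cannot reach the floor on some slice, an error names that slice.
#'
#' PSNR here is computed on display-windowed pixels with reference peak
#' `max_val` (see [quality_curve()]), using the original volume's stored
#' range as the window by default.
#'
#' @param volume an [aroi_volume()].
#' @param partition an `aroi_partition` matching the volume.
#' @param threshold_db minimum acceptable per-slice PSNR (dB); 40 dB is the
#'   conventional bar above which original and reconstruction are visually
#'   indistinguishable.
#' @param step_down multiplicative rate decrement per slice (default 10%).
#' @param initial_bpp SROI rate tried on the first slice.
#' @param bpp_min,bpp_max admissible SROI rate bounds.
#' @param bpp_background fixed background rate (heavy compression; the
#'   background is clinically void air).
#' @param max_val,window PSNR windowing convention (see [quality_curve()]).
#' @return list with elements `compressed` (an `aroi_compressed`) and
#'   `schedule` (an `aroi_schedule` whose `trace` records, per slice, the
#'   attempted rate, final rate, achieved PSNR and re-encode count).
#' @export
mvar_compress <- function(volume, partition, threshold_db = 40,
                          step_down = 0.10, initial_bpp = 2.0,
                          bpp_min = 0.05, bpp_max = 8.0,
                          bpp_background = 0.05,
                          max_val = 255, window = NULL) {
  assert_that(identical(dim(partition$proi), dim(volume$pixels)),
              "partition shape must match the volume")
  assert_that(threshold_db >= 0, "threshold_db must be non-negative")
  assert_that(step_down > 0 && step_down < 1, "step_down must lie in (0, 1)")
  if (is.null(window)) window <- default_window(volume)
  n <- n_slices(volume)
  slices <- vector("list", n)
  final_bpp <- numeric(n); attempted <- numeric(n)
  psnr_db <- numeric(n); retries <- integer(n)
  prev <- initial_bpp

  for (i in seq_len(n)) {
    sl <- volume_slice(volume, i)
    ps <- partition_slice(partition, i)
    bpp <- if (i == 1L) initial_bpp else max(bpp_min, prev * (1 - step_down))
    attempted[i] <- bpp
    enc <- encode_slice_regions(sl, ps, bpp, bpp_background, bpp_min, bpp_max)
    p <- slice_psnr_windowed(sl, enc$recon, window, max_val)
    k <- 0L
    while (p < threshold_db && bpp < bpp_max) {
      bpp <- min(bpp * 2, bpp_max)
      enc <- encode_slice_regions(sl, ps, bpp, bpp_background, bpp_min, bpp_max)
      p <- slice_psnr_windowed(sl, enc$recon, window, max_val)
      k <- k + 1L
    }
    if (p < threshold_db) {
      stop(sprintf(
        "PSNR floor %g dB unreachable at slice %d: %.2f dB at bpp_max = %g",
        threshold_db, i, p, bpp_max), call. = FALSE)
    }
    final_bpp[i] <- bpp; psnr_db[i] <- p; retries[i] <- k
    slices[[i]] <- list(proi_mask = ps$proi,
                        body_mask = ps$proi | ps$sroi,
                        regions = enc$regions)
    prev <- bpp
  }

  trace <- data.frame(slice = seq_len(n), attempted_bpp = attempted,
                      bpp = final_bpp, psnr_db = psnr_db, retries = retries)
  list(compressed = new_compressed(volume, partition, "MVAR", threshold_db,
                                   window, final_bpp, bpp_background, slices),
       schedule = new_schedule(final_bpp, threshold_db, "MVAR", trace))
}

#' Fixed rate derived from a variable-rate schedule
#'
#' The fixed-rate variant runs every slice at the arithmetic mean of the
#' rates the variable-rate controller chose on a first pass.
#'
#' @param schedule an `aroi_schedule` of mode `"MVAR"`.
#' @return the mean SROI rate (bits per pixel).
#' @export
mfix_rate <- function(schedule) {
  assert_that(inherits(schedule, "aroi_schedule") &&
                identical(schedule$mode, "MVAR"),
              "mfix_rate requires a schedule produced by mvar_compress()")
  assert_that(length(schedule$sroi_bpp) > 0, "schedule is empty")
  mean(schedule$sroi_bpp)
}

#' Fixed-bit-rate ROI compression
#'
#' Encodes every slice with a lossless primary ROI, the secondary ROI at one
#' fixed rate, and the background at `bpp_background`. Unlike
#' [mvar_compress()] there is no quality floor: slices whose content demands
#' more bits than the fixed rate provides (typically noisy proximal anatomy)
#' simply come out below 40 dB, which is precisely the failure mode the
#' variable-rate controller exists to prevent.
#'
#' @inheritParams mvar_compress
#' @param fixed_bpp the SROI rate applied to all slices (e.g. [mfix_rate()]).
#' @return list with `compressed` and `schedule` (mode `"MFIX"`, trace with
#'   achieved per-slice PSNR, zero retries).
#' @export
mfix_compress <- function(volume, partition, fixed_bpp,
                          bpp_min = 0.05, bpp_max = 8.0,
                          bpp_background = 0.05,
                          max_val = 255, window = NULL) {
  assert_that(identical(dim(partition$proi), dim(volume$pixels)),
              "partition shape must match the volume")
  if (fixed_bpp < bpp_min || fixed_bpp > bpp_max) {
    stop(sprintf("fixed_bpp %g outside the admissible range [%g, %g]",
                 fixed_bpp, bpp_min, bpp_max), call. = FALSE)
  }
  if (is.null(window)) window <- default_window(volume)
  n <- n_slices(volume)
  slices <- vector("list", n); psnr_db <- numeric(n)
  for (i in seq_len(n)) {
    sl <- volume_slice(volume, i)
    ps <- partition_slice(partition, i)
    enc <- encode_slice_regions(sl, ps, fixed_bpp, bpp_background,
                                bpp_min, bpp_max)
    psnr_db[i] <- slice_psnr_windowed(sl, enc$recon, window, max_val)
    slices[[i]] <- list(proi_mask = ps$proi,
                        body_mask = ps$proi | ps$sroi,
                        regions = enc$regions)
  }
  rates <- rep(fixed_bpp, n)
  trace <- data.frame(slice = seq_len(n), attempted_bpp = rates, bpp = rates,
                      psnr_db = psnr_db, retries = 0L)
  list(compressed = new_compressed(volume, partition, "MFIX", NA_real_,
                                   window, rates, bpp_background, slices),
       schedule = new_schedule(rates, NA_real_, "MFIX", trace))
}

#' Whole-frame lossy compression (no ROI)
#'
#' The no-ROI comparator: each slice is encoded as a single lossy region at
#' one fixed rate, with no partition and no lossless guarantee anywhere.
#'
#' @inheritParams mfix_compress
#' @return list with `compressed` (mode `"PLAIN"`) and `schedule`.
#' @export
plain_lossy_compress <- function(volume, fixed_bpp,
                                 bpp_min = 0.05, bpp_max = 8.0,
                                 max_val = 255, window = NULL) {
  if (fixed_bpp < bpp_min || fixed_bpp > bpp_max) {
    stop(sprintf("fixed_bpp %g outside the admissible range [%g, %g]",
                 fixed_bpp, bpp_min, bpp_max), call. = FALSE)
  }
  if (is.null(window)) window <- default_window(volume)
  n <- n_slices(volume)
  d <- dim(volume$pixels)
  full <- matrix(TRUE, d[1], d[2])
  slices <- vector("list", n); psnr_db <- numeric(n)
  for (i in seq_len(n)) {
    sl <- volume_slice(volume, i)
    reg <- encode_lossy(sl, full, fixed_bpp, bpp_min = bpp_min,
                        bpp_max = bpp_max, region_id = "FULL")
    psnr_db[i] <- slice_psnr_windowed(sl, decode_region(reg, d[1:2]),
                                      window, max_val)
    slices[[i]] <- list(regions = list(full = reg))
  }
  rates <- rep(fixed_bpp, n)
  trace <- data.frame(slice = seq_len(n), attempted_bpp = rates, bpp = rates,
                      psnr_db = psnr_db, retries = 0L)
  list(compressed = new_compressed(volume, NULL, "PLAIN", NA_real_,
                                   window, rates, NA_real_, slices),
       schedule = new_schedule(rates, NA_real_, "PLAIN", trace))
}

#' Whole-frame lossless compression baseline
#'
#' Compresses each slice bit-exactly as a single region; the size-reduction
#' baseline that stands in for conventional lossless coders in comparative
#' reports.
#'
#' @param volume an [aroi_volume()].
#' @return list with `compressed` (mode `"LOSSLESS"`) and `schedule`.
#' @export
lossless_baseline_compress <- function(volume) {
  n <- n_slices(volume)
  d <- dim(volume$pixels)
  full <- matrix(TRUE, d[1], d[2])
  slices <- vector("list", n)
  for (i in seq_len(n)) {
    slices[[i]] <- list(regions = list(
      full = encode_lossless(volume_slice(volume, i), full, region_id = "FULL")))
  }
  rates <- rep(NA_real_, n)
  trace <- data.frame(slice = seq_len(n), attempted_bpp = rates, bpp = rates,
                      psnr_db = Inf, retries = 0L)
  list(compressed = new_compressed(volume, NULL, "LOSSLESS", NA_real_,
                                   default_window(volume), rates, NA_real_,
                                   slices),
       schedule = new_schedule(rates, NA_real_, "LOSSLESS", trace))
}

#' Export a rate schedule as CSV
#'
#' @param schedule an `aroi_schedule`.
#' @param path output CSV path (columns slice, attempted_bpp, bpp, psnr_db,
#'   retries).
#' @return invisibly, `path`.
#' @export
write_schedule_csv <- function(schedule, path) {
  utils::write.csv(schedule$trace, path, row.names = FALSE)
  invisible(path)
}
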