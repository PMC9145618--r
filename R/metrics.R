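#' Mean squared error between two arrays
#'
#' @param a,b numeric or integer arrays of identical shape.
#' @return mean over pixels of the squared difference, accumulated in double
#'   precision.
#' @export
mse <- function(a, b) {
  assert_that(identical(dim(a), dim(b)) && length(a) == length(b),
              "arrays must have identical shapes")
  mean((as.double(a) - as.double(b))^2)
}

#' PSNR from an MSE value
#'
#' `10 * log10(max_val^2 / mse)`. An MSE of exactly zero (bit-identical
#' images) returns `Inf`, rendered as an unbounded ("infinite") PSNR in
#' reports.
#'
#' @param mse non-negative mean squared error.
#' @param max_val reference peak. The default 255 follows the display-window
#'   convention: pixel data are windowed to an 8-bit range before metric
#'   computation (see [quality_curve()]), which is also the convention the
#'   published per-slice CTA reference measurements shipped in
#'   `inst/extdata/` satisfy. Set to 65535 for metrics on raw stored values.
#' @return PSNR in dB.
#' @export
psnr_from_mse <- function(mse, max_val = 255) {
  assert_that(is.numeric(mse) && all(mse >= 0), "mse must be non-negative")
  assert_that(max_val > 0, "max_val must be positive")
  ifelse(mse == 0, Inf, 10 * log10(max_val^2 / mse))
}

#' PSNR between two arrays
#' @inheritParams mse
#' @inheritParams psnr_from_mse
#' @return PSNR in dB.
#' @export
psnr <- function(a, b, max_val = 255) psnr_from_mse(mse(a, b), max_val)

#' Compression ratio
#'
#' @param original_kb,compressed_kb positive sizes (any common unit).
#' @return the numeric ratio `original / compressed`.
#' @export
compression_ratio <- function(original_kb, compressed_kb) {
  assert_that(all(original_kb > 0), "original size must be positive")
  assert_that(all(compressed_kb > 0), "compressed size must be zero-free and positive")
  original_kb / compressed_kb
}

#' Format a compression ratio as "N:1"
#'
#' Ratios within 1% (relative) of an integer are displayed as that integer
#' ("9:1" for 9.07); otherwise one decimal is shown, with a trailing ".0"
#' dropped ("3.5:1", "3:1" for 3.006).
#'
#' @param ratio numeric ratio from [compression_ratio()].
#' @return character.
#' @export
format_compression_ratio <- function(ratio) {
  vapply(ratio, function(r) {
    n <- round(r)
    val <- if (n > 0 && abs(r - n) <= 0.01 * r) n else round(r, 1)
    if (val == round(val)) sprintf("%d:1", as.integer(round(val)))
    else sprintf("%.1f:1", val)
  }, character(1))
}

#' Percentage size reduction against a baseline
#'
#' @param reference_kb,compressed_kb positive sizes.
#' @param digits rounding for display (default integer percent, matching
#'   common reporting practice).
#' @return percentage `100 * (1 - compressed / reference)`, rounded.
#' @export
percent_reduction <- function(reference_kb, compressed_kb, digits = 0) {
  assert_that(all(reference_kb > 0) && all(compressed_kb > 0),
              "sizes must be positive")
  round(100 * (1 - compressed_kb / reference_kb), digits)
}

#' Per-slice quality curve of a reconstruction
#'
#' Computes per-slice MSE and PSNR between an original volume and its
#' reconstruction. Both volumes are first windowed linearly to the 8-bit
#' display range: `scaled = (stored - window[1]) * 255 / (window[2] -
#' window[1])` (no rounding), and PSNR uses `max_val = 255` on that scale.
#' The default window is the stored-value range of the original volume, and
#' the window used is recorded in the report. The same windowing drives the
#' rate controller's PSNR floor, so post-hoc curves computed here are
#' directly comparable with controller traces.
#'
#' @param original,reconstructed [aroi_volume()]s of identical shape.
#' @param max_val reference peak after windowing (default 255).
#' @param window numeric length-2 stored-value window, or `NULL` for the
#'   original volume's range.
#' @param mode label carried into the report (e.g. `"MVAR"`).
#' @return an `aroi_quality` list: `slice_mse`, `slice_psnr_db`, `avg_mse`,
#'   `min_psnr_db`, `window`, `max_val`, `mode`. Per-slice PSNR and MSE
#'   always satisfy `psnr == psnr_from_mse(mse, max_val)` exactly (they are
#'   cross-checked to 1e-9 dB at construction).
#' @export
quality_curve <- function(original, reconstructed, max_val = 255,
                          window = NULL, mode = "") {
  a <- original$pixels; b <- reconstructed$pixels
  assert_that(identical(dim(a), dim(b)), "volumes must have identical shapes")
  if (is.null(window)) window <- range(a)
  assert_that(window[2] > window[1], "window must have positive width")
  sc <- max_val / (window[2] - window[1])
  n <- dim(a)[3]
  slice_mse <- vapply(seq_len(n), function(i)
    mean(((as.double(a[, , i]) - as.double(b[, , i])) * sc)^2), numeric(1))
  slice_psnr <- psnr_from_mse(slice_mse, max_val)
  finite <- is.finite(slice_psnr)
  if (any(finite)) {
    chk <- abs(slice_psnr[finite] - psnr_from_mse(slice_mse[finite], max_val))
    assert_that(all(chk < 1e-9), "internal PSNR/MSE cross-check failed")
  }
  structure(list(slice_mse = slice_mse,
                 slice_psnr_db = slice_psnr,
                 avg_mse = mean(slice_mse),
                 min_psnr_db = min(slice_psnr),
                 window = as.numeric(window),
                 max_val = max_val,
                 mode = mode),
            class = "aroi_quality")
}

#' @export
print.aroi_quality <- function(x, ...) {
  fmt_db <- function(v) if (is.finite(v)) sprintf("%.2f dB", v) else "∞ dB"
  cat(sprintf("<aroi_quality>%s %d slice(s)\n",
              if (nzchar(x$mode)) paste0(" [", x$mode, "]") else "",
              length(x$slice_mse)))
  cat(sprintf("  avg MSE %.2f, min PSNR %s (window [%g, %g], peak %g)\n",
              x$avg_mse, fmt_db(x$min_psnr_db), x$window[1], x$window[2],
              x$max_val))
  invisible(x)
}

#' @export
as.data.frame.aroi_quality <- function(x, ...) {
  data.frame(slice = seq_along(x$slice_mse),
             mse = x$slice_mse,
             psnr_db = x$slice_psnr_db)
}

#' Size summary for a compressed volume
#'
#' Converts a container byte count into the per-slice size, compression
#' ratio, and percent-reduction figures used in size-reduction reports.
#' Sizes use kB = 1024 bytes; the uncompressed reference slice is
#' `rows * cols * 2` bytes (16-bit storage), i.e. 512 kB for a 512x512
#' slice and 128 kB for 256x256.
#'
#' @param total_bytes container size in bytes (e.g. the return value of
#'   [write_container()]).
#' @param n_slices,rows,cols volume geometry.
#' @param baseline_kb optional per-slice size of a named baseline (e.g. a
#'   lossless whole-frame compression) against which an additional percent
#'   reduction is reported.
#' @param mode label.
#' @return an `aroi_size_summary` list: `avg_slice_kb`, `original_slice_kb`,
#'   `cr` (numeric), `cr_label` ("N:1"), `reduction_vs_original_pct`, and,
#'   when `baseline_kb` is given, `reduction_vs_baseline_pct`.
#' @export
size_summary <- function(total_bytes, n_slices, rows, cols,
                         baseline_kb = NULL, mode = "") {
  avg_kb <- total_bytes / n_slices / 1024
  orig_kb <- rows * cols * 2 / 1024
  out <- list(avg_slice_kb = avg_kb,
              original_slice_kb = orig_kb,
              cr = compression_ratio(orig_kb, avg_kb),
              cr_label = format_compression_ratio(compression_ratio(orig_kb, avg_kb)),
              reduction_vs_original_pct = percent_reduction(orig_kb, avg_kb),
              mode = mode)
  if (!is.null(baseline_kb)) {
    out$baseline_kb <- baseline_kb
    out$reduction_vs_baseline_pct <- percent_reduction(baseline_kb, avg_kb)
  }
  structure(out, class = "aroi_size_summary")
}

#' @export
print.aroi_size_summary <- function(x, ...) {
  cat(sprintf("<aroi_size_summary>%s\n",
              if (nzchar(x$mode)) paste0(" [", x$mode, "]") else ""))
  cat(sprintf("  avg slice %.2f kB (original %.0f kB), CR %s, reduction %d%% vs original\n",
              x$avg_slice_kb, x$original_slice_kb, x$cr_label,
              as.integer(x$reduction_vs_original_pct)))
  if (!is.null(x$baseline_kb)) {
    cat(sprintf("  reduction vs baseline (%.2f kB): %d%%\n",
                x$baseline_kb, as.integer(x$reduction_vs_baseline_pct)))
  }
  invisible(x)
}

#' Write a quality report as CSV and JSON
#'
#' @param quality an `aroi_quality`.
#' @param prefix output path prefix; writes `<prefix>.csv` (per-slice table)
#'   and `<prefix>.json` (per-slice arrays plus summary).
#' @param size optional `aroi_size_summary` merged into the JSON.
#' @return invisibly, the paths written.
#' @export
write_quality_report <- function(quality, prefix, size = NULL) {
  csv <- paste0(prefix, ".csv"); js <- paste0(prefix, ".json")
  utils::write.csv(as.data.frame(quality), csv, row.names = FALSE)
  payload <- list(mode = quality$mode,
                  window = quality$window,
                  max_val = quality$max_val,
                  avg_mse = quality$avg_mse,
                  min_psnr_db = if (is.finite(quality$min_psnr_db))
                    quality$min_psnr_db else "Inf",
                  slice_mse = quality$slice_mse,
                  slice_psnr_db = ifelse(is.finite(quality$slice_psnr_db),
                                         quality$slice_psnr_db, "Inf"))
  if (!is.null(size)) payload$size <- unclass(size)
  jsonlite::write_json(payload, js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, json = js))
}
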