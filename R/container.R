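# ---- binary mask run-length coding ----------------------------------------
# Row-major runs with 16-bit counts, alternating values starting with the
# count of zeros. Runs longer than 65535 are continued by inserting a
# zero-length run of the opposite value. Layout:
# [u16 rows][u16 cols][u32 n_runs][u16 run ...]

rle_mask_encode <- function(mask) {
  v <- as.integer(t(mask))
  r <- rle(v)
  lens <- r$lengths; vals <- r$values
  if (length(vals) > 0 && vals[1] == 1L) {
    lens <- c(0L, lens); vals <- c(0L, vals)
  }
  out <- integer(0)
  for (L in lens) {
    while (L > 65535L) {
      out <- c(out, 65535L, 0L)
      L <- L - 65535L
    }
    out <- c(out, L)
  }
  c(u16_pack(c(nrow(mask), ncol(mask))), u32_pack(length(out)), u16_pack(out))
}

rle_mask_decode <- function(bytes) {
  dims <- u16_unpack(bytes[1:4], 2L)
  n_runs <- u32_unpack(bytes[5:8], 1L)
  assert_that(length(bytes) >= 8L + 2L * n_runs, "truncated mask RLE")
  runs <- u16_unpack(bytes[8L + seq_len(2L * n_runs)], n_runs)
  vals <- rep_len(c(0L, 1L), n_runs)
  v <- inverse.rle(list(lengths = runs, values = vals))
  assert_that(length(v) == prod(dims), "mask RLE length mismatch")
  matrix(v, nrow = dims[1], byrow = TRUE) == 1L
}

# ---- container -------------------------------------------------------------
# .aroi layout (little-endian throughout):
#   "AROI" | u8 version | u32 json_len | header JSON |
#   per slice: [masks if partitioned] [region records] |
#   u8 n_totals | f64 totals ... | "ENDA"
# Region record: u8 region code | u8 mode code | u32 n_region_pixels |
#   u32 codestream length | codestream bytes.
# Mask block: u32 RLE length | RLE bytes (PROI, then body = PROI union SROI;
# SROI and background are derived as body\PROI and the complement).

region_code <- c(PROI = 1L, SROI = 2L, BACKGROUND = 3L, FULL = 4L)

serialize_region <- function(reg) {
  c(as.raw(region_code[[reg$region_id]]),
    as.raw(if (reg$codec$mode == "lossless") 1L else 2L),
    u32_pack(reg$n_region_pixels),
    u32_pack(reg$byte_length),
    reg$codestream)
}

#' Write a compressed volume to an `.aroi` container
#'
#' Serialises the header metadata (geometry, mode, PSNR window, per-slice
#' SROI rates), the run-length-encoded PROI/body masks, every region
#' codestream, and a self-consistency footer holding per-region byte totals.
#' Mask overhead is therefore charged to the reported compressed size.
#'
#' @param compressed an `aroi_compressed` (from [mvar_compress()] and
#'   friends).
#' @param path output file path.
#' @return the container size in bytes (equal to the file size on disk).
#' @export
write_container <- function(compressed, path) {
  x <- compressed
  header <- list(format = "AROI", version = 1L,
                 mode = x$mode,
                 threshold_db = if (is.na(x$threshold_db)) NULL else x$threshold_db,
                 window = x$window,
                 n_slices = x$n_slices, rows = x$rows, cols = x$cols,
                 bit_depth = x$bit_depth,
                 pixel_spacing = x$pixel_spacing,
                 slice_thickness = x$slice_thickness,
                 codec_ids = as.list(x$codec_ids),
                 sroi_bpp = x$sroi_bpp,
                 bpp_background = x$bpp_background,
                 has_partition = x$has_partition)
  hjson <- charToRaw(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA,
                                      null = "null"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("AROI"), con)
  writeBin(as.raw(1L), con)
  writeBin(u32_pack(length(hjson)), con)
  writeBin(hjson, con)

  totals <- numeric(0)
  for (sl in x$slices) {
    if (x$has_partition) {
      for (m in list(sl$proi_mask, sl$body_mask)) {
        rle <- rle_mask_encode(m)
        writeBin(u32_pack(length(rle)), con)
        writeBin(rle, con)
      }
    }
    for (reg in sl$regions) {
      rec <- serialize_region(reg)
      writeBin(rec, con)
      nm <- reg$region_id
      totals[nm] <- (if (nm %in% names(totals)) totals[nm] else 0) +
        reg$byte_length
    }
  }
  writeBin(as.raw(length(totals)), con)
  writeBin(as.numeric(totals), con, size = 8L, endian = "little")
  writeBin(charToRaw("ENDA"), con)
  close(con)
  on.exit(NULL)
  file.size(path)
}

read_region_record <- function(con, sroi_bpp, bpp_background) {
  code <- as.integer(read_exact(con, 1L, "region code"))
  mode_code <- as.integer(read_exact(con, 1L, "codec mode"))
  n_px <- u32_unpack(read_exact(con, 4L, "region pixel count"), 1L)
  len <- u32_unpack(read_exact(con, 4L, "codestream length"), 1L)
  cs <- read_exact(con, len, "codestream")
  rid <- names(region_code)[match(code, region_code)]
  assert_that(!is.na(rid), "unknown region code in container")
  bpp <- switch(rid, SROI = sroi_bpp, BACKGROUND = bpp_background, NULL)
  spec <- if (mode_code == 1L) codec_spec(mode = "lossless")
          else codec_spec(mode = "lossy", bpp = max(bpp %||% 0.05, 0.05))
  new_region(cs, spec, rid, n_px)
}

#' Read an `.aroi` container
#'
#' Validates the magic bytes, format version, and the footer's per-region
#' byte totals against the actual codestream lengths; a truncated or
#' tampered file raises an integrity error.
#'
#' @param path container path.
#' @return an `aroi_compressed`.
#' @export
read_container <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(read_exact(con, 4L, "magic"))
  assert_that(identical(magic, "AROI"),
              sprintf("not an AROI container (magic '%s')", magic))
  version <- as.integer(read_exact(con, 1L, "version"))
  assert_that(version == 1L, sprintf("unsupported container version %d", version))
  hlen <- u32_unpack(read_exact(con, 4L, "header length"), 1L)
  header <- jsonlite::fromJSON(rawToChar(read_exact(con, hlen, "header")))

  n <- header$n_slices
  slices <- vector("list", n)
  totals_seen <- numeric(0)
  for (i in seq_len(n)) {
    sl <- list()
    if (isTRUE(header$has_partition)) {
      masks <- lapply(1:2, function(k) {
        mlen <- u32_unpack(read_exact(con, 4L, "mask length"), 1L)
        rle_mask_decode(read_exact(con, mlen, "mask RLE"))
      })
      sl$proi_mask <- masks[[1]]; sl$body_mask <- masks[[2]]
      regs <- lapply(1:3, function(k)
        read_region_record(con, header$sroi_bpp[i], header$bpp_background))
      names(regs) <- vapply(regs, `[[`, "", "region_id")
      sl$regions <- list(proi = regs[["PROI"]], sroi = regs[["SROI"]],
                         background = regs[["BACKGROUND"]])
    } else {
      sl$regions <- list(full = read_region_record(con, NA, NA))
    }
    for (reg in sl$regions) {
      nm <- reg$region_id
      totals_seen[nm] <- (if (nm %in% names(totals_seen)) totals_seen[nm] else 0) +
        reg$byte_length
    }
    slices[[i]] <- sl
  }
  n_tot <- as.integer(read_exact(con, 1L, "footer count"))
  totals <- readBin(read_exact(con, 8L * n_tot, "footer totals"), "double",
                    n = n_tot, endian = "little")
  tail_magic <- rawToChar(read_exact(con, 4L, "footer magic"))
  assert_that(identical(tail_magic, "ENDA"), "corrupted footer")
  assert_that(isTRUE(all.equal(sort(unname(totals_seen)), sort(totals))),
              "integrity error: footer byte totals do not match codestreams")
  extra <- readBin(con, "raw", n = 1L)
  assert_that(length(extra) == 0L, "trailing bytes after footer")

  vol_stub <- list(pixels = array(0L, dim = c(header$rows, header$cols, n)),
                   pixel_spacing = header$pixel_spacing,
                   slice_thickness = header$slice_thickness)
  out <- new_compressed(structure(vol_stub, class = "aroi_volume"),
                        if (isTRUE(header$has_partition)) TRUE else NULL,
                        header$mode,
                        header$threshold_db %||% NA_real_,
                        header$window, header$sroi_bpp,
                        header$bpp_background %||% NA_real_, slices)
  out$has_partition <- isTRUE(header$has_partition)
  out
}

#' Reconstruct a volume from a compressed representation
#'
#' Decodes every region codestream and reassembles each slice via
#' [compose_slice()]. Primary-ROI pixels are bit-exact copies of the
#' original for every partitioned mode; the output carries the geometry
#' metadata stored in the container header.
#'
#' @param compressed an `aroi_compressed`, in-memory or from
#'   [read_container()].
#' @return an [aroi_volume()].
#' @export
decompress <- function(compressed) {
  x <- compressed
  shape <- c(x$rows, x$cols)
  px <- array(0L, dim = c(x$rows, x$cols, x$n_slices))
  for (i in seq_len(x$n_slices)) {
    sl <- x$slices[[i]]
    if (x$has_partition) {
      proi <- sl$proi_mask
      sroi <- sl$body_mask & !proi
      background <- !(sl$body_mask | proi)
      ps <- list(proi = proi, sroi = sroi, background = background)
      px[, , i] <- compose_slice(ps,
                                 decode_region(sl$regions$proi, shape),
                                 decode_region(sl$regions$sroi, shape),
                                 decode_region(sl$regions$background, shape))
    } else {
      px[, , i] <- decode_region(sl$regions$full, shape)
    }
  }
  aroi_volume(px, pixel_spacing = x$pixel_spacing,
              slice_thickness = x$slice_thickness)
}

#' Total codestream bytes per region
#'
#' Sums the per-slice codestream lengths by region; useful for size
#' accounting next to [size_summary()].
#'
#' @param compressed an `aroi_compressed`.
#' @return named numeric vector of byte totals.
#' @export
region_byte_totals <- function(compressed) {
  totals <- numeric(0)
  for (sl in compressed$slices) {
    for (reg in sl$regions) {
      nm <- reg$region_id
      totals[nm] <- (if (nm %in% names(totals)) totals[nm] else 0) +
        reg$byte_length
    }
  }
  totals
}
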