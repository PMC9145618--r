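# Minimal single-frame CT DICOM writer/reader, Part-10 files with the
# Explicit VR Little Endian transfer syntax only (1.2.840.10008.1.2.1).
# This deliberately covers just the uncompressed 16-bit monochrome subset the
# compression pipeline needs; encapsulated transfer syntaxes are out of scope.

UID_TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_SOP_CT <- "1.2.840.10008.5.1.4.1.1.2"
UID_IMPL_ROOT <- "1.2.826.0.1.3680043.10.2048"

dcm_long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

dcm_pad <- function(bytes, pad) {
  if (length(bytes) %% 2L == 1L) c(bytes, pad) else bytes
}

dcm_element <- function(group, elem, vr, value_bytes) {
  pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
  v <- dcm_pad(value_bytes, pad)
  head <- c(u16_pack(c(group, elem)), charToRaw(vr))
  if (vr %in% dcm_long_vrs) {
    c(head, raw(2L), u32_pack(length(v)), v)
  } else {
    assert_that(length(v) <= 65534L, "value too long for short-form VR")
    c(head, u16_pack(length(v)), v)
  }
}

dcm_str <- function(group, elem, vr, s) dcm_element(group, elem, vr, charToRaw(s))
dcm_us <- function(group, elem, x) dcm_element(group, elem, "US", u16_pack(x))

dcm_format_ds <- function(x) {
  # DS allows at most 16 bytes per value
  paste(vapply(x, function(v) formatC(v, format = "fg", digits = 10),
               character(1)), collapse = "\\")
}

#' Write a volume as a DICOM series
#'
#' One Part-10 file per slice (Explicit VR Little Endian, 16-bit
#' MONOCHROME2), named `IM000001.dcm` onward in slice order. Slice positions
#' advance along z by the volume's slice thickness; SOP instance UIDs are
#' derived deterministically from the pixel content and slice index, so
#' rewriting the same volume is byte-identical.
#'
#' @param volume an [aroi_volume()].
#' @param directory output directory (created if missing).
#' @return invisibly, the file paths written.
#' @export
write_dicom_series <- function(volume, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  d <- dim(volume$pixels)
  series_tag <- (sum(as.double(volume$pixels[, , 1])) + 131 * d[3] +
                   17 * d[1] + d[2]) %% 2^31
  series_uid <- sprintf("%s.1.%.0f", UID_IMPL_ROOT, series_tag)
  paths <- character(d[3])
  for (i in seq_len(d[3])) {
    sop_uid <- sprintf("%s.2.%.0f.%d", UID_IMPL_ROOT, series_tag, i)
    z <- (i - 1) * volume$slice_thickness

    meta <- c(
      dcm_element(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
      dcm_str(0x0002, 0x0002, "UI", UID_SOP_CT),
      dcm_str(0x0002, 0x0003, "UI", sop_uid),
      dcm_str(0x0002, 0x0010, "UI", UID_TS_EXPLICIT_LE),
      dcm_str(0x0002, 0x0012, "UI", paste0(UID_IMPL_ROOT, ".0.1"))
    )
    meta <- c(dcm_element(0x0002, 0x0000, "UL", u32_pack(length(meta))), meta)

    pixel_bytes <- u16_pack(as.vector(t(volume$pixels[, , i])))
    body <- c(
      dcm_str(0x0008, 0x0016, "UI", UID_SOP_CT),
      dcm_str(0x0008, 0x0018, "UI", sop_uid),
      dcm_str(0x0008, 0x0060, "CS", "CT"),
      dcm_str(0x0018, 0x0050, "DS", dcm_format_ds(volume$slice_thickness)),
      dcm_str(0x0020, 0x000e, "UI", series_uid),
      dcm_str(0x0020, 0x0013, "IS", as.character(i)),
      dcm_str(0x0020, 0x0032, "DS", dcm_format_ds(c(0, 0, z))),
      dcm_us(0x0028, 0x0002, 1L),
      dcm_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
      dcm_us(0x0028, 0x0010, d[1]),
      dcm_us(0x0028, 0x0011, d[2]),
      dcm_str(0x0028, 0x0030, "DS", dcm_format_ds(volume$pixel_spacing)),
      dcm_us(0x0028, 0x0100, 16L),
      dcm_us(0x0028, 0x0101, 16L),
      dcm_us(0x0028, 0x0102, 15L),
      dcm_us(0x0028, 0x0103, 0L),
      dcm_str(0x0028, 0x1052, "DS", dcm_format_ds(volume$rescale_intercept)),
      dcm_str(0x0028, 0x1053, "DS", dcm_format_ds(volume$rescale_slope)),
      dcm_element(0x7fe0, 0x0010, "OW", pixel_bytes)
    )

    paths[i] <- file.path(directory, sprintf("IM%06d.dcm", i))
    con <- file(paths[i], "wb")
    writeBin(c(raw(128L), charToRaw("DICM"), meta, body), con)
    close(con)
  }
  invisible(paths)
}

# Parse one explicit-VR-LE Part-10 file, returning the tags of interest.
dcm_parse_file <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  assert_that(length(bytes) > 132L &&
                identical(rawToChar(bytes[129:132]), "DICM"),
              sprintf("%s: not a Part-10 DICOM file", path))
  pos <- 133L
  tags <- list()
  while (pos + 7L <= length(bytes)) {
    ge <- u16_unpack(bytes[pos:(pos + 3L)], 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    assert_that(grepl("^[A-Z]{2}$", vr),
                sprintf("%s: unsupported (implicit VR?) element at byte %d",
                        path, pos))
    if (vr %in% dcm_long_vrs) {
      len <- u32_unpack(bytes[(pos + 8L):(pos + 11L)], 1L)
      vstart <- pos + 12L
    } else {
      len <- u16_unpack(bytes[(pos + 6L):(pos + 7L)], 1L)
      vstart <- pos + 8L
    }
    assert_that(vstart + len - 1L <= length(bytes),
                sprintf("%s: truncated element (%04x,%04x)", path, ge[1], ge[2]))
    key <- sprintf("%04x%04x", ge[1], ge[2])
    tags[[key]] <- list(vr = vr,
                        value = if (len > 0) bytes[vstart:(vstart + len - 1L)]
                                else raw(0))
    pos <- vstart + len
    if (key == "7fe00010") break
  }
  tags
}

dcm_tag_str <- function(tags, key) {
  t <- tags[[key]]
  if (is.null(t)) return(NA_character_)
  trimws(rawToChar(t$value[t$value != as.raw(0L)]))
}

dcm_tag_us <- function(tags, key) {
  t <- tags[[key]]
  if (is.null(t)) return(NA_integer_)
  u16_unpack(t$value, 1L)
}

#' Read a DICOM series into a volume
#'
#' Reads every `.dcm` file in a directory (uncompressed Explicit VR Little
#' Endian, single-frame, 16-bit), sorts slices by instance number (falling
#' back to the z image position when instance numbers are absent), and
#' returns the stored pixel values untouched -- no rescale is applied on the
#' compression path. Slice order is therefore independent of file naming.
#'
#' @param directory directory containing the series.
#' @return an [aroi_volume()] with spacing metadata from the headers.
#' @export
read_dicom_series <- function(directory) {
  files <- list.files(directory, pattern = "\\.dcm$", full.names = TRUE)
  assert_that(length(files) > 0,
              sprintf("no .dcm files found in %s", directory))
  parsed <- lapply(files, dcm_parse_file)

  rows <- vapply(parsed, dcm_tag_us, integer(1), key = "00280010")
  cols <- vapply(parsed, dcm_tag_us, integer(1), key = "00280011")
  assert_that(!anyNA(rows) && !anyNA(cols), "missing Rows/Columns tag")
  if (length(unique(rows)) > 1L || length(unique(cols)) > 1L) {
    ur <- rows[1]; uc <- cols[1]
    bad <- basename(files)[rows != ur | cols != uc]
    stop(sprintf("mixed slice shapes in series: %s differ from %d x %d",
                 paste(bad, collapse = ", "), ur, uc), call. = FALSE)
  }

  inst <- suppressWarnings(as.integer(
    vapply(parsed, dcm_tag_str, character(1), key = "00200013")))
  zpos <- vapply(parsed, function(t) {
    s <- dcm_tag_str(t, "00200032")
    if (is.na(s)) NA_real_ else as.numeric(strsplit(s, "\\\\")[[1]][3])
  }, numeric(1))
  ord <- if (!anyNA(inst) && !anyDuplicated(inst)) order(inst)
         else if (!anyNA(zpos)) order(zpos)
         else seq_along(files)
  parsed <- parsed[ord]

  nr <- rows[1]; nc <- cols[1]; n <- length(parsed)
  px <- array(0L, dim = c(nr, nc, n))
  for (i in seq_len(n)) {
    pd <- parsed[[i]][["7fe00010"]]
    assert_that(!is.null(pd) && length(pd$value) == 2L * nr * nc,
                sprintf("pixel data missing or wrong length in slice %d", i))
    px[, , i] <- t(matrix(u16_unpack(pd$value), nrow = nc, ncol = nr))
  }

  spacing_s <- dcm_tag_str(parsed[[1]], "00280030")
  spacing <- if (is.na(spacing_s)) c(0.7, 0.7)
             else as.numeric(strsplit(spacing_s, "\\\\")[[1]])
  thick_s <- dcm_tag_str(parsed[[1]], "00180050")
  slope_s <- dcm_tag_str(parsed[[1]], "00281053")
  inter_s <- dcm_tag_str(parsed[[1]], "00281052")
  aroi_volume(px,
              pixel_spacing = spacing,
              slice_thickness = if (is.na(thick_s)) 1.25 else as.numeric(thick_s),
              rescale_slope = if (is.na(slope_s)) 1 else as.numeric(slope_s),
              rescale_intercept = if (is.na(inter_s)) 0 else as.numeric(inter_s))
}
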