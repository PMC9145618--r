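test_that("mask run-length coding round-trips arbitrary masks", {
  masks <- list(
    matrix(FALSE, 7, 9),
    matrix(TRUE, 7, 9),
    matrix(TRUE, 300, 300),               # run length > 65535, continuation
    outer(1:33, 1:17, function(i, j) (i * j) %% 3 == 0)
  )
  set.seed(42)
  for (p in c(0.1, 0.5, 0.9)) {
    masks[[length(masks) + 1]] <- matrix(runif(40 * 25) < p, 40, 25)
  }
  for (m in masks) {
    expect_identical(aroi:::rle_mask_decode(aroi:::rle_mask_encode(m)), m)
  }
})

test_that("container write-then-read is the identity on all fields", {
  ph <- generate_phantom(phantom_config(n_slices = 4, slice_shape = c(64, 64),
                                        seed = 5))
  part <- segment_volume(ph$volume)
  res <- mvar_compress(ph$volume, part)
  path <- file.path(withr::local_tempdir(), "vol.aroi")
  bytes <- write_container(res$compressed, path)
  expect_equal(bytes, file.size(path))
  back <- read_container(path)
  expect_identical(back$mode, "MVAR")
  expect_equal(back$threshold_db, 40)
  expect_equal(back$window, res$compressed$window)
  expect_equal(back$sroi_bpp, res$compressed$sroi_bpp)
  expect_equal(back$pixel_spacing, res$compressed$pixel_spacing)
  for (i in 1:4) {
    a <- res$compressed$slices[[i]]; b <- back$slices[[i]]
    expect_identical(b$proi_mask, a$proi_mask)
    expect_identical(b$body_mask, a$body_mask)
    for (r in c("proi", "sroi", "background")) {
      expect_identical(b$regions[[r]]$codestream, a$regions[[r]]$codestream)
      expect_identical(b$regions[[r]]$n_region_pixels,
                       a$regions[[r]]$n_region_pixels)
    }
  }
  # and the round-tripped container decompresses identically
  expect_identical(decompress(back)$pixels, decompress(res$compressed)$pixels)
})

test_that("container size equals independent structural byte accounting", {
  ph <- generate_phantom(phantom_config(n_slices = 3, slice_shape = c(48, 48),
                                        seed = 6))
  res <- mfix_compress(ph$volume, segment_volume(ph$volume), 0.8)
  path <- file.path(withr::local_tempdir(), "vol.aroi")
  bytes <- write_container(res$compressed, path)

  # independent walk of the on-disk structure
  con <- file(path, "rb")
  on.exit(close(con))
  expect_identical(rawToChar(readBin(con, "raw", 4)), "AROI")
  readBin(con, "raw", 1)                      # version
  hlen <- aroi:::u32_unpack(readBin(con, "raw", 4), 1)
  readBin(con, "raw", hlen)                   # header JSON
  acc <- 4 + 1 + 4 + hlen
  for (i in 1:3) {
    for (k in 1:2) {                          # two masks
      mlen <- aroi:::u32_unpack(readBin(con, "raw", 4), 1)
      readBin(con, "raw", mlen)
      acc <- acc + 4 + mlen
    }
    for (k in 1:3) {                          # three region records
      readBin(con, "raw", 2)                  # region + mode codes
      readBin(con, "raw", 4)                  # n pixels
      clen <- aroi:::u32_unpack(readBin(con, "raw", 4), 1)
      readBin(con, "raw", clen)
      acc <- acc + 2 + 4 + 4 + clen
    }
  }
  ntot <- as.integer(readBin(con, "raw", 1))
  acc <- acc + 1 + 8 * ntot + 4               # footer
  expect_equal(acc, bytes)
  # codestream totals also match the region accounting
  expect_equal(sum(aroi:::region_byte_totals(res$compressed)),
               sum(vapply(res$compressed$slices, function(s)
                 sum(vapply(s$regions, `[[`, 0L, "byte_length")), 0)))
})

test_that("truncated or corrupted containers raise integrity errors", {
  ph <- generate_phantom(phantom_config(n_slices = 2, slice_shape = c(32, 32)))
  res <- lossless_baseline_compress(ph$volume)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "ok.aroi")
  write_container(res$compressed, path)
  bytes <- readBin(path, "raw", file.size(path))

  trunc <- file.path(dir, "trunc.aroi")
  writeBin(bytes[1:(length(bytes) - 1)], trunc)
  expect_error(read_container(trunc), "truncated|corrupted|integrity")

  bad <- file.path(dir, "bad.aroi")
  bytes2 <- bytes; bytes2[1:4] <- charToRaw("NOPE")
  writeBin(bytes2, bad)
  expect_error(read_container(bad), "magic")
})

test_that("all-lossless containers reproduce the volume bit-exactly", {
  ph <- generate_phantom(phantom_config(n_slices = 3, slice_shape = c(32, 32),
                                        seed = 8))
  res <- lossless_baseline_compress(ph$volume)
  path <- file.path(withr::local_tempdir(), "ll.aroi")
  write_container(res$compressed, path)
  expect_identical(decompress(read_container(path))$pixels, ph$volume$pixels)
})

test_that("decompressed ROI volumes keep the PROI bit-exact and the floor intact", {
  ph <- small_phantom()
  part <- small_partition()
  res <- small_mvar()
  path <- file.path(withr::local_tempdir(), "mvar.aroi")
  write_container(res$compressed, path)
  recon <- decompress(read_container(path))
  expect_identical(recon$pixels[part$proi], ph$volume$pixels[part$proi])
  q <- quality_curve(ph$volume, recon)
  expect_gte(q$min_psnr_db, 40)
})

test_that("partition files round-trip", {
  part <- small_partition()
  path <- file.path(withr::local_tempdir(), "p.arpt")
  write_partition(part, path)
  back <- read_partition(path)
  expect_identical(back$proi, part$proi)
  expect_identical(back$sroi, part$sroi)
  expect_identical(back$background, part$background)
  expect_equal(back$enlargement_factor, 8)
})

test_that("DICOM series round-trip bit-exactly and sort by position", {
  ph <- generate_phantom(phantom_config(n_slices = 4, slice_shape = c(64, 48),
                                        seed = 7))
  dir <- withr::local_tempdir()
  write_dicom_series(ph$volume, file.path(dir, "series"))
  v2 <- read_dicom_series(file.path(dir, "series"))
  expect_identical(v2$pixels, ph$volume$pixels)
  expect_equal(v2$pixel_spacing, ph$volume$pixel_spacing)
  expect_equal(v2$slice_thickness, ph$volume$slice_thickness)
  # shuffled file names: same volume
  shuf <- file.path(dir, "shuffled")
  dir.create(shuf)
  files <- list.files(file.path(dir, "series"), full.names = TRUE)
  file.copy(files, file.path(shuf, sprintf("%s.dcm", rev(letters[seq_along(files)]))))
  expect_identical(read_dicom_series(shuf)$pixels, ph$volume$pixels)
})

test_that("mixed slice shapes are rejected naming the offending file", {
  dir <- withr::local_tempdir()
  a <- generate_phantom(phantom_config(n_slices = 2, slice_shape = c(32, 32)))
  b <- generate_phantom(phantom_config(n_slices = 1, slice_shape = c(48, 48)))
  write_dicom_series(a$volume, dir)
  odd <- file.path(withr::local_tempdir(), "odd")
  write_dicom_series(b$volume, odd)
  file.copy(list.files(odd, full.names = TRUE), file.path(dir, "IM000099.dcm"))
  expect_error(read_dicom_series(dir), "IM000099")
})

test_that("written series are readable by an independent DICOM implementation", {
  ph <- generate_phantom(phantom_config(n_slices = 2, slice_shape = c(40, 32),
                                        seed = 12))
  dir <- withr::local_tempdir()
  write_dicom_series(ph$volume, dir)
  script <- file.path(dir, "check.py")
  writeLines(c(
    "import sys, glob, pydicom",
    "files = sorted(glob.glob(sys.argv[1] + '/*.dcm'))",
    "for f in files:",
    "    ds = pydicom.dcmread(f)",
    "    assert ds.Modality == 'CT'",
    "    assert (int(ds.Rows), int(ds.Columns)) == (40, 32)",
    "    print(int(ds.pixel_array.sum()))"), script)
  out <- system2("python", c(script, dir), stdout = TRUE)
  expect_equal(as.numeric(out),
               apply(ph$volume$pixels, 3, function(s) sum(as.double(s))))
})
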