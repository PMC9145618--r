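test_that("the variable-rate controller honours the PSNR floor", {
  ph <- small_phantom()
  res <- small_mvar()
  tr <- res$schedule$trace
  expect_true(all(tr$psnr_db >= 40))
  # recomputed post hoc from the decompressed volume, independent of the trace
  q <- quality_curve(ph$volume, decompress(res$compressed), mode = "MVAR")
  expect_gte(q$min_psnr_db, 40)
  expect_equal(q$slice_psnr_db, tr$psnr_db, tolerance = 1e-9)
})

test_that("a zero threshold lets the schedule decay to the rate floor", {
  ph <- small_phantom()
  res <- mvar_compress(ph$volume, small_partition(), threshold_db = 0,
                       initial_bpp = 0.1)
  tr <- res$schedule$trace
  expect_true(all(tr$retries == 0))
  expect_true(all(diff(tr$bpp) <= 0))
  expect_equal(min(tr$bpp), 0.05)
})

test_that("a single-slice run matches an independent replay of the adaptation loop", {
  ph <- small_phantom()
  vol1 <- aroi_volume(ph$volume$pixels[, , 1, drop = FALSE])
  part <- small_partition()
  part1 <- make_partition(
    (part$proi | part$sroi)[, , 1, drop = FALSE],
    part$proi[, , 1, drop = FALSE],
    part$enlargement_factor)
  threshold <- 41
  res <- mvar_compress(vol1, part1, threshold_db = threshold,
                       initial_bpp = 0.1)
  # oracle: scripted replay of the while-loop using only codec + metric calls
  sl <- volume_slice(vol1, 1)
  ps <- partition_slice(part1, 1)
  w <- range(vol1$pixels)
  slice_psnr <- function(bpp) {
    proi <- decode_region(encode_lossless(sl, ps$proi), dim(sl))
    sroi <- decode_region(encode_lossy(sl, ps$sroi, bpp), dim(sl))
    bg <- decode_region(encode_lossy(sl, ps$background, 0.05), dim(sl))
    recon <- compose_slice(ps, proi, sroi, bg)
    psnr_from_mse(mean(((sl - recon) * 255 / diff(w))^2), 255)
  }
  bpp <- 0.1; retries <- 0L; p <- slice_psnr(bpp)
  while (p < threshold && bpp < 8) {
    bpp <- min(2 * bpp, 8)
    p <- slice_psnr(bpp)
    retries <- retries + 1L
  }
  expect_gt(retries, 0L)
  expect_equal(res$schedule$trace$retries, retries)
  expect_equal(res$schedule$trace$bpp, bpp)
  expect_gte(res$schedule$trace$psnr_db, threshold)
})

test_that("an unreachable floor raises an error naming the slice", {
  ph <- small_phantom()
  expect_error(
    mvar_compress(ph$volume, small_partition(), threshold_db = 70,
                  bpp_max = 0.2, initial_bpp = 0.1),
    "slice 1")
})

test_that("the rate trace is serrated: decay except after drop-backs", {
  res <- small_mvar()
  tr <- res$schedule$trace
  for (i in 2:nrow(tr)) {
    if (tr$retries[i - 1] == 0 && tr$bpp[i - 1] > 0.05) {
      expect_lt(tr$attempted_bpp[i], tr$attempted_bpp[i - 1])
    }
    expect_equal(tr$attempted_bpp[i], max(0.05, 0.9 * tr$bpp[i - 1]))
  }
})

test_that("mfix_rate is the arithmetic mean of the variable schedule", {
  sched <- aroi:::new_schedule(c(1, 2, 3), 40, "MVAR",
                               data.frame(slice = 1:3, attempted_bpp = 1:3,
                                          bpp = c(1, 2, 3), psnr_db = 41,
                                          retries = 0L))
  expect_equal(mfix_rate(sched), 2)
  sched1 <- aroi:::new_schedule(0.7, 40, "MVAR", sched$trace[1, ])
  expect_equal(mfix_rate(sched1), 0.7)
  res <- small_mvar()
  acc <- 0
  for (r in res$schedule$sroi_bpp) acc <- acc + r
  expect_equal(mfix_rate(res$schedule), acc / length(res$schedule$sroi_bpp),
               tolerance = 1e-9)
  expect_error(mfix_rate(structure(list(mode = "PLAIN"), class = "aroi_schedule")),
               "mvar")
  empty <- aroi:::new_schedule(numeric(0), 40, "MVAR", sched$trace[0, ])
  expect_error(mfix_rate(empty), "empty")
})

test_that("fixed-rate compression keeps the PROI lossless at any rate", {
  ph <- small_phantom()
  part <- small_partition()
  for (bpp in c(0.1, 1)) {
    mf <- mfix_compress(ph$volume, part, bpp)
    recon <- decompress(mf$compressed)
    expect_identical(recon$pixels[part$proi], ph$volume$pixels[part$proi])
    expect_identical(mf$schedule$sroi_bpp, rep(bpp, 12))
  }
  expect_error(mfix_compress(ph$volume, part, 0.01), "range")
})

test_that("noisy proximal slices score lower than smooth distal ones at a fixed rate", {
  ph <- small_phantom()
  mf <- mfix_compress(ph$volume, small_partition(), 0.5)
  p <- mf$schedule$trace$psnr_db
  expect_lt(p[1], p[length(p)])
  expect_lt(mean(p[1:3]), mean(p[10:12]))
})

test_that("fixed-rate PSNR is monotone in the rate", {
  ph <- small_phantom()
  part <- small_partition()
  p_hi <- mfix_compress(ph$volume, part, 8)$schedule$trace$psnr_db
  p_lo <- mfix_compress(ph$volume, part, 0.3)$schedule$trace$psnr_db
  expect_true(all(p_hi >= p_lo))
})

test_that("ROI compression beats whole-frame lossy at the same rate on vessel slices", {
  ph <- small_phantom()
  res <- small_mvar()
  recon <- decompress(res$compressed)
  vslices <- which(apply(ph$truth$vessel_mask, 3, any))
  expect_gt(length(vslices), 0)
  d <- dim(ph$volume$pixels)[1:2]
  for (i in vslices) {
    sl <- volume_slice(ph$volume, i)
    plain <- decode_region(
      encode_lossy(sl, full_mask(d[1], d[2]), res$schedule$sroi_bpp[i]), d)
    expect_lte(mse(recon$pixels[, , i], sl), mse(plain, sl))
  }
})

test_that("whole-frame modes record schedules with equal rates", {
  ph <- small_phantom()
  pl <- plain_lossy_compress(ph$volume, 0.5)
  expect_identical(pl$schedule$mode, "PLAIN")
  expect_true(all(pl$schedule$sroi_bpp == 0.5))
  expect_false(pl$compressed$has_partition)
  # constant slice at the top rate: effectively lossless, sentinel PSNR
  const <- aroi_volume(array(777L, dim = c(32, 32, 1)))
  pc <- plain_lossy_compress(const, 8, window = c(0, 1000))
  expect_identical(pc$schedule$trace$psnr_db, Inf)
})
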