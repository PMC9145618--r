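# Independent 3D connected-component oracle: breadth-first flood fill over
# the 26-neighbourhood, structurally unrelated to the union-find used by
# segment_vessels().
count_components_bfs <- function(mask) {
  d <- dim(mask)
  seen <- array(FALSE, dim = d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  n_comp <- 0L
  todo <- which(mask & !seen)
  while (length(todo) > 0) {
    n_comp <- n_comp + 1L
    queue <- todo[1]
    seen[queue] <- TRUE
    while (length(queue) > 0) {
      idx <- queue[1]; queue <- queue[-1]
      i <- ((idx - 1) %% d[1]) + 1
      j <- (((idx - 1) %/% d[1]) %% d[2]) + 1
      k <- ((idx - 1) %/% (d[1] * d[2])) + 1
      for (o in seq_len(nrow(offs))) {
        ni <- i + offs[o, 1]; nj <- j + offs[o, 2]; nk <- k + offs[o, 3]
        if (ni >= 1 && ni <= d[1] && nj >= 1 && nj <= d[2] &&
            nk >= 1 && nk <= d[3] && mask[ni, nj, nk] && !seen[ni, nj, nk]) {
          seen[ni, nj, nk] <- TRUE
          queue <- c(queue, (nk - 1) * d[1] * d[2] + (nj - 1) * d[1] + ni)
        }
      }
    }
    todo <- which(mask & !seen)
  }
  n_comp
}

test_that("body segmentation recovers the phantom body almost exactly", {
  ph <- small_phantom()
  body <- segment_body(ph$volume, 565)
  truth <- ph$truth$body_mask
  dice <- 2 * sum(body & truth) / (sum(body) + sum(truth))
  expect_gte(dice, 0.99)
})

test_that("body segmentation handles degenerate inputs", {
  air <- aroi_volume(array(50L, dim = c(32, 32, 2)))
  expect_false(any(segment_body(air, 565)))
  ph <- small_phantom()
  expect_false(any(segment_body(ph$volume, 65535)))
})

test_that("vessel segmentation is conservative: high recall against truth", {
  ph <- small_phantom()
  body <- segment_body(ph$volume, 565)
  vessels <- segment_vessels(ph$volume, body, 1340)
  truth <- ph$truth$vessel_mask
  recall <- sum(vessels & truth) / sum(truth)
  expect_gte(recall, 0.95)
})

test_that("no vessels means an empty vessel mask", {
  ph <- generate_phantom(phantom_config(n_slices = 4, slice_shape = c(48, 48),
                                        vessel_count = 0))
  body <- segment_body(ph$volume, 565)
  expect_false(any(segment_vessels(ph$volume, body, 1340)))
})

test_that("a single unbranched tube yields one 3D component", {
  ph <- generate_phantom(phantom_config(n_slices = 10, slice_shape = c(64, 64),
                                        vessel_count = 1, branch_prob = 0,
                                        seed = 3))
  body <- segment_body(ph$volume, 565)
  vessels <- segment_vessels(ph$volume, body, 1340)
  expect_identical(count_components_bfs(vessels), 1L)
})

test_that("PROI enlargement reaches the area target and matches a step-by-step oracle", {
  m <- array(FALSE, dim = c(32, 32, 1))
  m[14:18, 15:16, 1] <- TRUE  # 10-pixel blob
  proi <- enlarge_proi(m, factor = 8)
  expect_gte(sum(proi), 80)
  expect_true(all(proi[m]))
  # oracle: EBImage dilation with a 3x3 cross, iterated until >= 80 px
  kern <- EBImage::makeBrush(3, shape = "diamond")
  o <- m[, , 1]
  n_iter <- 0L
  while (sum(o) < 80) {
    o <- EBImage::dilate(o, kern) > 0
    n_iter <- n_iter + 1L
  }
  expect_identical(proi[, , 1], o)
  expect_gt(n_iter, 0L)
})

test_that("enlargement edge cases: identity at factor 1, cap at full frame", {
  ph <- small_phantom()
  expect_identical(enlarge_proi(ph$truth$vessel_mask, 1),
                   ph$truth$vessel_mask)
  m <- array(TRUE, dim = c(16, 16, 1))
  expect_true(all(enlarge_proi(m, 8)))
  empty <- array(FALSE, dim = c(16, 16, 2))
  expect_false(any(enlarge_proi(empty, 8)))
})

test_that("enlargement is monotone in the factor", {
  ph <- small_phantom()
  p8 <- enlarge_proi(ph$truth$vessel_mask, 8)
  p12 <- enlarge_proi(ph$truth$vessel_mask, 12)
  expect_true(all(p12[p8]))
})

test_that("the three masks form an exact partition on every slice", {
  part <- small_partition()
  expect_true(all(part$proi + part$sroi + part$background == 1))
  # degenerate: full-frame body, empty PROI
  body <- array(TRUE, dim = c(16, 16, 1))
  proi <- array(FALSE, dim = c(16, 16, 1))
  p <- make_partition(body, proi)
  expect_true(all(p$sroi))
  expect_false(any(p$background))
  expect_error(make_partition(body, array(FALSE, dim = c(8, 8, 1))), "shape")
})

test_that("ground-truth vessels are always inside the enlarged PROI", {
  ph <- small_phantom()
  part <- small_partition()
  expect_true(all(part$proi[ph$truth$vessel_mask]))
})

test_that("SROI occupies a plausible body fraction at CT scale", {
  ph <- generate_phantom(phantom_config(n_slices = 6, seed = 42))
  part <- segment_volume(ph$volume)
  frac <- apply(part$sroi, 3, mean)
  expect_true(all(frac >= 0.3 & frac <= 0.7))
})
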