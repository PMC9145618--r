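#' @import EBImage
NULL

# One step of binary dilation with a 3x3 cross (4-neighbourhood) structuring
# element, implemented by mask shifts. Used by enlarge_proi(); EBImage's
# dilate() serves as an independent cross-check in the test suite.
dilate_cross <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  out[-1, ] <- out[-1, ] | m[-nr, ]
  out[-nr, ] <- out[-nr, ] | m[-1, ]
  out[, -1] <- out[, -1] | m[, -nc]
  out[, -nc] <- out[, -nc] | m[, -1]
  out
}

#' Segment the body on every slice
#'
#' Thresholds each slice, keeps the largest 2D connected component, and fills
#' interior holes. The body/background boundary in CT is high-contrast, so a
#' simple threshold is reliable; the largest-component and hole-filling steps
#' guard against stray bright pixels and against carving low-intensity tissue
#' out of the patient -- mislabelling patient tissue as background would
#' expose it to heavy compression, the one failure mode this stage must
#' avoid. No pixel at or above the threshold inside the retained component is
#' ever excluded.
#'
#' @param volume an [aroi_volume()].
#' @param threshold stored-value intensity threshold separating air from
#'   tissue (e.g. midway between the air and soft-tissue levels).
#' @return logical array of the volume's dimension (per-slice body mask). An
#'   all-air slice yields an empty mask.
#' @export
segment_body <- function(volume, threshold) {
  px <- volume$pixels
  d <- dim(px)
  assert_that(threshold <= 65535 && threshold >= 0,
              "threshold must lie within the stored-value range")
  out <- array(FALSE, dim = d)
  for (i in seq_len(d[3])) {
    bw <- px[, , i] >= threshold
    if (!any(bw)) next
    lab <- EBImage::bwlabel(bw)
    tab <- tabulate(lab[lab > 0])
    keep <- which.max(tab)
    comp <- lab == keep
    comp <- EBImage::fillHull(comp)
    out[, , i] <- comp > 0
  }
  out
}

# 26-connected 3D component labelling on a sparse voxel set. Mask volumes
# here are small (vessels are <5% of the frame), so a union-find over the
# voxel list with hashed neighbour lookups is adequate.
label_components_3d <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  nv <- length(idx)
  if (nv == 0L) return(list(labels = integer(0), index = idx, n = 0L))
  r <- ((idx - 1L) %% d[1]) + 1L
  c <- (((idx - 1L) %/% d[1]) %% d[2]) + 1L
  s <- ((idx - 1L) %/% (d[1] * d[2])) + 1L

  parent <- seq_len(nv)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }

  # forward half of the 26-neighbourhood (13 offsets)
  offs <- expand.grid(dr = -1:1, dc = -1:1, ds = -1:1)
  offs <- offs[(offs$ds > 0) |
                 (offs$ds == 0 & offs$dc > 0) |
                 (offs$ds == 0 & offs$dc == 0 & offs$dr > 0), ]
  key <- (s - 1) * (d[1] * d[2]) + (c - 1) * d[1] + r  # == idx, numeric
  for (k in seq_len(nrow(offs))) {
    nr <- r + offs$dr[k]; nc <- c + offs$dc[k]; ns <- s + offs$ds[k]
    ok <- nr >= 1 & nr <= d[1] & nc >= 1 & nc <= d[2] & ns >= 1 & ns <= d[3]
    if (!any(ok)) next
    nkey <- (ns[ok] - 1) * (d[1] * d[2]) + (nc[ok] - 1) * d[1] + nr[ok]
    hit <- match(nkey, key)
    src <- which(ok)[!is.na(hit)]
    dst <- hit[!is.na(hit)]
    for (j in seq_along(src)) {
      a <- find(src[j]); b <- find(dst[j])
      if (a != b) parent[b] <- a
    }
  }
  roots <- vapply(seq_len(nv), find, integer(1))
  labels <- match(roots, unique(roots))
  list(labels = labels, index = idx, n = length(unique(roots)))
}

#' Segment the arterial tree
#'
#' Marks supra-threshold pixels inside the body mask as vessel candidates,
#' links them across slices with 26-connected 3D components, and removes
#' components smaller than `min_size` voxels. The stage is deliberately
#' conservative: it is tuned for recall (never losing vessel lumen) rather
#' than precision, since missed vessel pixels would be compressed lossily
#' while extra pixels merely enlarge the losslessly stored region slightly.
#'
#' @param volume an [aroi_volume()].
#' @param body logical body mask from [segment_body()].
#' @param vessel_threshold intensity above which in-body pixels count as
#'   contrast-enhanced vessel (e.g. midway between tissue and contrast
#'   levels).
#' @param min_size minimum 3D component size in voxels; smaller speckle
#'   components (noise excursions) are dropped.
#' @return logical array: per-slice vessel mask. Empty when no pixel exceeds
#'   the threshold.
#' @export
segment_vessels <- function(volume, body, vessel_threshold, min_size = 10L) {
  assert_that(identical(dim(body), dim(volume$pixels)),
              "body mask shape must match the volume")
  cand <- (volume$pixels >= vessel_threshold) & body
  if (!any(cand)) return(cand)
  lab <- label_components_3d(cand)
  sizes <- tabulate(lab$labels, nbins = lab$n)
  keep <- which(sizes >= min_size)
  out <- array(FALSE, dim = dim(cand))
  out[lab$index[lab$labels %in% keep]] <- TRUE
  out
}

#' Enlarge the vessel mask into the primary ROI
#'
#' Per slice, iteratively dilates the vessel mask with a 3x3 cross until its
#' area reaches `factor` times the original vessel area (default 8, the
#' safety margin that makes under-segmentation of the arteries practically
#' impossible), capped at the full frame. The result is always a superset of
#' the vessel mask and may include nearby non-vessel tissue such as bone --
#' intentional over-segmentation, cheap because the vessels occupy a few
#' percent of the frame at most.
#'
#' @param vessel_mask logical array (per-slice vessel mask).
#' @param factor target area multiple, `>= 1`. `factor = 1` returns the mask
#'   unchanged.
#' @return logical array: the primary ROI mask. Slices with an empty vessel
#'   mask get an empty PROI (no lossless region there).
#' @export
enlarge_proi <- function(vessel_mask, factor = 8) {
  assert_that(factor >= 1, "enlargement factor must be >= 1")
  d <- dim(vessel_mask)
  out <- vessel_mask
  for (i in seq_len(d[3])) {
    m <- vessel_mask[, , i]
    area0 <- sum(m)
    if (area0 == 0L) next
    target <- ceiling(factor * area0)
    full <- d[1] * d[2]
    while (sum(m) < target && sum(m) < full) {
      m <- dilate_cross(m)
    }
    out[, , i] <- m
  }
  out
}

#' Build the three-region partition
#'
#' Combines the body mask and the primary ROI into the exact three-way
#' partition the compressor consumes: the secondary ROI is body tissue
#' outside the PROI, and the background is everything outside body and PROI.
#' The PROI is not clipped to the body -- its margin may legitimately cover
#' bone or immediately adjacent air, and clipping would risk the
#' under-segmentation the margin exists to prevent.
#'
#' @param body logical array from [segment_body()].
#' @param proi logical array from [enlarge_proi()].
#' @param enlargement_factor the factor used to build `proi`; carried as
#'   metadata.
#' @return an `aroi_partition`: list of logical arrays `proi`, `sroi`,
#'   `background` (pairwise disjoint, union = full grid on every slice) plus
#'   `enlargement_factor`.
#' @export
make_partition <- function(body, proi, enlargement_factor = 8) {
  assert_that(identical(dim(body), dim(proi)),
              "body and proi masks must have identical shapes")
  sroi <- body & !proi
  background <- !(body | proi)
  structure(list(proi = proi, sroi = sroi, background = background,
                 enlargement_factor = as.numeric(enlargement_factor)),
            class = "aroi_partition")
}

#' @export
print.aroi_partition <- function(x, ...) {
  d <- dim(x$proi)
  cat(sprintf("<aroi_partition> %d slice(s) of %d x %d (enlargement factor %g)\n",
              d[3], d[1], d[2], x$enlargement_factor))
  cat(sprintf("  mean fractions: PROI %.3f, SROI %.3f, background %.3f\n",
              mean(x$proi), mean(x$sroi), mean(x$background)))
  invisible(x)
}

#' One-call segmentation pipeline
#'
#' Runs [segment_body()], [segment_vessels()], [enlarge_proi()] and
#' [make_partition()] with thresholds that default to the midpoints of the
#' phantom's intensity levels.
#'
#' @param volume an [aroi_volume()].
#' @param body_threshold air/tissue threshold.
#' @param vessel_threshold tissue/contrast threshold.
#' @param factor PROI enlargement factor.
#' @param min_size minimum vessel component size in voxels.
#' @return an `aroi_partition`, with the intermediate `body` and
#'   `vessel_mask` attached as attributes `"body"` and `"vessels"`.
#' @export
segment_volume <- function(volume, body_threshold = 565, vessel_threshold = 1340,
                           factor = 8, min_size = 10L) {
  body <- segment_body(volume, body_threshold)
  vessels <- segment_vessels(volume, body, vessel_threshold, min_size)
  proi <- enlarge_proi(vessels, factor)
  part <- make_partition(body, proi, factor)
  attr(part, "body") <- body
  attr(part, "vessels") <- vessels
  part
}

# Exact-partition check used by compose_slice() and the container reader.
is_exact_partition <- function(proi, sroi, background) {
  all(proi + sroi + background == 1L)
}
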