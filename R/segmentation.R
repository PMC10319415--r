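# Plant/soil segmentation.
#
# The dual-stream model consumes each canopy image twice: once with soil
# pixels zeroed (plant stream) and once with plant pixels zeroed (soil
# stream). Segmentation is training-free: an excess-green index on
# chromaticity-normalised RGB, thresholded by Otsu's method (or a fixed
# threshold), then cleaned by 3x3 morphological opening/closing and removal
# of small connected components.

#' Excess-green index of an RGB image
#'
#' Computes `ExG = 2 g - r - b` on per-pixel chromaticity coordinates
#' (channels divided by the per-pixel channel sum). Vegetation scores high,
#' soil near zero. Pixels with zero channel sum map to 0.
#'
#' @param image numeric array `H x W x 3` in `[0, 1]`.
#' @return numeric `H x W` matrix, finite everywhere, conceptually in `[-1, 2]`.
#' @export
excess_green <- function(image) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop("excess_green expects an RGB image (H x W x 3)")
  }
  s <- image[, , 1] + image[, , 2] + image[, , 3]
  z <- s <= 0
  s[z] <- 1
  exg <- (2 * image[, , 2] - image[, , 1] - image[, , 3]) / s
  exg[z] <- 0
  exg
}

#' Otsu threshold of a numeric field
#'
#' Standard between-class-variance maximisation over a histogram of the
#' values. Returns `NA` for a (near-)constant input.
#'
#' @param x numeric vector or matrix.
#' @param nbins histogram resolution.
#' @return threshold value, or `NA` if the histogram is degenerate.
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  x <- as.numeric(x)
  rng <- range(x)
  if (!is.finite(diff(rng)) || diff(rng) < 1e-12) return(NA_real_)
  brk <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, brk, all.inside = TRUE), nbins)
  p <- h / sum(h)
  mids <- (brk[-1] + brk[-length(brk)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, nbins)
  sigma_b[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  # the maximum can be a plateau (an empty gap between modes): take its middle
  best <- which(sigma_b >= max(sigma_b) - 1e-12 * abs(max(sigma_b)))
  brk[round(mean(range(best))) + 1L]
}

# binary 3x3 dilation / erosion via shifted copies (edge-replicated)
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

dilate3 <- function(m) {
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out | shift_mat(m, dr, dc)
  }
  out
}

erode3 <- function(m) {
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out & shift_mat(m, dr, dc)
  }
  out
}

# 4-connected component labelling (iterative flood fill)
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  todo <- which(mask)
  stack <- integer(0)
  for (s0 in todo) {
    if (lab[s0] != 0L) next
    cur <- cur + 1L
    stack <- s0
    lab[s0] <- cur
    while (length(stack)) {
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- ((i - 1L) %% nr) + 1L
      cc <- ((i - 1L) %/% nr) + 1L
      for (nb in c(if (r > 1L) i - 1L, if (r < nr) i + 1L,
                   if (cc > 1L) i - nr, if (cc < nc) i + nr)) {
        if (mask[nb] && lab[nb] == 0L) {
          lab[nb] <- cur
          stack <- c(stack, nb)
        }
      }
    }
  }
  lab
}

#' Segment an RGB canopy image into plant and soil parts
#'
#' Thresholds the excess-green index (Otsu by default), applies a 3x3
#' morphological opening then closing, and discards connected plant
#' components smaller than `min_region` pixels. The two output images are
#' complementary maskings of the input: their sum reconstructs it exactly.
#'
#' @param image numeric array `H x W x 3` in `[0, 1]`.
#' @param mode `"otsu"` or `"fixed"`.
#' @param fixed_threshold ExG threshold used when `mode = "fixed"`.
#' @param min_region minimum plant-component area in pixels.
#' @return list of class `segmented_pair`: `plant_image`, `soil_image`
#'   (H x W x 3 arrays), `plant_mask` (logical matrix).
#' @export
segment_plant_soil <- function(image, mode = c("otsu", "fixed"),
                               fixed_threshold = 0.2, min_region = 16L) {
  mode <- match.arg(mode)
  exg <- excess_green(image)
  thr <- if (mode == "otsu") otsu_threshold(exg) else fixed_threshold
  if (is.na(thr)) {
    warning("degenerate ExG histogram; falling back to an all-soil mask")
    mask <- matrix(FALSE, nrow(exg), ncol(exg))
  } else {
    mask <- exg > thr
    if (any(mask) && !all(mask)) {
      mask <- dilate3(erode3(mask))   # opening
      mask <- erode3(dilate3(mask))   # closing
      if (min_region > 1 && any(mask)) {
        lab <- label_components(mask)
        sizes <- tabulate(lab[lab > 0L])
        keep <- which(sizes >= min_region)
        mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
      }
    }
  }
  m3 <- array(rep(as.numeric(mask), 3L), dim = dim(image))
  structure(list(plant_image = image * m3,
                 soil_image = image * (1 - m3),
                 plant_mask = mask),
            class = "segmented_pair")
}

#' Intersection-over-union of two binary masks
#' @param a,b logical matrices of equal size.
#' @return IoU in `[0, 1]`; defined as 1 when both masks are empty.
#' @export
mask_iou <- function(a, b) {
  un <- sum(a | b)
  if (un == 0) return(1)
  sum(a & b) / un
}
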