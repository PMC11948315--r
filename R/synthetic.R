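#' Synthetic labelled blob-image dataset
#'
#' Generates a K-class image set with a learnable class signal: each class has
#' a distinct blob position and colour prototype, and every image is its class
#' prototype plus i.i.d. Gaussian pixel noise, clipped to `[0, 255]`. With
#' `signalStrength = 0` the prototypes coincide and the classes are
#' indistinguishable (any classifier is at chance); with `noiseSd = 0` images
#' equal their prototypes and a nearest-prototype classifier is perfect. The
#' generator is a pure function of its seed.
#'
#' The defaults (4 classes, 50 images per class, 32-px images, blob amplitude
#' 25 over a background of 30, noise SD 80) put the per-pixel signal-to-noise
#' ratio well below 1: the class signal is only recoverable by pooling over
#' the blob area, so a small CNN learns the task to well above chance but
#' optimisation is noisy and the validation loss plateaus and fluctuates —
#' the regime the switching controller is designed for. Raise
#' `signalStrength` (or drop `noiseSd`) for trivially separable sets.
#'
#' @param nClasses number of classes, `>= 2`.
#' @param nPerClass images per class.
#' @param imageSize image side in pixels (square), `>= 12` so blobs fit.
#' @param signalStrength blob amplitude added to the background (0–225).
#' @param noiseSd Gaussian pixel-noise standard deviation.
#' @param seed integer seed; identical seeds give byte-identical datasets.
#' @return list with `images` (`n x S x S x 3` array, values 0–255), `labels`
#'   (integer `1..K`), `prototypes` (`K x S x S x 3`) and `spec` (the
#'   arguments).
#' @examples
#' ds <- makeBlobDataset(nClasses = 3, nPerClass = 5, imageSize = 16, seed = 7)
#' dim(ds$images)
#' @export
makeBlobDataset <- function(nClasses = 4L, nPerClass = 50L, imageSize = 32L,
                            signalStrength = 25, noiseSd = 80, seed = 1L) {
  stopifnot(nClasses >= 2L, nPerClass >= 1L, signalStrength >= 0, noiseSd >= 0)
  if (imageSize < 12L) stop("image too small to place blobs (need >= 12 px)", call. = FALSE)
  S <- as.integer(imageSize); K <- as.integer(nClasses)
  background <- 30
  # class prototypes: blob centred on a ring, colour direction cycling
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                c(1, 1, 0), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1))
  xy <- expand.grid(row = seq_len(S), col = seq_len(S))
  prototypes <- array(background, c(K, S, S, 3))
  for (k in seq_len(K)) {
    ang <- 2 * pi * (k - 1) / K
    cy <- S / 2 + (S / 4) * sin(ang)
    cx <- S / 2 + (S / 4) * cos(ang)
    blob <- matrix(as.numeric((xy$row - cy)^2 + (xy$col - cx)^2 <= (S / 6)^2), S, S)
    dir <- dirs[(k - 1) %% nrow(dirs) + 1, ]
    for (ch in 1:3)
      prototypes[k, , , ch] <- pmin(255, background + signalStrength * dir[ch] * blob)
  }
  n <- K * nPerClass
  labels <- rep(seq_len(K), each = nPerClass)
  images <- array(0, c(n, S, S, 3))
  withr::with_seed(as.integer(seed), {
    noise <- array(stats::rnorm(n * S * S * 3, sd = noiseSd), c(n, S, S, 3))
    for (i in seq_len(n))
      images[i, , , ] <- pmin(255, pmax(0, prototypes[labels[i], , , ] + noise[i, , , ]))
  })
  list(images = images, labels = labels, prototypes = prototypes,
       spec = list(nClasses = K, nPerClass = as.integer(nPerClass), imageSize = S,
                   signalStrength = signalStrength, noiseSd = noiseSd,
                   seed = as.integer(seed)))
}

#' Synthetic plant-green test image with ground-truth mask
#'
#' Builds a raster in which a stated fraction of pixels lie inside a colour
#' window (see [maskRange()]) and the rest lie strictly outside, returning the
#' exact boolean membership mask alongside. Used to test
#' [colorRangeMask()] pixel-for-pixel. In RGB mode green pixels are drawn
#' uniformly inside the window and non-green pixels violate at least one
#' channel bound by construction; in HSV mode pixels are classified by the
#' same inclusive window test the generator embeds, so the returned mask is
#' exact in either mode.
#'
#' @param seed integer seed.
#' @param greenFraction fraction of pixels inside the window, in `[0, 1]`.
#' @param width,height raster size in pixels.
#' @param range a [maskRange()].
#' @return list with `image` (`height x width x 3`, integer values 0–255) and
#'   `mask` (logical `height x width`, `TRUE` = inside the window).
#' @export
makeGreenPlantImage <- function(seed = 1L, greenFraction = 0.3,
                                width = 48L, height = 48L, range = maskRange()) {
  stopifnot(greenFraction >= 0, greenFraction <= 1)
  n <- as.integer(width) * as.integer(height)
  nGreen <- round(greenFraction * n)
  withr::with_seed(as.integer(seed), {
    greenIdx <- sample.int(n, nGreen)
    px <- matrix(0L, n, 3)
    if (range$colorspace == "rgb") {
      for (ch in 1:3) {
        lo <- range$lower[ch]; up <- range$upper[ch]
        px[greenIdx, ch] <- sample(seq.int(lo, up), nGreen, replace = TRUE)
      }
      other <- setdiff(seq_len(n), greenIdx)
      # violate one channel bound; channels with room outside the window
      canViolate <- which(range$lower > 0 | range$upper < 255)
      if (length(other) && !length(canViolate))
        stop("window covers the full colour cube; no outside pixels exist", call. = FALSE)
      for (i in other) {
        ch <- canViolate[(i %% length(canViolate)) + 1L]
        below <- range$lower[ch] > 0; above <- range$upper[ch] < 255
        side <- if (below && above) sample(c(TRUE, FALSE), 1) else below
        px[i, ch] <- if (side) sample.int(range$lower[ch], 1) - 1L
                     else sample(seq.int(range$upper[ch] + 1L, 255L), 1)
        rest <- setdiff(1:3, ch)
        px[i, rest] <- sample(0:255, 2, replace = TRUE)
      }
    } else {
      # rejection-sample random pixels into inside/outside quotas, classifying
      # with the same inclusive window test the mask applies
      inside <- matrix(NA_integer_, 0, 3); outside <- matrix(NA_integer_, 0, 3)
      while (nrow(inside) < nGreen || nrow(outside) < n - nGreen) {
        cand <- matrix(sample(0:255, 3 * 256, replace = TRUE), ncol = 3)
        member <- as.vector(.inMaskRange(array(cand, c(nrow(cand), 1, 3)), range))
        inside <- rbind(inside, cand[member, , drop = FALSE])
        outside <- rbind(outside, cand[!member, , drop = FALSE])
      }
      px[greenIdx, ] <- inside[seq_len(nGreen), , drop = FALSE]
      px[setdiff(seq_len(n), greenIdx), ] <- outside[seq_len(n - nGreen), , drop = FALSE]
    }
    img <- array(0, c(height, width, 3))
    mask <- matrix(FALSE, height, width)
    mask[seq_len(n) %in% greenIdx] <- TRUE
    for (ch in 1:3) img[, , ch] <- matrix(px[, ch], height, width)
    list(image = img, mask = mask)
  })
}
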