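#' Colour bounds for plant-green masking
#'
#' An inclusive per-channel window used to keep "plant-green" pixels and zero
#' out everything else. The default window is lower `(27, 45, 45)`, upper
#' `(100, 255, 255)`. By default the bounds are applied to the raw RGB
#' channels (`colorspace = "rgb"`); they can instead be interpreted in HSV
#' (`colorspace = "hsv"`), where they form a canonical green hue window with
#' hue scaled to `[0, 180)` and saturation/value to `[0, 255]`. Both readings
#' are supported because the window is ambiguous between the two conventions;
#' neither is silently corrected.
#'
#' @param lower,upper numeric length-3 channel bounds in `[0, 255]`,
#'   `lower <= upper` per channel.
#' @param colorspace `"rgb"` (bounds on raw channels) or `"hsv"`.
#' @return a `maskRange` object (named list).
#' @export
maskRange <- function(lower = c(27, 45, 45), upper = c(100, 255, 255),
                      colorspace = c("rgb", "hsv")) {
  colorspace <- match.arg(colorspace)
  stopifnot(length(lower) == 3L, length(upper) == 3L,
            all(lower >= 0), all(upper <= 255), all(lower <= upper))
  structure(list(lower = lower, upper = upper, colorspace = colorspace),
            class = "maskRange")
}

# channel planes of an image in the range's colorspace
# img: H x W x 3 array, values 0..255
.rangeChannels <- function(img, range) {
  if (range$colorspace == "rgb") return(img)
  n <- dim(img)[1] * dim(img)[2]
  rgb <- rbind(as.vector(img[, , 1]), as.vector(img[, , 2]), as.vector(img[, , 3]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 255)
  out <- array(0, dim = dim(img))
  out[, , 1] <- hsv[1, ] * 180   # hue in [0, 180)
  out[, , 2] <- hsv[2, ] * 255
  out[, , 3] <- hsv[3, ] * 255
  out
}

# logical H x W membership mask
.inMaskRange <- function(img, range) {
  ch <- .rangeChannels(img, range)
  d <- dim(img)[1:2]
  keep <- array(TRUE, d)
  for (k in 1:3)
    keep <- keep & array(ch[, , k] >= range$lower[k] & ch[, , k] <= range$upper[k], d)
  keep
}

#' Colour-range segmentation mask
#'
#' Keeps every pixel whose channels all lie inside the inclusive window of a
#' [maskRange()] (after conversion to the window's colorspace) and sets every
#' other pixel to 0 in all channels. The operation is idempotent in RGB mode
#' and never changes the raster's shape; masked output channel values never
#' exceed the input's.
#'
#' @param img numeric `H x W x 3` array with values in `[0, 255]`.
#' @param range a [maskRange()].
#' @return masked array, same shape as `img`, with attribute `"mask"` holding
#'   the logical `H x W` keep mask.
#' @examples
#' px <- array(c(50, 10, 50, 100, 100, 40, 100, 100, 100), c(1, 3, 3))
#' colorRangeMask(px)[1, , 1]  # 50 0 0
#' @export
colorRangeMask <- function(img, range = maskRange()) {
  d <- dim(img)
  if (length(d) != 3L || d[3] != 3L) stop("image must be H x W x 3", call. = FALSE)
  if (any(img < 0 | img > 255)) stop("pixel values must be in [0, 255]", call. = FALSE)
  keep <- .inMaskRange(img, range)
  out <- img * as.vector(keep)   # keep recycles across the 3 channel planes
  attr(out, "mask") <- keep
  out
}

#' Bilinear image resize
#'
#' Resizes a raster to a target size (default `224 x 224`) by bilinear
#' interpolation, without preserving aspect ratio.
#'
#' @param img numeric `H x W x 3` array, values in `[0, 255]`.
#' @param width,height target size in pixels.
#' @return numeric `height x width x 3` array.
#' @export
resizeImage <- function(img, width = 224L, height = 224L) {
  d <- dim(img)
  if (length(d) != 3L || d[3] != 3L || any(d[1:2] < 1L))
    stop("image must be a non-empty H x W x 3 array", call. = FALSE)
  if (d[1] == height && d[2] == width) return(img)
  im <- EBImage::Image(aperm(img, c(2L, 1L, 3L)) / 255, colormode = "Color")
  out <- EBImage::resize(im, w = width, h = height, filter = "bilinear")
  aperm(EBImage::imageData(out), c(2L, 1L, 3L)) * 255
}

#' Reproducible train/validation/test split
#'
#' Partitions item indices into 2 or 3 disjoint, exhaustive splits whose sizes
#' match the requested fractions by largest-remainder rounding. In stratified
#' mode (the default) the allocation is done per class, preserving class
#' proportions within one item per split. The same seed always yields the
#' same partition.
#'
#' @param labels vector of class labels, one per item.
#' @param fractions length-2 (`train`, `test`) or length-3 (`train`,
#'   `validation`, `test`) positive fractions summing to 1 (tolerance `1e-9`).
#' @param seed integer seed for the shuffling.
#' @param stratified preserve per-class proportions (default `TRUE`).
#' @return named list of disjoint integer index vectors (`train`,
#'   `validation` if requested, `test`).
#' @examples
#' sp <- splitDataset(rep(1:2, c(60, 40)), c(0.8, 0.2), seed = 1)
#' lengths(sp)  # 80, 20
#' @export
splitDataset <- function(labels, fractions = c(0.7, 0.15, 0.15), seed = 1L,
                         stratified = TRUE) {
  if (!length(fractions) %in% 2:3 || any(fractions <= 0))
    stop("fractions must be 2 or 3 positive numbers", call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1", call. = FALSE)
  nm <- if (length(fractions) == 2L) c("train", "test") else c("train", "validation", "test")
  n <- length(labels)
  out <- stats::setNames(rep(list(integer(0)), length(fractions)), nm)
  withr::with_seed(as.integer(seed), {
    groups <- if (stratified) split(seq_len(n), labels) else list(seq_len(n))
    for (idx in groups) {
      if (stratified && length(idx) < 1L) stop("empty class in stratified split", call. = FALSE)
      idx <- idx[sample.int(length(idx))]
      sizes <- .largestRemainder(length(idx), fractions)
      at <- cumsum(c(0L, sizes))
      for (k in seq_along(fractions))
        out[[k]] <- c(out[[k]], idx[seq_len(sizes[k]) + at[k]])
    }
  })
  lapply(out, sort)
}

# integer allocation of n items to fractions, largest remainder
.largestRemainder <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    o <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[o] <- base[o] + 1
  }
  as.integer(base)
}

#' Read and write image rasters
#'
#' Thin wrappers around EBImage I/O converting to and from the `H x W x 3`
#' 0–255 arrays used throughout the package.
#'
#' @param path PNG or JPEG file path.
#' @param img numeric `H x W x 3` array, values in `[0, 255]`.
#' @return `readImageRaster` the array; `writeImageRaster` the path, invisibly.
#' @export
readImageRaster <- function(path) {
  im <- EBImage::readImage(path)
  d <- dim(im)
  a <- EBImage::imageData(im)
  if (length(d) == 2L) a <- array(rep(a, 3L), c(d, 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3]
  aperm(a, c(2L, 1L, 3L)) * 255
}

#' @rdname readImageRaster
#' @export
writeImageRaster <- function(img, path) {
  EBImage::writeImage(EBImage::Image(aperm(img, c(2L, 1L, 3L)) / 255,
                                     colormode = "Color"), path)
  invisible(path)
}
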