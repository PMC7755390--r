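## Channel conditioning: histogram matching to a reference frame, then
## background subtraction -> Gaussian blur -> mean smoothing -> contrast
## rescale, mirroring the usual ImageJ-macro preprocessing chain.

#' Preprocessing parameters
#'
#' The conditioning chain applies, in order: rolling-ball-style background
#' subtraction, Gaussian blurring, mean-filter smoothing, and saturated
#' contrast rescaling to the full bit range.  Values are typical ImageJ
#' macro defaults; every choice is explicit and logged by the pipeline.
#'
#' @param background_radius_px Radius (px) of the disc structuring element
#'   used to estimate background (see [subtract_background()]).
#' @param blur_sigma_px Gaussian blur sigma in pixels.
#' @param smooth_kernel_px Side of the square mean filter (odd integer).
#' @param contrast_saturation_frac Fraction of pixels saturated at each tail
#'   during the final rescale (must be < 0.5).
#' @return An object of class `preproc_params`.
#' @export
preproc_params <- function(background_radius_px = 50, blur_sigma_px = 1,
                           smooth_kernel_px = 3,
                           contrast_saturation_frac = 0.003) {
  stopifnot(background_radius_px > 0, blur_sigma_px > 0,
            smooth_kernel_px > 0, contrast_saturation_frac > 0,
            contrast_saturation_frac < 0.5)
  if (smooth_kernel_px %% 2 != 1) stop("`smooth_kernel_px` must be odd")
  structure(list(background_radius_px = background_radius_px,
                 blur_sigma_px = blur_sigma_px,
                 smooth_kernel_px = smooth_kernel_px,
                 contrast_saturation_frac = contrast_saturation_frac),
            class = "preproc_params")
}

#' Match an image's histogram to a reference image
#'
#' Classic integer-level histogram specification: each gray level of the
#' input is mapped to the lowest reference level whose cumulative frequency
#' reaches the input level's cumulative frequency.  The mapping is monotone,
#' matching an image to itself is the identity, and matching twice to the
#' same reference equals matching once.
#'
#' @param image,reference [calibrated_image()]s of equal bit depth;
#'   `reference` must not be constant.
#' @return A [calibrated_image()] whose empirical CDF approximates the
#'   reference's.
#' @export
match_histogram <- function(image, reference) {
  stopifnot(is_calibrated_image(image), is_calibrated_image(reference))
  if (image$bit_depth != reference$bit_depth)
    stop("bit depths differ between image and reference")
  rpx <- round(reference$pixels)
  if (min(rpx) == max(rpx))
    stop("constant reference image: histogram mapping undefined")
  L <- 2^image$bit_depth
  ipx <- round(image$pixels)
  cdf_i <- cumsum(tabulate(ipx + 1L, nbins = L)) / length(ipx)
  cdf_r <- cumsum(tabulate(rpx + 1L, nbins = L)) / length(rpx)
  ## lowest reference level u with cdf_r[u] >= cdf_i[v], for each level v
  map <- as.integer(findInterval(cdf_i, cdf_r, left.open = TRUE))
  map <- pmin(map, L - 1L)   # 0-based gray level; map counts cdf_r < cdf_i
  out <- image
  out$pixels <- matrix(map[ipx + 1L], nrow(ipx), ncol(ipx))
  out
}

#' Background subtraction with a disc structuring element
#'
#' Estimates the background as the grayscale morphological opening of the
#' image with a disc of the given radius (the same idea as the rolling-ball
#' estimator: any plateau narrower than the disc is removed), and subtracts
#' it.  A constant image maps to all zeros.
#'
#' @param image A [calibrated_image()] or matrix.
#' @param radius_px Disc radius in pixels.
#' @return Same type as the input, background-subtracted.
#' @export
subtract_background <- function(image, radius_px) {
  px <- .px(image)
  side <- 2 * floor(radius_px) + 1
  if (side > min(dim(px))) stop("background disc larger than the image")
  top <- max(px, 1)
  bg <- EBImage::opening(px / top, EBImage::makeBrush(side, "disc")) * top
  res <- pmax(px - bg, 0)
  if (is_calibrated_image(image)) { image$pixels <- res; image } else res
}

## Mean filter with replicated edges.
.mean_filter <- function(px, k) {
  if (k > min(dim(px))) stop("smoothing kernel larger than the image")
  kern <- matrix(1 / (k * k), k, k)
  EBImage::filter2(px, kern, boundary = "replicate")
}

#' Condition a channel for segmentation
#'
#' Applies, in order: [subtract_background()], Gaussian blur, mean-filter
#' smoothing and (optionally) a saturated contrast rescale to the full bit
#' range.  Output is clipped to `[0, 2^bit_depth - 1]`.  Before the final
#' rescale the chain is linear, so scaling the input intensities scales the
#' intermediate output by the same factor.
#'
#' @param image A [calibrated_image()].
#' @param params A [preproc_params()].
#' @param rescale Apply the final contrast rescale (set `FALSE` to inspect
#'   the linear part of the chain).
#' @param method `"rescale"` (saturated percentile stretch, default) or
#'   `"equalize"` (histogram equalization).
#' @return A conditioned [calibrated_image()].
#' @export
condition_channel <- function(image, params = preproc_params(),
                              rescale = TRUE,
                              method = c("rescale", "equalize")) {
  stopifnot(is_calibrated_image(image), inherits(params, "preproc_params"))
  method <- match.arg(method)
  px <- .px(subtract_background(image, params$background_radius_px))
  px <- EBImage::gblur(px, sigma = params$blur_sigma_px,
                       boundary = "replicate")
  px <- .mean_filter(px, params$smooth_kernel_px)
  top <- 2^image$bit_depth - 1
  if (rescale) {
    if (method == "equalize") {
      r <- rank(px, ties.method = "average")
      px <- matrix((r - 1) / (length(px) - 1) * top, nrow(px), ncol(px))
    } else {
      q <- quantile(px, c(params$contrast_saturation_frac,
                          1 - params$contrast_saturation_frac), names = FALSE)
      if (q[2] > q[1]) px <- (px - q[1]) / (q[2] - q[1]) * top
      ## degenerate (near-constant) images are left unscaled
    }
  }
  image$pixels <- pmin(pmax(px, 0), top)
  image
}
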