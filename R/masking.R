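#' Mask-derivation parameters
#'
#' @param gradient_threshold_fraction gradient pixels at or above this
#'   fraction of the maximal gradient magnitude are flagged as edge
#'   (default 0.2).
#' @param min_object_area smallest connected component kept, um^2
#'   (default 0.5; removes bilayer inhomogeneities).
#' @param smoothing_sigma Gaussian pre-smoothing sigma in px before the
#'   gradient (default 1; `0` disables smoothing).
#' @param dilation_width default width (px) for the dilated control mask.
#' @return list of class `mask_params`.
#' @export
mask_params <- function(gradient_threshold_fraction = 0.2,
                        min_object_area = 0.5,
                        smoothing_sigma = 1,
                        dilation_width = 6L) {
  stopifnot(gradient_threshold_fraction > 0, gradient_threshold_fraction < 1,
            min_object_area >= 0, smoothing_sigma >= 0, dilation_width >= 0)
  structure(list(gradient_threshold_fraction = gradient_threshold_fraction,
                 min_object_area = min_object_area,
                 smoothing_sigma = smoothing_sigma,
                 dilation_width = as.integer(dilation_width)),
            class = "mask_params")
}

#' Gradient magnitude of a spacer-channel image
#'
#' Gaussian pre-smoothing followed by Sobel derivatives; returns the
#' per-pixel gradient magnitude.
#'
#' @param image 2D numeric matrix with finite values.
#' @param smoothing_sigma Gaussian sigma in px; `0` skips smoothing.
#' @return matrix of the same size.
#' @export
gradient_magnitude <- function(image, smoothing_sigma = 1) {
  if (!is.matrix(image) || length(dim(image)) != 2L)
    stop("image must be a 2D matrix")
  if (!all(is.finite(image))) stop("image must be finite")
  img <- if (smoothing_sigma > 0)
    as.matrix(EBImage::gblur(image, sigma = smoothing_sigma)) else image
  sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)  # d/dcol (x)
  sy <- t(sx)                                          # d/drow (y)
  gx <- as.matrix(EBImage::filter2(img, sx))
  gy <- as.matrix(EBImage::filter2(img, sy))
  sqrt(gx^2 + gy^2)
}

#' Segment the contact mask from a spacer-channel image
#'
#' Pixels whose gradient magnitude reaches
#' `gradient_threshold_fraction * max(gradient)` form an edge ring around
#' the contact; morphological closing and hole filling convert the ring
#' into a filled region, components smaller than `min_object_area` are
#' discarded, and the largest remaining component is returned as the
#' contact. The threshold is relative to the image's own maximal gradient,
#' so the mask is invariant to affine intensity rescaling.
#'
#' @param image 2D matrix (typically the temporal mean of the spacer
#'   channel).
#' @param params a [mask_params()] object.
#' @param pixel_size pixel edge, um/px.
#' @return A `contact_mask` on success. If nothing survives filtering, a
#'   `contact_mask` with an all-`FALSE` grid and `provenance$found = FALSE`
#'   (an explicit "no contact found" result, not an error).
#' @export
contact_mask <- function(image, params = mask_params(), pixel_size = 0.16) {
  if (!is.matrix(image)) stop("image must be a 2D matrix")
  if (!all(is.finite(image))) stop("image must be finite")
  g <- gradient_magnitude(image, params$smoothing_sigma)
  gmax <- max(g)
  prov <- list(type = "gradient_threshold", params = unclass(params),
               found = FALSE)
  no_contact <- contact_mask_from_matrix(
    matrix(FALSE, nrow(image), ncol(image)), pixel_size, provenance = prov)
  if (gmax <= 0) return(no_contact)
  bw <- g >= params$gradient_threshold_fraction * gmax
  brush <- EBImage::makeBrush(5L, shape = "disc")  # closing radius 2 px
  closed <- as.matrix(EBImage::closing(matrix(as.numeric(bw), nrow(bw)),
                                       brush)) > 0.5
  filled <- as.matrix(EBImage::fillHull(matrix(as.numeric(closed),
                                               nrow(closed)))) > 0.5
  # the thresholded gradient band straddles the true edge, so the filled
  # region's boundary sits at the band's outer rim; eroding by the closing
  # radius re-centres the boundary on the edge
  filled <- as.matrix(EBImage::erode(matrix(as.numeric(filled), nrow(filled)),
                                     brush)) > 0.5
  lab <- as.matrix(EBImage::bwlabel(matrix(as.numeric(filled), nrow(filled))))
  if (max(lab) == 0) return(no_contact)
  areas_px <- tabulate(lab[lab > 0], nbins = max(lab))
  min_px <- params$min_object_area / pixel_size^2
  keep <- which(areas_px >= min_px)
  if (length(keep) == 0) return(no_contact)
  best <- keep[which.max(areas_px[keep])]
  prov$found <- TRUE
  prov$n_components <- length(keep)
  contact_mask_from_matrix(lab == best, pixel_size, provenance = prov)
}
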