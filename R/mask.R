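#' Contact mask container
#'
#' A `contact_mask` bundles a binary pixel grid marking the cell-bilayer
#' contact with its physical pixel size, the derived boundary pixel set and
#' provenance. Images are plain matrices indexed `[row, col]`; pixel
#' `(i, j)` covers the half-open physical square
#' `[(j-1)*pixel_size, j*pixel_size) x [(i-1)*pixel_size, i*pixel_size)`
#' with x along columns and y along rows (origin top-left). A localization
#' on a mask pixel counts as inside; boundary pixels are inside.
#'
#' @param mask logical or 0/1 matrix; `TRUE` marks contact pixels.
#' @param pixel_size physical pixel edge in micrometres.
#' @param provenance free-form list recording how the mask was obtained.
#' @return An object of class `contact_mask` with elements `mask`,
#'   `pixel_size`, `boundary` (logical matrix of mask pixels with at least
#'   one non-mask 4-neighbour), `area_um2` and `provenance`.
#' @export
contact_mask_from_matrix <- function(mask, pixel_size, provenance = list()) {
  stopifnot(is.matrix(mask), pixel_size > 0)
  m <- matrix(as.logical(mask), nrow = nrow(mask))
  structure(list(
    mask = m,
    pixel_size = pixel_size,
    boundary = mask_boundary(m),
    area_um2 = sum(m) * pixel_size^2,
    provenance = provenance
  ), class = "contact_mask")
}

#' @export
print.contact_mask <- function(x, ...) {
  cat(sprintf("<contact_mask> %d x %d px (%.2f um/px), area %.2f um^2, %d boundary px\n",
              nrow(x$mask), ncol(x$mask), x$pixel_size, x$area_um2, sum(x$boundary)))
  invisible(x)
}

# mask pixels with >= 1 non-mask 4-neighbour (off-grid neighbours count as non-mask)
mask_boundary <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  up    <- pad[1:nr,         2:(nc + 1L)]
  down  <- pad[3:(nr + 2L),  2:(nc + 1L)]
  left  <- pad[2:(nr + 1L),  1:nc]
  right <- pad[2:(nr + 1L),  3:(nc + 2L)]
  m & !(up & down & left & right)
}

# pixel indices of physical points; points off grid get NA
point_to_pixel <- function(x_um, y_um, dim, pixel_size) {
  col <- floor(x_um / pixel_size) + 1L
  row <- floor(y_um / pixel_size) + 1L
  bad <- col < 1L | col > dim[2L] | row < 1L | row > dim[1L] |
    !is.finite(x_um) | !is.finite(y_um)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  list(row = row, col = col)
}

#' Test whether points fall inside a contact mask
#'
#' Points off the pixel grid count as outside.
#'
#' @param mask a `contact_mask`.
#' @param x_um,y_um point coordinates in micrometres.
#' @return logical vector.
#' @export
mask_contains <- function(mask, x_um, y_um) {
  stopifnot(inherits(mask, "contact_mask"))
  px <- point_to_pixel(x_um, y_um, dim(mask$mask), mask$pixel_size)
  inside <- rep(FALSE, length(x_um))
  ok <- !is.na(px$row)
  inside[ok] <- mask$mask[cbind(px$row[ok], px$col[ok])]
  inside
}

# Signed distance field in original-pixel units: positive outside the
# mask, negative inside. Computed on an `upsample`-times finer grid
# (nearest-neighbour upsampling preserves the pixel-membership boundary
# exactly) so that the interpolated zero level tracks the true boundary
# to a fraction of a pixel even where the edge is diagonal or curved.
mask_signed_distance <- function(mask, upsample = 4L) {
  m <- mask$mask
  u <- as.integer(upsample)
  mf <- m[rep(seq_len(nrow(m)), each = u), rep(seq_len(ncol(m)), each = u)]
  d_to_mask <- EBImage::distmap(matrix(as.numeric(!mf), nrow(mf)))  # >0 outside
  d_to_bg   <- EBImage::distmap(matrix(as.numeric(mf),  nrow(mf)))  # >0 inside
  sdf <- (as.matrix(d_to_mask) - as.matrix(d_to_bg)) / u
  attr(sdf, "upsample") <- u
  sdf
}

# Distance (um) of points to the mask edge, positive outside / negative
# inside, bilinearly interpolated from the signed pixel-distance field so
# the zero level sits on the pixel border between mask and background.
# Off-grid points: clamp to the grid and add the clamped off-grid excess.
mask_edge_distance <- function(mask, x_um, y_um, sdf = NULL) {
  if (is.null(sdf)) sdf <- mask_signed_distance(mask)
  u <- attr(sdf, "upsample"); if (is.null(u)) u <- 1L
  ps <- mask$pixel_size
  nr <- nrow(sdf); nc <- ncol(sdf)
  xc <- x_um / ps * u + 0.5  # fine-grid pixel-center coordinates (1-based)
  yc <- y_um / ps * u + 0.5
  x0 <- pmin(pmax(floor(xc), 1L), nc - 1L)
  y0 <- pmin(pmax(floor(yc), 1L), nr - 1L)
  fx <- pmin(pmax(xc - x0, 0), 1)
  fy <- pmin(pmax(yc - y0, 0), 1)
  base <- (sdf[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
           sdf[cbind(y0, x0 + 1L)] * fx * (1 - fy) +
           sdf[cbind(y0 + 1L, x0)] * (1 - fx) * fy +
           sdf[cbind(y0 + 1L, x0 + 1L)] * fx * fy) * ps
  dx <- pmax(0, -x_um, x_um - nc / u * ps)
  dy <- pmax(0, -y_um, y_um - nr / u * ps)
  base + sqrt(dx^2 + dy^2)
}

#' Dilate a contact mask and return the annulus control region
#'
#' The annulus (dilated minus original mask) is the region of free bilayer
#' surrounding the contact used as a control where no entry restriction is
#' expected.
#'
#' @param mask a `contact_mask`.
#' @param width dilation width in pixels (`>= 1`; `0` returns an empty
#'   annulus).
#' @return A `contact_mask` whose `mask` slot is the annulus. If the
#'   dilation reaches the field edge the annulus is clipped there and
#'   `provenance$clipped` is `TRUE`.
#' @export
dilate_mask <- function(mask, width) {
  stopifnot(inherits(mask, "contact_mask"), width >= 0)
  if (width == 0) {
    return(contact_mask_from_matrix(
      matrix(FALSE, nrow(mask$mask), ncol(mask$mask)), mask$pixel_size,
      provenance = list(type = "annulus", width_px = 0, clipped = FALSE)))
  }
  brush <- EBImage::makeBrush(2L * as.integer(width) + 1L, shape = "disc")
  dil <- as.matrix(EBImage::dilate(matrix(as.numeric(mask$mask), nrow(mask$mask)),
                                   brush)) > 0.5
  annulus <- dil & !mask$mask
  edge <- c(dil[1, ], dil[nrow(dil), ], dil[, 1], dil[, ncol(dil)])
  contact_mask_from_matrix(annulus, mask$pixel_size,
    provenance = list(type = "annulus", width_px = as.integer(width),
                      clipped = any(edge)))
}

#' Write a contact mask as an 8-bit TIFF plus JSON provenance
#'
#' @param mask a `contact_mask`.
#' @param path output TIFF path; provenance goes to `<path>.json`.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "contact_mask"))
  tiff::writeTIFF(matrix(as.numeric(mask$mask), nrow(mask$mask)), path,
                  bits.per.sample = 8L)
  jsonlite::write_json(
    c(list(pixel_size_um = mask$pixel_size, area_um2 = mask$area_um2),
      mask$provenance),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
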