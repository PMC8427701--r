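# Slice-wise (2D) morphological clean-up of thresholded bone masks.
# All four operators work slice by slice, mirroring 2D Fill holes /
# Remove outliers / Erode / Watershed applied to a tomogram stack.

.each_slice <- function(mask, fun) {
  out <- mask
  for (i in seq_len(dim(mask$data)[1]))
    out$data[i, , ] <- fun(mask$data[i, , ])
  out
}

#' Fill enclosed holes slice by slice
#'
#' Per slice, background regions not connected (4-connectivity) to the
#' slice border become foreground, closing solid structures such as the
#' marrow cavity before measurement.
#'
#' @param mask a [bone_mask()].
#' @return The filled `bone_mask`.
#' @export
fill_holes_2d <- function(mask) {
  stopifnot(inherits(mask, "bone_mask"))
  .each_slice(mask, function(sl) EBImage::fillHull(sl * 1L) > 0)
}

#' Remove small foreground specks slice by slice
#'
#' Per slice, foreground connected components (8-connectivity) with area
#' strictly below `min_retained` pixels are deleted (area opening). Small
#' radio-dense debris in some tomograms would otherwise be labelled and
#' measured as elements. The `radius` convenience sets
#' `min_retained = ceil(pi * radius^2)` when `min_retained` is missing.
#'
#' @param mask a [bone_mask()].
#' @param radius speck radius in px used to derive `min_retained`.
#' @param min_retained minimum component area (px) kept; components of
#'   exactly this area survive.
#' @return The cleaned `bone_mask`.
#' @export
remove_outliers_2d <- function(mask, radius = 2,
                               min_retained = ceiling(pi * radius^2)) {
  stopifnot(inherits(mask, "bone_mask"), radius >= 1)
  .each_slice(mask, function(sl) {
    lab <- EBImage::bwlabel(sl * 1L)
    if (max(lab) == 0) return(sl & FALSE)
    areas <- tabulate(lab[lab > 0], nbins = max(lab))
    keep <- which(areas >= min_retained)
    array(lab %in% keep, dim(sl))
  })
}

#' Binary erosion slice by slice
#'
#' Per-slice erosion with a 3x3 box structuring element, repeated
#' `iterations` times; `erode_2d(m, a+b)` equals
#' `erode_2d(erode_2d(m, a), b)`.
#'
#' @param mask a [bone_mask()].
#' @param iterations non-negative iteration count.
#' @return The eroded `bone_mask`.
#' @export
erode_2d <- function(mask, iterations = 1) {
  stopifnot(inherits(mask, "bone_mask"), iterations >= 0)
  if (iterations == 0) return(mask)
  brush <- EBImage::makeBrush(3, "box")
  .each_slice(mask, function(sl) {
    m <- sl * 1L
    for (k in seq_len(iterations)) m <- EBImage::erode(m, brush)
    m > 0
  })
}

#' Distance-transform watershed separation slice by slice
#'
#' Per slice: Euclidean distance transform of the foreground, regional
#' maxima merged within a plateau tolerance seed a marker flood by
#' descending distance, and 1-px lines between different markers are set to
#' background. This is what separates near-touching parallel elements
#' (radius/ulna) whose blurred boundary survives thresholding.
#'
#' @param mask a [bone_mask()].
#' @param tolerance plateau-merging tolerance on the distance value (px),
#'   default 0.5.
#' @return The separated `bone_mask`.
#' @export
watershed_separate_2d <- function(mask, tolerance = 0.5) {
  stopifnot(inherits(mask, "bone_mask"))
  .each_slice(mask, function(sl) {
    if (!any(sl)) return(sl)
    dm <- EBImage::distmap(sl * 1L)
    ws <- EBImage::watershed(dm, tolerance = tolerance, ext = 1)
    if (max(ws) <= 1) return(sl)
    # cut 1-px boundaries between distinct basins
    boundary <- .label_boundary_2d(ws)
    sl & !boundary
  })
}

# pixels whose 8-neighbourhood contains a different positive label
.label_boundary_2d <- function(lab) {
  d <- dim(lab)
  res <- matrix(FALSE, d[1], d[2])
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    r1 <- max(1, 1 + dr):min(d[1], d[1] + dr)
    r0 <- r1 - dr
    c1 <- max(1, 1 + dc):min(d[2], d[2] + dc)
    c0 <- c1 - dc
    a <- lab[r0, c0, drop = FALSE]
    b <- lab[r1, c1, drop = FALSE]
    diffm <- a > 0 & b > 0 & a != b
    res[r0, c0] <- res[r0, c0, drop = FALSE] | diffm
  }
  res & lab > 0
}

#' Standard clean-up chain
#'
#' Applies, in order: [fill_holes_2d()], [remove_outliers_2d()],
#' [erode_2d()], [watershed_separate_2d()] — the slice-wise refinement used
#' between thresholding and 3D labelling.
#'
#' @param mask a [bone_mask()].
#' @param outlier_radius speck radius (px) for [remove_outliers_2d()].
#' @param erode_iterations erosion count for [erode_2d()].
#' @param watershed_tolerance plateau tolerance for
#'   [watershed_separate_2d()].
#' @return The cleaned `bone_mask`.
#' @export
cleanup_mask <- function(mask, outlier_radius = 2, erode_iterations = 1,
                         watershed_tolerance = 0.5) {
  mask |>
    fill_holes_2d() |>
    remove_outliers_2d(radius = outlier_radius) |>
    erode_2d(iterations = erode_iterations) |>
    watershed_separate_2d(tolerance = watershed_tolerance)
}
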