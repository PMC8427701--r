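# Per-bone morphometry: inertia tensor -> principal axes -> minimum
# principal-axis-aligned bounding box -> length; maximum Feret diameter as
# the comparator estimator.

#' Extract one labelled component as a bone_component
#'
#' @param labels a [label_volume()].
#' @param label component label to extract.
#' @param bone,side canonical names attached to the record (optional).
#' @param composite logical composite flag (two bones in one component).
#' @return List of class `bone_component`: `voxels` (0-based integer
#'   coordinate matrix, columns slice/row/col), `centroid` (um),
#'   `volume_voxels`, `spacing`, plus the identity fields.
#' @export
bone_component <- function(labels, label, bone = NA_character_,
                           side = NA_character_, composite = FALSE) {
  stopifnot(inherits(labels, "label_volume"))
  lin <- which(labels$data == label)
  if (!length(lin)) stop("label ", label, " not present")
  co <- arrayInd(lin, dim(labels$data)) - 1L
  colnames(co) <- c("slice", "row", "col")
  ctr <- colMeans(co) * labels$spacing
  structure(list(label = as.integer(label), bone = bone, side = side,
                 composite = isTRUE(composite), voxels = co,
                 centroid = ctr, volume_voxels = nrow(co),
                 spacing = labels$spacing),
            class = "bone_component")
}

#' Inertia tensor and principal axes of a voxel component
#'
#' Point-mass model: each voxel contributes unit mass at its centre (in
#' um, anisotropic spacing respected). The tensor about the centroid is
#' `sum((r.r) I - r r^T)`; its eigenvectors are the principal axes and the
#' axis of the smallest moment is the long axis of an elongated bone.
#' Axes are made deterministic by orienting each eigenvector so its
#' largest-magnitude component is positive, then flipping the third axis
#' if needed for a right-handed triple.
#'
#' @param component a [bone_component()].
#' @param spacing voxel spacing um; defaults to the component's.
#' @return List of class `inertia_summary`: `tensor` (3x3, um^2 per unit
#'   mass), `eigenvalues` (ascending), `axes` (columns = unit axes, axis k
#'   paired with eigenvalue k), `degenerate` (TRUE for spheres/cubes/single
#'   voxels whose axes are not defined by the data).
#' @export
inertia_tensor <- function(component, spacing = component$spacing) {
  stopifnot(inherits(component, "bone_component"))
  r <- sweep(component$voxels, 2, c(0, 0, 0)) %*% diag(spacing)
  r <- sweep(r, 2, colMeans(r))
  n <- nrow(r)
  rr <- colSums(r^2)
  tensor <- diag(sum(rr), 3) - crossprod(r)
  if (n == 1L) {
    return(structure(list(tensor = matrix(0, 3, 3),
                          eigenvalues = c(0, 0, 0), axes = diag(3),
                          degenerate = TRUE), class = "inertia_summary"))
  }
  eig <- eigen(tensor, symmetric = TRUE)
  o <- order(eig$values)
  vals <- pmax(eig$values[o], 0)
  axes <- eig$vectors[, o, drop = FALSE]
  for (k in 1:3) {
    j <- which.max(abs(axes[, k]))
    if (axes[j, k] < 0) axes[, k] <- -axes[, k]
  }
  if (det(axes) < 0) axes[, 3] <- -axes[, 3]
  scale <- max(vals)
  degenerate <- scale <= 0 ||
    (vals[3] - vals[1]) / scale < 1e-9  # sphere/cube: all moments equal
  structure(list(tensor = tensor, eigenvalues = vals, axes = axes,
                 degenerate = degenerate),
            class = "inertia_summary")
}

# 0-based coordinates of surface voxels (some 6-neighbour missing or
# outside the component); extreme corners always belong to these
.surface_voxels <- function(voxels) {
  lo <- apply(voxels, 2, min) - 1L
  ext <- apply(voxels, 2, max) - lo + 2L       # bbox padded by 1
  stride <- c(1, ext[1], ext[1] * ext[2])
  lin <- function(m) (m[, 1] - lo[1]) + (m[, 2] - lo[2]) * stride[2] +
    (m[, 3] - lo[3]) * stride[3]
  occ <- logical(prod(ext))
  occ[lin(voxels) + 1] <- TRUE
  surf <- rep(FALSE, nrow(voxels))
  for (ax in 1:3) for (dd in c(-1L, 1L)) {
    nb <- voxels
    nb[, ax] <- nb[, ax] + dd
    surf <- surf | !occ[lin(nb) + 1]
  }
  voxels[surf, , drop = FALSE]
}

# all 8 physical corner points (um) of the given voxels
.voxel_corners <- function(voxels, spacing) {
  n <- nrow(voxels)
  corners <- as.matrix(expand.grid(c(-.5, .5), c(-.5, .5), c(-.5, .5)))
  out <- matrix(0, n * 8L, 3L)
  for (i in 1:8)
    out[((i - 1) * n + 1):(i * n), ] <-
      sweep(voxels, 2, -corners[i, ]) %*% diag(spacing)
  out
}

#' Minimum principal-axis-aligned bounding box
#'
#' For each principal axis the extent is the `[min, max]` of the
#' projections of all eight corners of every surface voxel (the support of
#' the voxel union), so axis-aligned shapes recover exact physical edge
#' lengths. `length` is the dimension along the long (smallest-moment)
#' axis. Degenerate axes (sphere-like components) fall back to the grid
#' axes and flag the result rather than guessing an orientation.
#'
#' @param component a [bone_component()].
#' @param inertia an `inertia_summary`; computed if missing.
#' @param spacing voxel spacing um.
#' @return List of class `aligned_box`: `axes`, `extents` (2x3 min/max um),
#'   `dims` (um), `length_um`, `width_um` (sorted remaining dims),
#'   `degenerate`.
#' @export
aligned_box <- function(component, inertia = inertia_tensor(component),
                        spacing = component$spacing) {
  stopifnot(inherits(component, "bone_component"))
  axes <- if (inertia$degenerate) diag(3) else inertia$axes
  surf <- .surface_voxels(component$voxels)
  pts <- .voxel_corners(surf, spacing)
  proj <- pts %*% axes
  ext <- rbind(apply(proj, 2, min), apply(proj, 2, max))
  dims <- ext[2, ] - ext[1, ]
  len <- dims[1]  # axis 1 = smallest moment = long axis
  if (inertia$degenerate) len <- max(dims)
  structure(list(axes = axes, extents = ext, dims = dims,
                 length_um = len,
                 width_um = sort(dims[-if (inertia$degenerate)
                   which.max(dims) else 1]),
                 degenerate = inertia$degenerate),
            class = "aligned_box")
}

# prune candidate diameter points: a vertex of the 3D convex hull must be a
# vertex of the 2D hull of the coplanar points in any plane containing it;
# applying grDevices::chull within constant-coordinate planes along each
# grid axis therefore preserves all hull vertices (exactness) while cutting
# the candidate set by orders of magnitude
.prune_hull_candidates <- function(pts) {
  for (ax in 1:3) {
    if (nrow(pts) <= 4) break
    groups <- split(seq_len(nrow(pts)), pts[, ax])
    keep <- unlist(lapply(groups, function(idx) {
      if (length(idx) <= 3) return(idx)
      q <- pts[idx, -ax, drop = FALSE]
      idx[unique(grDevices::chull(q[, 1], q[, 2]))]
    }), use.names = FALSE)
    pts <- pts[keep, , drop = FALSE]
  }
  unique(pts)
}

#' Maximum Feret diameter
#'
#' The longest distance between any two surface points (maximum caliper),
#' computed exactly over the corner points of surface voxels: candidates
#' are pruned to convex-hull vertices plane-by-plane, then the maximum
#' pairwise distance is taken in blocks. For oblique rods the Feret
#' diameter picks a body diagonal and so systematically exceeds the
#' aligned-box length.
#'
#' @param component a [bone_component()].
#' @param spacing voxel spacing um.
#' @return Feret diameter in um.
#' @export
feret_diameter <- function(component, spacing = component$spacing) {
  stopifnot(inherits(component, "bone_component"))
  surf <- .surface_voxels(component$voxels)
  pts <- .prune_hull_candidates(.voxel_corners(surf, spacing))
  n <- nrow(pts)
  if (n == 1) return(0)
  best <- 0
  block <- 2048L
  sq <- rowSums(pts^2)
  for (i0 in seq(1L, n, by = block)) {
    i1 <- min(i0 + block - 1L, n)
    cross <- pts[i0:i1, , drop = FALSE] %*% t(pts)
    d2 <- outer(sq[i0:i1], rep(1, n)) + outer(rep(1, i1 - i0 + 1L), sq) -
      2 * cross
    best <- max(best, max(d2))
  }
  sqrt(max(best, 0))
}

#' Measure one bone: length, widths, Feret
#'
#' Assembles inertia tensor, aligned box and Feret diameter into one tidy
#' length record. Lengths are reported in mm (the working unit for murine
#' long bones); provenance fields record the threshold and spacing so batch
#' tables remain auditable.
#'
#' @param component a [bone_component()].
#' @param spacing voxel spacing um.
#' @param specimen,batch,condition free-text batch metadata.
#' @param method method label stored in the record.
#' @param threshold_hu threshold used upstream (provenance).
#' @return One-row data.frame: specimen, batch, side, bone, composite,
#'   length_mm, feret_mm, width1_mm, width2_mm, method, condition,
#'   threshold_hu, spacing_um, degenerate.
#' @export
measure_component <- function(component, spacing = component$spacing,
                              specimen = "", batch = "", condition = "",
                              method = "aligned-box",
                              threshold_hu = NA_real_) {
  ine <- inertia_tensor(component, spacing)
  box <- aligned_box(component, ine, spacing)
  fer <- feret_diameter(component, spacing)
  data.frame(specimen = specimen, batch = batch,
             side = component$side, bone = component$bone,
             composite = component$composite,
             length_mm = box$length_um / 1000,
             feret_mm = fer / 1000,
             width1_mm = box$width_um[1] / 1000,
             width2_mm = box$width_um[2] / 1000,
             method = method, condition = condition,
             threshold_hu = threshold_hu,
             spacing_um = mean(spacing),
             degenerate = box$degenerate,
             stringsAsFactors = FALSE)
}
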