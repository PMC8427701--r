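# 3D connected components on voxel grids. Adjacency edges are built by
# vectorised coordinate offsets and partitioned with igraph; labels are then
# renumbered by first encounter in column-major scan order so the result is
# deterministic and independent of the graph library's internal ordering.

.neighbour_offsets <- function(connectivity, half = TRUE) {
  offs <- expand.grid(ds = -1:1, dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$ds == 0 & offs$dr == 0 & offs$dc == 0), ]
  if (connectivity == 6) {
    offs <- offs[abs(offs$ds) + abs(offs$dr) + abs(offs$dc) == 1, ]
  } else if (connectivity == 18) {
    offs <- offs[abs(offs$ds) + abs(offs$dr) + abs(offs$dc) <= 2, ]
  } else if (connectivity != 26) {
    stop("connectivity must be 6, 18 or 26")
  }
  if (half) {
    # one offset per unordered neighbour pair
    key <- offs$ds * 9 + offs$dr * 3 + offs$dc
    offs <- offs[key > 0, ]
  }
  as.matrix(offs)
}

# edge list (compact vertex ids) between adjacent foreground voxels
.adjacency_edges <- function(data, fg_lin, connectivity) {
  d <- dim(data)
  idmap <- array(0L, d)
  idmap[fg_lin] <- seq_along(fg_lin)
  co <- arrayInd(fg_lin, d)
  offs <- .neighbour_offsets(connectivity)
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(offs))) {
    s <- co[, 1] + offs[k, 1]; r <- co[, 2] + offs[k, 2]
    c <- co[, 3] + offs[k, 3]
    ok <- s >= 1 & s <= d[1] & r >= 1 & r <= d[2] & c >= 1 & c <= d[3]
    if (!any(ok)) next
    nb <- idmap[cbind(s[ok], r[ok], c[ok])]
    hit <- nb > 0L
    from <- c(from, which(ok)[hit])
    to <- c(to, nb[hit])
  }
  cbind(from, to)
}

#' Label 3D connected components
#'
#' Partitions the foreground into connected components under 6-, 18- or
#' 26-connectivity and assigns labels 1..k by first encounter in
#' column-major scan order (slice index fastest), so repeated runs and
#' reimplementations agree voxel for voxel.
#'
#' @param mask a [bone_mask()].
#' @param connectivity 6, 18 or 26 (default 26; two voxels sharing only a
#'   corner are connected at 26 but not at 6).
#' @return A [label_volume()].
#' @export
label_components_3d <- function(mask, connectivity = 26) {
  stopifnot(inherits(mask, "bone_mask"))
  d <- dim(mask$data)
  lab <- array(0L, d)
  fg <- which(mask$data)
  if (!length(fg)) return(label_volume(lab, mask$spacing))
  edges <- .adjacency_edges(mask$data, fg, connectivity)
  g <- igraph::make_graph(t(edges), n = length(fg), directed = FALSE)
  memb <- igraph::components(g)$membership
  # renumber by first encounter: fg is ascending linear index already
  first <- !duplicated(memb)
  relabel <- integer(max(memb))
  relabel[memb[first]] <- seq_len(sum(first))
  lab[fg] <- relabel[memb]
  label_volume(lab, mask$spacing)
}

#' Drop components below a voxel-count floor
#'
#' Removes labelled components with fewer than `min_voxels` voxels and
#' renumbers the survivors 1..k preserving their order. Whole-body scans
#' segment hundreds of elements; a volume floor removes debris and
#' ossification specks before landmark resolution.
#'
#' @param labels a [label_volume()].
#' @param min_voxels minimum voxel count retained (components of exactly
#'   `min_voxels` survive). See [default_min_voxels()] for the
#'   spacing-scaled default used by the pipeline.
#' @return A filtered [label_volume()].
#' @export
filter_by_volume <- function(labels, min_voxels) {
  stopifnot(inherits(labels, "label_volume"), min_voxels >= 0)
  if (labels$n_labels == 0L || min_voxels == 0) return(labels)
  sizes <- tabulate(labels$data[labels$data > 0L], nbins = labels$n_labels)
  keep <- which(sizes >= min_voxels)
  relabel <- integer(labels$n_labels)
  relabel[keep] <- seq_along(keep)
  out <- labels
  pos <- labels$data > 0L
  out$data[pos] <- relabel[labels$data[pos]]
  out$n_labels <- length(keep)
  out
}

#' Spacing-scaled default component-volume floor
#'
#' 1000 voxels at 20 um isotropic spacing, scaled by voxel volume so the
#' physical floor (8e6 um^3, clavicle-sized elements survive) is resolution
#' independent.
#'
#' @param spacing voxel spacing in um (length 3 or 1).
#' @return Minimum voxel count (numeric).
#' @export
default_min_voxels <- function(spacing) {
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  1000 * 20^3 / prod(spacing)
}

#' Grow the connected region containing a seed
#'
#' Flood fill of the foreground component containing `seed`, the
#' non-interactive equivalent of a region-grow click on a thresholded mask.
#'
#' @param mask a [bone_mask()].
#' @param seed voxel coordinate `c(slice, row, col)`, 0-based.
#' @param connectivity 6, 18 or 26.
#' @return Integer matrix of 0-based voxel coordinates (columns slice, row,
#'   col), one row per voxel of the component, in scan order.
#' @export
region_grow <- function(mask, seed, connectivity = 26) {
  stopifnot(inherits(mask, "bone_mask"))
  seed <- as.integer(seed) + 1L
  d <- dim(mask$data)
  if (length(seed) != 3L || any(seed < 1L) || any(seed > d))
    stop("seed out of grid bounds")
  if (!mask$data[seed[1], seed[2], seed[3]])
    stop("seed not on bone: voxel (", paste(seed - 1L, collapse = ","),
         ") is background")
  labs <- label_components_3d(mask, connectivity)
  target <- labs$data[seed[1], seed[2], seed[3]]
  co <- arrayInd(which(labs$data == target), d)
  colnames(co) <- c("slice", "row", "col")
  co - 1L
}
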