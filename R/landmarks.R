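#' Canonical bone names
#' @return Character vector of the long-bone names the pipeline recognises.
#' @export
canonical_bones <- function() {
  c("HUMERUS", "RADIUS", "ULNA", "FEMUR", "TIBIA", "FIBULA", "CLAVICLE")
}

#' Build a landmark table
#'
#' One record per bone of interest: the declarative replacement for the
#' interactive select/skip landmarking loop. `present = FALSE` records a
#' skip (bone absent from the scan); its seed is ignored.
#'
#' @param bone character, names from [canonical_bones()].
#' @param side character, `"LEFT"`, `"RIGHT"` or `NA`.
#' @param slice,row,col 0-based seed voxel coordinates.
#' @param present logical, default `TRUE`.
#' @return A data.frame of class `landmark_set`.
#' @export
landmarks <- function(bone, side = NA_character_, slice, row, col,
                      present = TRUE) {
  bone <- toupper(as.character(bone))
  bad <- setdiff(unique(bone), canonical_bones())
  if (length(bad))
    stop("unknown bone name(s): ", paste(bad, collapse = ", "))
  side <- toupper(as.character(side))
  side[!side %in% c("LEFT", "RIGHT")] <- NA_character_
  df <- data.frame(bone = bone, side = side,
                   slice = as.integer(slice), row = as.integer(row),
                   col = as.integer(col), present = as.logical(present),
                   stringsAsFactors = FALSE)
  key <- paste(df$bone, df$side)
  if (anyDuplicated(key))
    stop("duplicate (bone, side) landmark: ", key[duplicated(key)][1])
  class(df) <- c("landmark_set", "data.frame")
  df
}

#' Read / write landmark files
#'
#' Plain CSV with columns `bone, side, present, slice, row, col`
#' (0-based seed coordinates).
#'
#' @param path file path.
#' @return `read_landmarks` returns a `landmark_set`.
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("bone", "side", "present", "slice", "row", "col")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("landmark file lacks column(s): ", paste(miss, collapse = ", "))
  landmarks(df$bone, df$side, df$slice, df$row, df$col, df$present)
}

#' @rdname read_landmarks
#' @param lm a `landmark_set`.
#' @export
write_landmarks <- function(lm, path) {
  utils::write.csv(
    lm[, c("bone", "side", "present", "slice", "row", "col")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resolve landmarks to labelled components
#'
#' Maps each present landmark to the component containing its seed. If two
#' landmarks resolve to one component the label is flagged composite (the
#' near-touching pair was segmented together, e.g. radius+ulna) with a
#' warning; such elements are measured as-is and flagged rather than
#' force-split. Skipped landmarks are omitted. The result is independent of
#' landmark order.
#'
#' @param labels a [label_volume()].
#' @param lm a `landmark_set`.
#' @param review if `TRUE`, print one line per landmark resolution so the
#'   assignment can be audited.
#' @return A list of class `bone_label_map`: `entries` (data.frame `label`,
#'   `bone`, `side`, `composite`) and `composite_flags` (labels claimed by
#'   more than one landmark).
#' @export
assign_labels <- function(labels, lm, review = FALSE) {
  stopifnot(inherits(labels, "label_volume"), inherits(lm, "landmark_set"))
  if (!nrow(lm)) stop("landmark set is empty")
  lm <- lm[order(lm$bone, lm$side), , drop = FALSE]  # order independence
  d <- dim(labels$data)
  act <- lm[lm$present, , drop = FALSE]
  lab_of <- integer(nrow(act))
  for (i in seq_len(nrow(act))) {
    s <- act$slice[i] + 1L; r <- act$row[i] + 1L; c <- act$col[i] + 1L
    if (s < 1 || s > d[1] || r < 1 || r > d[2] || c < 1 || c > d[3])
      stop("seed for ", act$bone[i], " out of grid bounds")
    v <- labels$data[s, r, c]
    if (v == 0L)
      stop("seed not on bone for ", paste(act$side[i], act$bone[i]),
           " at (", act$slice[i], ",", act$row[i], ",", act$col[i], ")")
    lab_of[i] <- v
    if (review)
      cat(sprintf("%-6s %-8s -> component %d\n",
                  ifelse(is.na(act$side[i]), "", act$side[i]),
                  act$bone[i], v))
  }
  dup <- unique(lab_of[duplicated(lab_of)])
  if (length(dup)) {
    for (v in dup) {
      members <- paste(paste(act$side[lab_of == v], act$bone[lab_of == v]),
                       collapse = " + ")
      warning("component ", v, " is composite: ", members,
              " segmented together", call. = FALSE)
    }
  }
  entries <- data.frame(label = lab_of, bone = act$bone, side = act$side,
                        composite = lab_of %in% dup,
                        stringsAsFactors = FALSE)
  structure(list(entries = entries, composite_flags = dup),
            class = "bone_label_map")
}

#' @export
print.bone_label_map <- function(x, ...) {
  cat("bone_label_map:", nrow(x$entries), "landmarks,",
      length(x$composite_flags), "composite label(s)\n")
  print(x$entries)
  invisible(x)
}

# erosion-depth distance on a 3D foreground: number of 26-neighbour
# erosions a voxel survives; a cheap chebyshev-metric distance transform
.erosion_depth <- function(data) {
  depth <- array(0L, dim(data))
  cur <- data
  k <- 0L
  while (any(cur)) {
    k <- k + 1L
    depth[cur] <- k
    cur <- .erode26(cur)
  }
  depth
}

# 26-neighbour (box) erosion: separable AND over the three axes
.erode26 <- function(m) {
  for (ax in 1:3)
    m <- m & .shift3(m, ax, 1L, FALSE) & .shift3(m, ax, -1L, FALSE)
  m
}

.shift3 <- function(m, axis, by, fill = FALSE) {
  d <- dim(m)
  out <- array(fill, d)
  idx_src <- idx_dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  n <- d[axis]
  if (abs(by) >= n) return(out)
  if (by > 0) { idx_dst[[axis]] <- (1 + by):n; idx_src[[axis]] <- 1:(n - by) }
  else { idx_dst[[axis]] <- 1:(n + by); idx_src[[axis]] <- (1 - by):n }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

#' Split one fused component with seed groups
#'
#' Algorithmic stand-in for manual plane-based mask splitting: a
#' marker-driven 3D watershed on the component's distance transform.
#' Markers are the user's seed groups; voxels are flooded in order of
#' decreasing distance-to-background and the 1-voxel boundary where
#' competing markers meet is removed. Exact parity with interactive
#' splitting is not claimed — the contract is that each output part
#' contains its own seeds and the cut falls in the low-thickness bridge.
#'
#' @param mask a [bone_mask()].
#' @param seed_groups list of >= 2 matrices/vectors of 0-based seed
#'   coordinates (slice, row, col), one group per desired part.
#' @param connectivity 6, 18 or 26.
#' @return A `bone_mask` with the boundary voxels removed so the parts are
#'   disconnected.
#' @export
split_component <- function(mask, seed_groups, connectivity = 26) {
  stopifnot(inherits(mask, "bone_mask"), is.list(seed_groups))
  d <- dim(mask$data)
  seeds <- lapply(seed_groups, function(g) {
    g <- matrix(as.integer(g), ncol = 3) + 1L
    if (any(g < 1L) || any(g[, 1] > d[1] | g[, 2] > d[2] | g[, 3] > d[3]))
      stop("seed out of bounds")
    g
  })
  if (length(seeds) < 2) return(mask)
  labs <- label_components_3d(mask, connectivity)
  comp_ids <- vapply(seeds, function(g) {
    ids <- labs$data[g]
    if (any(ids == 0L)) stop("seed not on bone")
    if (length(unique(ids)) > 1) stop("seeds of one group span components")
    ids[1]
  }, integer(1))
  if (length(unique(comp_ids)) > 1)
    stop("seed groups lie in different components; nothing to split")
  comp <- labs$data == comp_ids[1]

  depth <- .erosion_depth(comp)
  marker <- array(0L, d)                 # 0 unassigned, -1 boundary, else part
  for (i in seq_along(seeds)) marker[seeds[[i]]] <- i

  offs <- .neighbour_offsets(connectivity, half = FALSE)

  # neighbour marker summary for a set of voxel linear indices:
  # first claimed marker and whether a second, different one also claims
  claims <- function(lin) {
    co <- arrayInd(lin, d)
    first <- integer(length(lin)); conflict <- logical(length(lin))
    for (k in seq_len(nrow(offs))) {
      s <- co[, 1] + offs[k, 1]; r <- co[, 2] + offs[k, 2]
      c2 <- co[, 3] + offs[k, 3]
      ok <- s >= 1 & s <= d[1] & r >= 1 & r <= d[2] & c2 >= 1 & c2 <= d[3]
      nb <- integer(length(lin))
      nb[ok] <- marker[cbind(s[ok], r[ok], c2[ok])]
      hit <- nb > 0L
      conflict <- conflict | (hit & first > 0L & nb != first)
      take <- hit & first == 0L
      first[take] <- nb[take]
    }
    list(first = first, conflict = conflict)
  }

  # bucketed priority flood, depth levels high -> low: connected plateaus
  # touching one marker are assigned wholesale; contested regions are
  # resolved wavefront-style so the cut falls where competing floods meet
  for (lev in seq(max(depth), 1L)) {
    un <- which(comp & depth >= lev & marker == 0L)
    if (!length(un)) next
    sub <- array(FALSE, d); sub[un] <- TRUE
    edges <- .adjacency_edges(sub, un, connectivity)
    g <- igraph::make_graph(t(edges), n = length(un), directed = FALSE)
    memb <- igraph::components(g)$membership
    cl <- claims(un)
    # markers touched per sub-component
    touch <- unique(data.frame(comp = memb[cl$first > 0L],
                               m = cl$first[cl$first > 0L]))
    conf_comp <- unique(c(memb[cl$conflict],
                          touch$comp[duplicated(touch$comp)]))
    single <- touch[!(touch$comp %in% conf_comp), , drop = FALSE]
    for (j in seq_len(nrow(single)))
      marker[un[memb == single$comp[j]]] <- single$m[j]
    # contested: grow all markers one wave at a time inside the region
    for (cc in conf_comp) {
      vox <- un[memb == cc]
      repeat {
        open <- vox[marker[vox] == 0L]
        if (!length(open)) break
        cl2 <- claims(open)
        newly <- cl2$first > 0L
        if (!any(newly)) break
        marker[open[newly & !cl2$conflict]] <-
          cl2$first[newly & !cl2$conflict]
        marker[open[newly & cl2$conflict]] <- -1L
      }
    }
  }
  # demote one side of any residual adjacent different-marker pair
  half <- .neighbour_offsets(connectivity, half = TRUE)
  pos <- which(marker > 0L)
  co <- arrayInd(pos, d)
  for (k in seq_len(nrow(half))) {
    s <- co[, 1] + half[k, 1]; r <- co[, 2] + half[k, 2]
    c2 <- co[, 3] + half[k, 3]
    ok <- s >= 1 & s <= d[1] & r >= 1 & r <= d[2] & c2 >= 1 & c2 <= d[3]
    nb <- integer(length(pos))
    nb[ok] <- marker[cbind(s[ok], r[ok], c2[ok])]
    bad <- nb > 0L & marker[pos] > 0L & nb != marker[pos]
    if (any(bad)) {
      a <- pos[bad]
      b <- as.integer((cbind(s[bad], r[bad], c2[bad]) - 1L) %*%
                        c(1, d[1], d[1] * d[2]) + 1L)
      seed_lin <- unlist(lapply(seeds, function(g)
        as.integer((g - 1L) %*% c(1, d[1], d[1] * d[2]) + 1L)))
      lower <- ifelse(depth[a] <= depth[b], a, b)
      lower[lower %in% seed_lin] <- ifelse(lower[lower %in% seed_lin] == a[lower %in% seed_lin],
                                           b[lower %in% seed_lin],
                                           a[lower %in% seed_lin])
      marker[lower] <- -1L
    }
  }
  out <- mask
  out$data <- mask$data & !(marker == -1L)
  out
}
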