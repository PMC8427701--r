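# Batch reporting: the measurement-table dialect ("RIGHT HUMERUS,7.415"),
# merge/clean of batch tables, left/right and intra-limb ratios, and
# cross-batch coefficient of variation.

.bone_label <- function(side, bone, composite = FALSE) {
  lab <- ifelse(is.na(side) | side == "", bone, paste(side, bone))
  # composite elements carry both names, e.g. "RIGHT TIBIA+FIBULA"
  lab
}

#' Export a measurement table in the per-bone CSV dialect
#'
#' One line per bone, `"<SIDE> <BONE>,<length_mm>"` with three decimal
#' places (e.g. `"RIGHT HUMERUS,7.415"`). A composite element keeps one
#' line under its combined name (`"RIGHT TIBIA+FIBULA"`). The full record
#' set, including metadata columns, goes to a companion tidy CSV when
#' `tidy_path` is given.
#'
#' @param table data.frame of measurement records (see
#'   [measure_component()]).
#' @param path optional output file for the dialect lines.
#' @param tidy_path optional output file for the tidy table with header.
#' @return Character vector of dialect lines, invisibly if `path` given.
#' @export
export_csv <- function(table, path = NULL, tidy_path = NULL) {
  if (!nrow(table)) stop("empty measurement table")
  name <- .bone_label(table$side, table$bone)
  lines <- sprintf("%s,%.3f", name, table$length_mm)
  if (!is.null(tidy_path))
    utils::write.csv(table, tidy_path, row.names = FALSE)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Parse the per-bone CSV dialect back into a table
#'
#' Inverse of [export_csv()] for the dialect lines: recovers side, bone
#' (composite names split on `+` are kept joined in `bone`), and length.
#'
#' @param lines character vector of `"SIDE BONE,length"` lines, or a file
#'   path.
#' @return data.frame with `side`, `bone`, `composite`, `length_mm`.
#' @export
parse_csv <- function(lines) {
  if (length(lines) == 1 && file.exists(lines)) lines <- readLines(lines)
  parts <- strsplit(lines, ",", fixed = TRUE)
  bad <- lengths(parts) != 2
  if (any(bad)) stop("malformed line(s): ", lines[bad][1])
  name <- vapply(parts, `[[`, "", 1)
  len <- as.numeric(vapply(parts, `[[`, "", 2))
  side <- rep(NA_character_, length(name))
  bone <- name
  has_side <- grepl("^(LEFT|RIGHT) ", name)
  side[has_side] <- sub(" .*", "", name[has_side])
  bone[has_side] <- sub("^(LEFT|RIGHT) ", "", name[has_side])
  data.frame(side = side, bone = bone, composite = grepl("+", bone, fixed = TRUE),
             length_mm = len, stringsAsFactors = FALSE)
}

#' Merge and clean batch measurement tables
#'
#' Drops rows whose bone label is not in the canonical list, sorts the
#' survivors alphabetically by their `"SIDE BONE"` label, and binds tables
#' together with a `batch` identifier — the table-hygiene stage between
#' per-scan export and batch statistics.
#'
#' @param tables a single data.frame or list of data.frames sharing the
#'   measurement schema.
#' @param canonical vector of bone names to keep (composite names match on
#'   either member); default [canonical_bones()].
#' @param batch_ids batch labels, one per table; defaults to 1..n.
#' @return The merged, cleaned, sorted data.frame.
#' @export
merge_and_clean <- function(tables, canonical = canonical_bones(),
                            batch_ids = NULL) {
  if (is.data.frame(tables)) tables <- list(tables)
  if (!length(canonical)) stop("canonical bone list is empty")
  if (is.null(batch_ids)) batch_ids <- seq_along(tables)
  stopifnot(length(batch_ids) == length(tables))
  out <- do.call(rbind, lapply(seq_along(tables), function(i) {
    t <- tables[[i]]
    if (is.null(t$batch) || all(t$batch == "" | is.na(t$batch)))
      t$batch <- batch_ids[i]
    t
  }))
  members <- strsplit(out$bone, "+", fixed = TRUE)
  keep <- vapply(members, function(m) any(m %in% canonical), TRUE)
  out <- out[keep, , drop = FALSE]
  if (!nrow(out)) stop("no rows of interest survive the canonical filter")
  out <- out[order(.bone_label(out$side, out$bone), out$batch), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Left/right length ratios
#'
#' Per (specimen, batch, bone): left length / right length — the internal
#' consistency readout, with 1 the value expected for equally long paired
#' bones and deviations the signature of asymmetry phenotypes. Pairs with a
#' missing side are omitted with a warning.
#'
#' @param table merged measurement table.
#' @return data.frame `specimen`, `batch`, `bone`, `left_mm`, `right_mm`,
#'   `lr_ratio`.
#' @export
lr_ratio <- function(table) {
  groups <- split(table, list(table$specimen, table$batch, table$bone),
                  drop = TRUE)
  rows <- lapply(groups, function(g) {
    l <- g$length_mm[g$side == "LEFT"]
    r <- g$length_mm[g$side == "RIGHT"]
    if (length(l) != 1 || length(r) != 1) {
      warning("L/R pair incomplete for ", g$bone[1], " (specimen ",
              g$specimen[1], ", batch ", g$batch[1], "); row omitted",
              call. = FALSE)
      return(NULL)
    }
    data.frame(specimen = g$specimen[1], batch = g$batch[1],
               bone = g$bone[1], left_mm = l, right_mm = r,
               lr_ratio = l / r, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(specimen = character(), batch = character(),
                      bone = character(), left_mm = numeric(),
                      right_mm = numeric(), lr_ratio = numeric())
  rownames(out) <- NULL
  out
}

#' Intra-limb length ratios (humerus/radius, femur/tibia)
#'
#' Per (specimen, batch, side): H/R and F/T — the normalisation usable when
#' contralateral bones are unavailable. A composite-flagged member (e.g.
#' radius fused with ulna) disqualifies its ratio with a warning, since the
#' composite length is not the lone bone's.
#'
#' @param table merged measurement table.
#' @return data.frame `specimen`, `batch`, `side`, `ratio` (`"H/R"` or
#'   `"F/T"`), `value`.
#' @export
intralimb_ratio <- function(table) {
  pairs <- list(c("HUMERUS", "RADIUS", "H/R"), c("FEMUR", "TIBIA", "F/T"))
  groups <- split(table, list(table$specimen, table$batch, table$side),
                  drop = TRUE)
  rows <- list()
  for (g in groups) {
    for (p in pairs) {
      num <- g[g$bone == p[1], , drop = FALSE]
      den <- g[g$bone == p[2], , drop = FALSE]
      if (nrow(num) != 1 || nrow(den) != 1) {
        if (nrow(num) + nrow(den) > 0)
          warning(p[3], " omitted for specimen ", g$specimen[1], " side ",
                  g$side[1], ": member missing", call. = FALSE)
        next
      }
      if (isTRUE(num$composite) || isTRUE(den$composite)) {
        warning(p[3], " omitted for specimen ", g$specimen[1], " side ",
                g$side[1], ": composite member cannot enter the ratio",
                call. = FALSE)
        next
      }
      rows[[length(rows) + 1L]] <-
        data.frame(specimen = g$specimen[1], batch = g$batch[1],
                   side = g$side[1], ratio = p[3],
                   value = num$length_mm / den$length_mm,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(specimen = character(), batch = character(),
                      side = character(), ratio = character(),
                      value = numeric())
  rownames(out) <- NULL
  out
}

#' Coefficient of variation across batches
#'
#' Per (specimen, side, bone, condition): `100 * SD / mean` of the length
#' over batches, the repeatability readout for repeated scans of one
#' specimen. Sample SD (n-1 denominator) by default — material at three
#' batches — switchable to the population formula.
#'
#' @param table merged measurement table with >= 2 batches per group.
#' @param sd_type `"sample"` (n-1) or `"population"` (n).
#' @return data.frame `specimen`, `side`, `bone`, `condition`,
#'   `mean_mm`, `cv_percent`, `n_batches`.
#' @export
cv_across_batches <- function(table, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (is.null(table$condition)) table$condition <- ""
  groups <- split(table,
                  list(table$specimen, table$side, table$bone,
                       table$condition), drop = TRUE)
  rows <- lapply(groups, function(g) {
    n <- length(unique(g$batch))
    if (n < 2) {
      warning("CV omitted for ", .bone_label(g$side[1], g$bone[1]),
              " (specimen ", g$specimen[1], "): single batch", call. = FALSE)
      return(NULL)
    }
    x <- g$length_mm
    s <- stats::sd(x)
    if (sd_type == "population") s <- s * sqrt((length(x) - 1) / length(x))
    data.frame(specimen = g$specimen[1], side = g$side[1], bone = g$bone[1],
               condition = g$condition[1], mean_mm = mean(x),
               cv_percent = 100 * s / mean(x), n_batches = n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(specimen = character(), side = character(),
                      bone = character(), condition = character(),
                      mean_mm = numeric(), cv_percent = numeric(),
                      n_batches = integer())
  rownames(out) <- NULL
  out
}
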