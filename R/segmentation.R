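#' Intensity histogram of a volume
#'
#' Equal-width histogram over `[min, max]` of the data with the rightmost
#' bin closed, the probability basis for entropy-based threshold selection.
#' A constant volume yields a single occupied bin; threshold selection
#' rejects that downstream.
#'
#' @param volume a [ct_volume()] (typically in HU).
#' @param n_bins number of bins, default 256 (the ImageJ convention for
#'   data deeper than 8 bits).
#' @return A list of class `hu_histogram` with `bin_edges` (`n_bins + 1`
#'   monotone values) and `counts` (`n_bins` non-negative integers).
#' @export
compute_histogram <- function(volume, n_bins = 256) {
  stopifnot(inherits(volume, "ct_volume"), n_bins >= 1)
  x <- as.numeric(volume$data)
  if (!length(x)) stop("empty volume")
  lo <- min(x); hi <- max(x)
  if (hi == lo) {
    edges <- lo + seq(0, n_bins) * (if (lo == 0) 1 else abs(lo) * 1e-9 + 1e-12)
    counts <- c(length(x), rep(0L, n_bins - 1L))
  } else {
    edges <- seq(lo, hi, length.out = n_bins + 1)
    idx <- pmin(floor((x - lo) / (hi - lo) * n_bins) + 1L, n_bins)
    counts <- tabulate(idx, nbins = n_bins)
  }
  structure(list(bin_edges = edges, counts = as.integer(counts)),
            class = "hu_histogram")
}

#' Maximum-entropy (Kapur) threshold
#'
#' Selects the threshold maximising the sum of Shannon entropies of the
#' background and foreground gray-level distributions (Kapur's criterion),
#' the classic histogram-entropy segmentation used for bone/soft-tissue
#' separation in low-contrast stacks. Entropies use natural logarithms with
#' `0 * log 0 := 0`; only splits giving both classes positive probability
#' are considered; ties break to the lowest qualifying split.
#'
#' @param hist a `hu_histogram` from [compute_histogram()], with at least
#'   two occupied bins.
#' @return The threshold as the lower edge of the first foreground bin
#'   (same units as the histogram, i.e. HU).
#' @export
max_entropy_threshold <- function(hist) {
  stopifnot(inherits(hist, "hu_histogram"))
  counts <- as.numeric(hist$counts)
  n <- length(counts)
  if (sum(counts > 0) < 2) stop("degenerate histogram: <2 occupied bins")
  p <- counts / sum(counts)
  P <- cumsum(p)                      # P[t] = background mass of split t
  plogp <- ifelse(p > 0, p * log(p), 0)
  S <- cumsum(plogp)
  total_S <- S[n]
  t <- seq_len(n - 1L)                # split after bin t (1-based)
  P0 <- P[t]; P1 <- 1 - P0
  ok <- P0 > 0 & P1 > 0
  Hb <- ifelse(ok, log(P0) - S[t] / P0, -Inf)
  Hf <- ifelse(ok, log(P1) - (total_S - S[t]) / P1, -Inf)
  crit <- Hb + Hf
  tstar <- which.max(crit)            # which.max returns first (lowest) max
  hist$bin_edges[tstar + 1L]
}

.preset_env <- new.env(parent = emptyenv())

#' Threshold preset table
#'
#' Ships the benchmarked stage-specific lower thresholds: for the
#' Mimics-style profile 650/398 HU (P7 high/low) and 398/226 HU (E17.5
#' high/low); for the BoneJ-style profile 500/385 HU (P7) and 400/280 HU
#' (E17.5). Each stage's `medium` is the rounded midpoint of its low/high
#' pair so presets are strictly ordered within a stage; all values are
#' user-editable via `options(osteobox.presets = <data.frame>)` or a custom
#' table passed to [preset_threshold()].
#'
#' @return data.frame with columns `stage`, `level`, `profile`, `hu`.
#' @export
threshold_presets <- function() {
  opt <- getOption("osteobox.presets")
  if (!is.null(opt)) return(opt)
  if (is.null(.preset_env$table)) {
    path <- system.file("extdata", "threshold_presets.csv",
                        package = "osteobox", mustWork = TRUE)
    .preset_env$table <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  .preset_env$table
}

#' Look up a preset lower threshold
#'
#' @param stage developmental stage label, e.g. `"P7"` or `"E17.5"`.
#' @param level one of `"low"`, `"medium"`, `"high"`.
#' @param profile preset profile, `"mimics-style"` or `"bonej-style"`.
#' @param table optional preset table overriding [threshold_presets()].
#' @return The configured HU value.
#' @examples
#' preset_threshold("P7", "high", "mimics-style")  # 650
#' @export
preset_threshold <- function(stage, level = c("low", "medium", "high"),
                             profile = "mimics-style", table = NULL) {
  level <- match.arg(level)
  tab <- if (is.null(table)) threshold_presets() else table
  hit <- tab$stage == stage & tab$level == level & tab$profile == profile
  if (sum(hit) != 1)
    stop("no preset for (", stage, ", ", level, ", ", profile,
         "); available: ",
         paste(unique(paste(tab$stage, tab$level, tab$profile, sep = "/")),
               collapse = ", "))
  tab$hu[hit]
}

#' Global threshold to a binary bone mask
#'
#' Keeps voxels with `lower <= value <= upper` (lower bound inclusive).
#' A single global HU threshold is used deliberately: local/adaptive
#' schemes trade reproducibility for contrast handling, and batch
#' comparability across scans is the design goal here.
#'
#' @param volume a [ct_volume()] in HU.
#' @param lower lower threshold (HU), inclusive.
#' @param upper upper threshold (HU), inclusive; default `Inf`.
#' @return A [bone_mask()].
#' @export
apply_threshold <- function(volume, lower, upper = Inf) {
  stopifnot(inherits(volume, "ct_volume"))
  if (!(lower < upper)) stop("'lower' must be < 'upper'")
  bone_mask(volume$data >= lower & volume$data <= upper, volume$spacing)
}
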