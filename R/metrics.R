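# Evaluation metrics in physical units (DSC, Hausdorff distance, mean
# surface distance) and the paired statistics used to compare approaches.

#' Dice similarity coefficient of two crisp masks
#'
#' `2|a&b| / (|a| + |b|)`; defined as 1 when both masks are empty.
#'
#' @param a,b logical/0-1 3D arrays of the same shape.
#' @return A unitless value in `[0, 1]`.
#' @export
dsc <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  a <- a > 0; b <- b > 0
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}

#' Surface voxels of a mask
#'
#' Mask voxels with at least one face-adjacent (6-connectivity) background
#' neighbour; the volume border counts as background.
#'
#' @param mask logical/0-1 3D array.
#' @return Logical array marking surface voxels (use `which(..., arr.ind =
#'   TRUE)` for coordinates).
#' @export
surfaceVoxels <- function(mask) {
  mask <- mask > 0
  d <- dim(mask)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  core <- function(sx, sy, sz)
    pad[(2:(d[1] + 1)) + sx, (2:(d[2] + 1)) + sy, (2:(d[3] + 1)) + sz]
  has_bg <- !core(1, 0, 0) | !core(-1, 0, 0) |
            !core(0, 1, 0) | !core(0, -1, 0) |
            !core(0, 0, 1) | !core(0, 0, -1)
  mask & has_bg
}

# directed surface distances (mm) from every surface voxel of `from` to the
# nearest surface voxel of `to`, via the anisotropic distance transform
.directed_surface_distances <- function(from, to, spacing) {
  sf <- surfaceVoxels(from)
  st <- surfaceVoxels(to)
  d2 <- .edt3d_sq(st, dim(st), as.numeric(spacing))
  sqrt(d2[sf])
}

#' Hausdorff distance between two masks
#'
#' The full (100th percentile) symmetric Hausdorff distance between the
#' surface voxel centres of the two masks, in mm with anisotropic spacing.
#'
#' @param a,b non-empty logical/0-1 3D arrays on the same grid.
#' @param spacing numeric(3), mm.
#' @return Distance in mm.
#' @export
hausdorffDistance <- function(a, b, spacing = c(1, 1, 1)) {
  if (!any(a > 0) || !any(b > 0))
    stop("hausdorffDistance: both masks must be non-empty")
  max(max(.directed_surface_distances(a, b, spacing)),
      max(.directed_surface_distances(b, a, spacing)))
}

#' Mean surface distance between two masks
#'
#' Symmetric average of the two directed mean surface-to-surface
#' distances, in mm.
#'
#' @inheritParams hausdorffDistance
#' @return Distance in mm.
#' @export
meanSurfaceDistance <- function(a, b, spacing = c(1, 1, 1)) {
  if (!any(a > 0) || !any(b > 0))
    stop("meanSurfaceDistance: both masks must be non-empty")
  (mean(.directed_surface_distances(a, b, spacing)) +
     mean(.directed_surface_distances(b, a, spacing))) / 2
}

#' Per-structure metric rows for one case
#'
#' Compares a hardened prediction against ground truth for every
#' foreground structure, returning one row per structure with DSC, HD (mm)
#' and MSD (mm). An empty predicted or true structure still yields the DSC
#' but flags HD/MSD as missing (NA).
#'
#' @param truth,pred LabelVolumes on the same grid.
#' @param seriesId identifier stored in the rows.
#' @param background background channel name.
#' @return data.frame(series_id, structure, dsc, hd, msd).
#' @export
metricRows <- function(truth, pred, seriesId = "series",
                       background = "background") {
  stopifnot(is(truth, "LabelVolume"), is(pred, "LabelVolume"))
  structures <- setdiff(truth@channelNames, background)
  sp <- truth@spacing
  rows <- lapply(structures, function(s) {
    ta <- .channel_mask(truth, s)
    pa <- .channel_mask(pred, s)
    hd <- msd <- NA_real_
    if (any(ta) && any(pa)) {
      hd <- hausdorffDistance(ta, pa, sp)
      msd <- meanSurfaceDistance(ta, pa, sp)
    }
    data.frame(series_id = seriesId, structure = s, dsc = dsc(ta, pa),
               hd = hd, msd = msd, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Aggregate metric rows
#'
#' Mean, median and sample SD (n-1 denominator) per structure and metric.
#' A single observation reports SD 0 with `sd_degenerate = TRUE`.
#'
#' @param rows data.frame as produced by [metricRows()] (long or wide;
#'   wide rows with `dsc`, `hd`, `msd` columns are melted).
#' @return data.frame(structure, metric, n, mean, median, sd,
#'   sd_degenerate).
#' @export
aggregateMetrics <- function(rows) {
  long <- do.call(rbind, lapply(c("dsc", "hd", "msd"), function(m)
    data.frame(structure = rows$structure, metric = m, value = rows[[m]],
               stringsAsFactors = FALSE)))
  long <- long[!is.na(long$value), ]
  out <- do.call(rbind, lapply(split(long, long[c("structure", "metric")],
                                     drop = TRUE), function(g) {
    n <- nrow(g)
    data.frame(structure = g$structure[1], metric = g$metric[1], n = n,
               mean = mean(g$value), median = stats::median(g$value),
               sd = if (n > 1) stats::sd(g$value) else 0,
               sd_degenerate = n == 1, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Two-sided paired Wilcoxon signed-rank test
#'
#' Zero differences are dropped (Wilcoxon's original treatment). With at
#' most 25 non-zero differences and untied absolute values the exact
#' signed-rank distribution is used; otherwise a normal approximation with
#' tie correction.
#'
#' @param x,y equal-length paired samples with at least 5 non-zero
#'   differences.
#' @return Two-sided p-value.
#' @export
pairedWilcoxon <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  if (length(d) == 0)
    stop("pairedWilcoxon: all differences are zero; no test possible")
  n <- length(d)
  if (n < 5)
    stop("pairedWilcoxon: fewer than 5 non-zero differences")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (n <= 25 && !ties) {
    p <- 2 * min(stats::psignrank(w, n),
                 stats::psignrank(w - 1, n, lower.tail = FALSE))
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (w - mu) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  min(p, 1)
}
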