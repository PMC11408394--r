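# Training losses: Dice loss, the bounding-box extent-mismatch loss and
# their sum (the Positional Dice Loss), plus the Dice + cross-entropy
# baseline. All accept crisp one-hot volumes (evaluation) or soft
# probability fields (training); analytic gradients with respect to the
# prediction are provided for the training loop.

.loss_array <- function(x) {
  if (is(x, "LabelVolume") || is(x, "PredictionVolume")) x@data
  else if (is.array(x) && length(dim(x)) == 4L) x
  else stop("expected a LabelVolume/PredictionVolume or a 4D array")
}

.loss_channels <- function(x, nch) {
  if (is(x, "LabelVolume") || is(x, "PredictionVolume")) x@channelNames
  else if (nch == 4L) .default_channels
  else paste0("channel", seq_len(nch) - 1L)
}

.check_pq <- function(p, q) {
  pa <- .loss_array(p); qa <- .loss_array(q)
  if (!identical(dim(pa), dim(qa)))
    stop("p and q must share shape and channel order: ",
         paste(dim(pa), collapse = "x"), " vs ",
         paste(dim(qa), collapse = "x"))
  list(p = pa, q = qa,
       channels = .loss_channels(p, dim(pa)[4]))
}

.included_channels <- function(channels, excludeBackground) {
  ch <- seq_along(channels)
  if (excludeBackground) {
    bg <- match("background", channels)
    if (is.na(bg)) bg <- 1L
    ch <- setdiff(ch, bg)
  }
  ch
}

# per-axis raw sums of a 3D array
.axis_sums <- function(a) {
  d <- dim(a)
  m <- matrix(a, d[1], d[2] * d[3])
  sx <- rowSums(m)
  sy <- rowSums(matrix(colSums(m), d[2], d[3]))
  sz <- colSums(matrix(a, d[1] * d[2], d[3]))
  list(x = sx, y = sy, z = sz)
}

# expand a per-axis vector back over the grid (as a flat vector)
.expand_axis <- function(v, d, axis) {
  switch(axis,
         x = rep.int(v, d[2] * d[3]),
         y = rep.int(rep(v, each = d[1]), d[3]),
         z = rep(v, each = d[1] * d[2]))
}

#' Per-axis occupancy profile of a mask
#'
#' Projects a (soft) mask onto one grid axis: the mask is summed over the
#' two orthogonal axes, then in `crisp` mode binarized (`> 0` becomes 1)
#' and in `soft` mode saturated at 1 (`min(sum, 1)`), which coincides with
#' the crisp profile on binary input while admitting gradients.
#'
#' @param mask 3D array, binary or `[0,1]`-valued.
#' @param axis one of `"x"`, `"y"`, `"z"`.
#' @param mode `"crisp"` or `"soft"`.
#' @return Numeric profile of length `dim(mask)[axis]`.
#' @export
axisProjection <- function(mask, axis = c("x", "y", "z"),
                           mode = c("crisp", "soft")) {
  axis <- match.arg(axis)
  mode <- match.arg(mode)
  s <- .axis_sums(mask)[[axis]]
  if (mode == "crisp") as.numeric(s > 0) else pmin(s, 1)
}

#' Extent of the union of two axis profiles
#'
#' Crisp mode counts positions covered by either profile; soft mode sums
#' the saturated union profile `min(p + q, 1)` (identical on binary
#' input).
#'
#' @param pProfile,qProfile equal-length numeric profiles for one axis.
#' @param mode `"crisp"` or `"soft"`.
#' @return A scalar extent (a count for crisp profiles).
#' @export
unionExtent <- function(pProfile, qProfile, mode = c("crisp", "soft")) {
  mode <- match.arg(mode)
  stopifnot(length(pProfile) == length(qProfile))
  if (mode == "crisp") sum(pProfile + qProfile > 0)
  else sum(pmin(pProfile + qProfile, 1))
}

#' Dice loss
#'
#' `1 - 2*sum(p*q) / (sum(p^2) + sum(q^2))` with the sums taken jointly
#' over all voxels and channels (optionally excluding the background
#' channel). Defined as 0 when both volumes are empty over the summed
#' region. Lies in `[0, 1]`.
#'
#' @param p ground-truth LabelVolume (or 4D array).
#' @param q predicted PredictionVolume/LabelVolume (or 4D array).
#' @param excludeBackground drop the background channel from the sums.
#' @return A LossValue with component `dice`.
#' @export
diceLoss <- function(p, q, excludeBackground = FALSE) {
  pq <- .check_pq(p, q)
  ch <- .included_channels(pq$channels, excludeBackground)
  pa <- pq$p[, , , ch, drop = FALSE]
  qa <- pq$q[, , , ch, drop = FALSE]
  denom <- sum(pa * pa) + sum(qa * qa)
  val <- if (denom == 0) 0 else 1 - 2 * sum(pa * qa) / denom
  lossValue(c(dice = val))
}

#' Bounding-box extent-mismatch loss
#'
#' For each foreground channel, the per-axis occupancy profiles of ground
#' truth and prediction are compared elementwise: the numerator sums
#' `|S_axis(p) - S_axis(q)|` over the three axes, the denominator the
#' union extents `R_x + R_y + R_z`; the channel loss is their ratio
#' (0 when the denominator is 0) and the returned value is the mean over
#' foreground channels. Lies in `[0, 1]`. Soft predictions use the
#' saturated-sum profile surrogate of [axisProjection()].
#'
#' @inheritParams diceLoss
#' @param background name of the channel excluded as background.
#' @return A LossValue with component `bbox`.
#' @export
bboxLoss <- function(p, q, background = "background") {
  pq <- .check_pq(p, q)
  ch <- .included_channels(pq$channels, TRUE)
  vals <- vapply(ch, function(c_) {
    pc <- pq$p[, , , c_]
    qc <- pq$q[, , , c_]
    num <- 0; den <- 0
    for (ax in c("x", "y", "z")) {
      sp <- axisProjection(pc, ax, "crisp")
      sq <- axisProjection(qc, ax, "soft")
      num <- num + sum(abs(sp - sq))
      den <- den + unionExtent(sp, sq, "soft")
    }
    if (den == 0) 0 else num / den
  }, numeric(1))
  lossValue(c(bbox = mean(vals)))
}

#' Positional Dice Loss
#'
#' The Dice loss plus the bounding-box mismatch term,
#' `PDL = D_loss + B_loss`, reported with both components. Lies in
#' `[0, 2]`. The bounding-box term steers training away from
#' spatially displaced false positives ("segmentation noise") for
#' structures known to occupy one continuous volume.
#'
#' @inheritParams diceLoss
#' @return A LossValue with components `dice` and `bbox`.
#' @export
positionalDiceLoss <- function(p, q, excludeBackground = FALSE) {
  d <- diceLoss(p, q, excludeBackground)
  b <- bboxLoss(p, q)
  lossValue(c(d@components, b@components))
}

#' Dice + cross-entropy loss
#'
#' The Dice loss plus the mean voxelwise categorical cross-entropy
#' `-sum_c p_c log q_c`, with `q` clipped at 1e-7 before the logarithm.
#'
#' @inheritParams diceLoss
#' @return A LossValue with components `dice` and `cross_entropy`.
#' @export
diceCrossEntropyLoss <- function(p, q, excludeBackground = FALSE) {
  pq <- .check_pq(p, q)
  d <- diceLoss(p, q, excludeBackground)
  qc <- pmax(pq$q, 1e-7)
  nvox <- prod(dim(pq$p)[1:3])
  ce <- -sum(pq$p * log(qc)) / nvox
  lossValue(c(d@components, cross_entropy = ce))
}

#' Evaluate a named loss
#'
#' @param p,q as in [diceLoss()].
#' @param loss one of `"dice"`, `"pdl"`, `"dce"`.
#' @param excludeBackground passed to the Dice term.
#' @return A LossValue.
#' @export
segLoss <- function(p, q, loss = c("dice", "pdl", "dce"),
                    excludeBackground = TRUE) {
  loss <- match.arg(loss)
  switch(loss,
         dice = diceLoss(p, q, excludeBackground),
         pdl = positionalDiceLoss(p, q, excludeBackground),
         dce = diceCrossEntropyLoss(p, q, excludeBackground))
}

# ---- analytic gradients ----------------------------------------------------

.dice_grad <- function(pa, qa, channels, excludeBackground) {
  ch <- .included_channels(channels, excludeBackground)
  d <- dim(pa)
  g <- array(0, dim = d)
  ps <- pa[, , , ch, drop = FALSE]
  qs <- qa[, , , ch, drop = FALSE]
  B <- sum(ps * ps) + sum(qs * qs)
  if (B > 0) {
    A <- sum(ps * qs)
    g[, , , ch] <- (-2 * ps * B + 4 * A * qs) / B^2
  }
  g
}

.bbox_grad <- function(pa, qa, channels) {
  ch <- .included_channels(channels, TRUE)
  d <- dim(pa)
  g <- array(0, dim = d)
  nfg <- length(ch)
  for (c_ in ch) {
    pc <- pa[, , , c_]
    qc <- qa[, , , c_]
    sp <- lapply(.axis_sums(pc), function(s) as.numeric(s > 0))
    sq_raw <- .axis_sums(qc)
    sq <- lapply(sq_raw, function(s) pmin(s, 1))
    num <- 0; den <- 0
    for (ax in c("x", "y", "z")) {
      num <- num + sum(abs(sp[[ax]] - sq[[ax]]))
      den <- den + sum(pmin(sp[[ax]] + sq[[ax]], 1))
    }
    if (den == 0) next
    gc <- numeric(prod(d[1:3]))
    for (ax in c("x", "y", "z")) {
      unsat <- as.numeric(sq_raw[[ax]] < 1)       # dS/ds through min(s,1)
      dnum <- sign(sq[[ax]] - sp[[ax]]) * unsat
      dden <- as.numeric(sp[[ax]] + sq[[ax]] < 1) * unsat
      dprof <- dnum / den - num * dden / den^2
      gc <- gc + .expand_axis(dprof, d[1:3], ax)
    }
    g[, , , c_] <- g[, , , c_] + array(gc, dim = d[1:3]) / nfg
  }
  g
}

.ce_grad <- function(pa, qa) {
  nvox <- prod(dim(pa)[1:3])
  g <- -pa / pmax(qa, 1e-7) / nvox
  g[qa < 1e-7] <- 0  # clip region is flat
  g
}

#' Analytic gradient of a loss with respect to the prediction
#'
#' Subgradients are used at the kinks of the saturated profiles and of the
#' absolute value; these coincide with finite differences almost
#' everywhere.
#'
#' @inheritParams segLoss
#' @return 4D array `dL/dq` matching `q`.
#' @export
lossGradient <- function(p, q, loss = c("dice", "pdl", "dce"),
                         excludeBackground = TRUE) {
  loss <- match.arg(loss)
  pq <- .check_pq(p, q)
  g <- .dice_grad(pq$p, pq$q, pq$channels, excludeBackground)
  if (loss == "pdl") g <- g + .bbox_grad(pq$p, pq$q, pq$channels)
  if (loss == "dce") g <- g + .ce_grad(pq$p, pq$q)
  g
}
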