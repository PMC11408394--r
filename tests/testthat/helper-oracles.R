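# Independent brute-force oracles and small fixture builders used across
# the test files. Oracles deliberately avoid the package's own code paths.

# one-hot 4D array (background + one foreground channel) from a mask
onehot2 <- function(mask) {
  mask <- mask > 0
  a <- array(0, dim = c(dim(mask), 2L))
  a[, , , 1] <- !mask
  a[, , , 2] <- mask
  a
}

lab2 <- function(mask, spacing = c(1, 1, 1)) {
  labelVolume(onehot2(mask), channelNames = c("background", "organ"),
              spacing = spacing)
}

# axis-aligned cuboid mask
cuboid_mask <- function(shape, xr, yr, zr) {
  m <- array(FALSE, shape)
  m[xr, yr, zr] <- TRUE
  m
}

# random one-hot pair on a small grid with nch channels
random_onehot <- function(shape, nch) {
  idx <- array(sample(0:(nch - 1), prod(shape), replace = TRUE),
               dim = shape)
  onehot <- array(0, dim = c(shape, nch))
  for (c_ in seq_len(nch)) onehot[, , , c_] <- idx == (c_ - 1)
  onehot
}

# brute-force bounding-box loss: per-axis occupancy sets, symmetric
# differences over unions, averaged over foreground channels
bbox_oracle <- function(parr, qarr) {
  d <- dim(parr)
  vals <- vapply(2:d[4], function(c_) {
    p <- parr[, , , c_] > 0
    q <- qarr[, , , c_] > 0
    num <- 0
    den <- 0
    for (ax in 1:3) {
      occ_p <- apply(p, ax, any)
      occ_q <- apply(q, ax, any)
      num <- num + sum(xor(occ_p, occ_q))
      den <- den + sum(occ_p | occ_q)
    }
    if (den == 0) 0 else num / den
  }, numeric(1))
  mean(vals)
}

# independent surface finder: 6-neighbourhood, border counts as background
surface_oracle <- function(mask) {
  mask <- mask > 0
  d <- dim(mask)
  out <- NULL
  for (idx in seq_len(prod(d))) {
    co <- arrayInd(idx, d)
    if (!mask[co[1], co[2], co[3]]) next
    on_surface <- FALSE
    for (dd in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                    c(0, 0, 1), c(0, 0, -1))) {
      nb <- co + dd
      if (any(nb < 1) || any(nb > d) || !mask[nb[1], nb[2], nb[3]]) {
        on_surface <- TRUE
        break
      }
    }
    if (on_surface) out <- rbind(out, co)
  }
  out
}

# all-pairs directed and symmetric surface distances
surface_metrics_oracle <- function(a, b, spacing) {
  sa <- surface_oracle(a)
  sb <- surface_oracle(b)
  dmat <- matrix(0, nrow(sa), nrow(sb))
  for (i in seq_len(nrow(sa)))
    for (j in seq_len(nrow(sb)))
      dmat[i, j] <- sqrt(sum(((sa[i, ] - sb[j, ]) * spacing)^2))
  dab <- apply(dmat, 1, min)
  dba <- apply(dmat, 2, min)
  list(hd = max(max(dab), max(dba)),
       msd = (mean(dab) + mean(dba)) / 2)
}

# random soft prediction volume (positive, channel-normalised)
random_soft <- function(shape, nch, concentration = 1) {
  e <- array(stats::rexp(prod(shape) * nch)^concentration,
             dim = c(shape, nch))
  s <- array(rep(apply(e, c(1, 2, 3), sum), times = nch),
             dim = c(shape, nch))
  e / s
}

# tiny phantom grid used by several tests
small_phantom <- function(seed = 1L) {
  generatePhantom(phantomSpec(shape = c(32L, 32L, 16L),
                              spacing = c(13.125, 13.125, 12),
                              seed = as.integer(seed)))
}
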