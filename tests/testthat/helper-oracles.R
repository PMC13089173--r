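# Independent numerical oracles used to validate the exact-traversal code.

# Dense midpoint-sampling WEPL: march the ray in ~`step` mm increments and
# accumulate sampled RSP. Shares no code with the Siddon traversal.
wepl_dense <- function(p0, d, vol, tmax = Inf, step = 0.01) {
  d <- d / sqrt(sum(d^2))
  dm <- dim(vol$data)
  lo <- vol$origin - vol$spacing / 2
  hi <- vol$origin + (dm - 0.5) * vol$spacing
  t0 <- 0
  t1 <- if (is.finite(tmax)) tmax else 1e12
  for (a in 1:3) {
    if (abs(d[a]) < 1e-14) {
      if (p0[a] < lo[a] || p0[a] >= hi[a]) return(0)
    } else {
      ta <- (lo[a] - p0[a]) / d[a]
      tb <- (hi[a] - p0[a]) / d[a]
      t0 <- max(t0, min(ta, tb))
      t1 <- min(t1, max(ta, tb))
    }
  }
  if (t1 <= t0) return(0)
  n <- ceiling((t1 - t0) / step)
  h <- (t1 - t0) / n
  ts <- t0 + (seq_len(n) - 0.5) * h
  ijk <- cbind(floor((p0[1] + ts * d[1] - lo[1]) / vol$spacing[1]),
               floor((p0[2] + ts * d[2] - lo[2]) / vol$spacing[2]),
               floor((p0[3] + ts * d[3] - lo[3]) / vol$spacing[3]))
  ijk <- pmin(pmax(ijk, 0), matrix(dm - 1L, nrow(ijk), 3, byrow = TRUE))
  lin <- ijk[, 1] + dm[1] * (ijk[, 2] + dm[2] * ijk[, 3]) + 1
  sum(vol$data[lin]) * h
}

# Brute-force margin expansion: physical distance from every grid voxel
# centre to every set voxel centre.
expand_brute <- function(mask, margin_mm) {
  dm <- dim(mask$data)
  ctr_all <- voxel_centers(mask, which = array(TRUE, dm))
  ctr_set <- voxel_centers(mask)
  out <- rep(FALSE, nrow(ctr_all))
  for (r in seq_len(nrow(ctr_set))) {
    d2 <- (ctr_all[, 1] - ctr_set[r, 1])^2 +
      (ctr_all[, 2] - ctr_set[r, 2])^2 +
      (ctr_all[, 3] - ctr_set[r, 3])^2
    out <- out | (d2 <= margin_mm^2 + 1e-9)
  }
  array(out, dm)
}

# Voxel-marking PIV oracle: march every bundle ray densely to its stop point
# and mark the voxels it passes through.
piv_dense <- function(bundle, oar, step = 0.05) {
  dm <- dim(oar$data)
  lo <- oar$origin - oar$spacing / 2
  hit <- array(FALSE, dm)
  d <- bundle$direction
  for (r in seq_len(nrow(bundle$p0))) {
    p0 <- bundle$p0[r, ]
    ts <- seq(step / 2, bundle$t_stop[r], by = step)
    ijk <- cbind(floor((p0[1] + ts * d[1] - lo[1]) / oar$spacing[1]),
                 floor((p0[2] + ts * d[2] - lo[2]) / oar$spacing[2]),
                 floor((p0[3] + ts * d[3] - lo[3]) / oar$spacing[3]))
    ok <- ijk[, 1] >= 0 & ijk[, 1] < dm[1] &
      ijk[, 2] >= 0 & ijk[, 2] < dm[2] &
      ijk[, 3] >= 0 & ijk[, 3] < dm[3]
    hit[ijk[ok, , drop = FALSE] + 1] <- TRUE
  }
  sum(hit & oar$data) / sum(oar$data)
}

# random unit vector
runit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}
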