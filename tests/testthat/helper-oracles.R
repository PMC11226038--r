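# Independent reference implementations used as oracles. These are written
# against the documented algorithm contracts, not against the package code:
# plain-R, brute-force, and deliberately slow.

# brute-force median of the (2r+1)^3 clamped neighbourhood of one voxel
oracle_median_at <- function(values, dm, x, y, z, r) {
  xs <- pmin(pmax((x - r):(x + r), 1L), dm[1])
  ys <- pmin(pmax((y - r):(y + r), 1L), dm[2])
  zs <- pmin(pmax((z - r):(z + r), 1L), dm[3])
  v <- as.numeric(values[xs, ys, zs])
  sort(v)[(length(v) + 1) / 2]
}

# brute-force Euclidean distance (voxel units) to the nearest background
# voxel, by scanning all background voxels
oracle_edt <- function(mask) {
  dm <- dim(mask)
  co <- as.matrix(expand.grid(x = seq_len(dm[1]), y = seq_len(dm[2]),
                              z = seq_len(dm[3])))
  bg <- co[!as.vector(mask), , drop = FALSE]
  out <- numeric(length(mask))
  fg_idx <- which(as.vector(mask))
  for (i in fg_idx) {
    d2 <- (bg[, 1] - co[i, 1])^2 + (bg[, 2] - co[i, 2])^2 +
      (bg[, 3] - co[i, 3])^2
    out[i] <- sqrt(min(d2))
  }
  array(out, dm)
}

# gradient magnitude by central differences, one-sided at faces (the
# documented landscape definition), plain R
oracle_gradient <- function(values) {
  dm <- dim(values)
  cl <- function(i, n) pmin(pmax(i, 1L), n)
  g2 <- array(0, dm)
  for (axis in 1:3) {
    hi <- lo <- seq_len(dm[axis])
    hi <- cl(hi + 1L, dm[axis]); lo <- cl(lo - 1L, dm[axis])
    pick <- function(idx) switch(axis, values[idx, , , drop = FALSE],
                                 values[, idx, , drop = FALSE],
                                 values[, , idx, drop = FALSE])
    step <- hi - lo
    step_arr <- switch(axis,
                       array(rep(step, times = dm[2] * dm[3]), dm),
                       array(rep(rep(step, each = dm[1]), times = dm[3]), dm),
                       array(rep(step, each = dm[1] * dm[2]), dm))
    g2 <- g2 + ((pick(hi) - pick(lo)) / step_arr)^2
  }
  sqrt(g2)
}

# brute-force priority flood implementing the documented queue discipline:
# frontier as flat vectors, the next entry found by scanning for minimum
# priority and, among equal priorities, the earliest insertion sequence
# (FIFO). Seeds enter in (label, scan-order) order and pre-claim their
# voxels; neighbours are pushed in lexicographic offset order;
# 26-connectivity.
oracle_priority_flood <- function(priority, mask, seeds) {
  dm <- dim(mask)
  n <- length(mask)
  lab <- integer(n)
  done <- logical(n)
  pv <- as.numeric(priority)
  mv <- as.vector(mask)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  nxy <- dm[1] * dm[2]
  xyz <- function(i) {
    i0 <- i - 1L
    c(i0 %% dm[1], (i0 %/% dm[1]) %% dm[2], i0 %/% nxy)
  }
  seed_idx <- which(seeds > 0L & mv)
  seed_idx <- seed_idx[order(seeds[seed_idx], seed_idx)]
  lab[seed_idx] <- as.integer(seeds[seed_idx])
  nseq <- length(seed_idx)
  fr_p <- pv[seed_idx]
  fr_s <- seq_len(nseq)
  fr_l <- as.integer(seeds[seed_idx])
  fr_i <- seed_idx
  while (length(fr_i) > 0L) {
    cand <- which(fr_p == min(fr_p))
    k <- cand[which.min(fr_s[cand])]
    i <- fr_i[k]; l <- fr_l[k]
    fr_p <- fr_p[-k]; fr_s <- fr_s[-k]; fr_l <- fr_l[-k]; fr_i <- fr_i[-k]
    if (done[i]) next
    done[i] <- TRUE
    if (lab[i] == 0L) lab[i] <- l
    mylab <- lab[i]
    c0 <- xyz(i)
    for (r in seq_len(nrow(off))) {
      q <- c0 + off[r, ]
      if (any(q < 0L) || any(q >= dm)) next
      j <- 1L + q[1] + dm[1] * q[2] + nxy * q[3]
      if (mv[j] && !done[j] && lab[j] == 0L) {
        nseq <- nseq + 1L
        fr_p <- c(fr_p, pv[j]); fr_s <- c(fr_s, nseq)
        fr_l <- c(fr_l, mylab); fr_i <- c(fr_i, j)
      }
    }
  }
  array(lab, dm)
}

# classical balanced two-way ANOVA via R's linear-model projections
oracle_anova_lm <- function(d) {
  fit <- stats::lm(response ~ A * B, data = transform(
    d, A = factor(group), B = factor(timepoint)))
  an <- stats::anova(fit)
  list(SS_A = an["A", "Sum Sq"], SS_B = an["B", "Sum Sq"],
       SS_effect = an["A:B", "Sum Sq"], SS_error = an["Residuals", "Sum Sq"],
       DF_effect = an["A:B", "Df"], DF_error = an["Residuals", "Df"])
}
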