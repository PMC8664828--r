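# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so seeded package functions never
# perturb the user's random stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Per-subject child seed: a fixed affine counter scheme on the master seed,
# kept below 2^31 so it is always a valid integer seed.
child_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) * 1009 + 7919 * as.numeric(index)) %% 2147483647)
}

# Shift a 3-D array by integer offset d = (dx, dy, dz): out[v] = a[v + d],
# padding with `fill` where v + d falls outside the array.
shift_array3 <- function(a, d, fill = NA) {
  dm <- dim(a)
  out <- array(fill, dm)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    lo <- max(1L, 1L - d[ax]); hi <- min(dm[ax], dm[ax] - d[ax])
    if (lo > hi) return(out)
    dst[[ax]] <- lo:hi
    src[[ax]] <- (lo + d[ax]):(hi + d[ax])
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# The 26 neighbourhood offsets (Chebyshev distance 1), as a 26 x 3 matrix.
offsets26 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

# The 13 unique direction offsets (one orientation per axis pair).
offsets13 <- function() {
  o <- offsets26()
  keep <- o[, 3] > 0 | (o[, 3] == 0 & o[, 2] > 0) |
    (o[, 3] == 0 & o[, 2] == 0 & o[, 1] > 0)
  o[keep, , drop = FALSE]
}

# Bounding box of TRUE voxels; NULL for an empty mask.
mask_bbox <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) == 0L) return(NULL)
  lapply(1:3, function(ax) seq(min(w[, ax]), max(w[, ax])))
}

# 26-connected component labelling of a logical 3-D array. Returns an
# integer array (0 outside) labelled in first-encounter (column-major) order.
label_components_3d <- function(mask) {
  dm <- dim(mask)
  pd <- dm + 2L
  padded <- array(FALSE, pd)
  padded[2:(pd[1] - 1L), 2:(pd[2] - 1L), 2:(pd[3] - 1L)] <- mask
  offs <- offsets26()
  loff <- offs[, 1] + offs[, 2] * pd[1] + offs[, 3] * pd[1] * pd[2]
  lab <- integer(prod(pd))
  todo <- which(padded)
  nxt <- 0L
  for (s in todo) {
    if (lab[s] != 0L) next
    nxt <- nxt + 1L
    lab[s] <- nxt
    frontier <- s
    while (length(frontier)) {
      nb <- unique(as.vector(outer(frontier, loff, `+`)))
      nb <- nb[padded[nb] & lab[nb] == 0L]
      lab[nb] <- nxt
      frontier <- nb
    }
  }
  lab <- array(lab, pd)
  lab[2:(pd[1] - 1L), 2:(pd[2] - 1L), 2:(pd[3] - 1L)]
}

# Dilate a logical mask by a physical radius (mm), using the ellipsoid of
# voxel offsets whose centre-to-centre distance is within `margin_mm`.
dilate_mm <- function(mask, spacing, margin_mm) {
  if (margin_mm <= 0) return(mask)
  r <- pmax(0L, floor(margin_mm / spacing))
  g <- as.matrix(expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3]))
  d2 <- (g[, 1] * spacing[1])^2 + (g[, 2] * spacing[2])^2 + (g[, 3] * spacing[3])^2
  g <- g[d2 <= margin_mm^2 & rowSums(abs(g)) > 0, , drop = FALSE]
  out <- mask
  for (i in seq_len(nrow(g)))
    out <- out | shift_array3(mask, g[i, ], fill = FALSE)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
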