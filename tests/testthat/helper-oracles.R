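# Independent brute-force oracles for the texture matrices, written as
# explicit per-voxel enumerations so they share no code path with the
# vectorized implementations they check.

# Build a discretized VOI directly from an integer level array (NA = out of
# mask), bypassing the segmentation/discretization chain.
make_dvoi <- function(levels, n_bins = max(levels, na.rm = TRUE),
                      spacing = c(1, 1, 1)) {
  if (length(dim(levels)) != 3L) dim(levels) <- c(dim(levels), 1L)
  structure(list(levels = levels, mask = !is.na(levels),
                 spacing = spacing,
                 spec = discretization_spec(max(2L, n_bins), 0, max(2L, n_bins))),
            class = "discretized_voi")
}

all_offsets26 <- local({
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(g[rowSums(abs(g)) > 0, ])
})

in_bounds <- function(v, dm) all(v >= 1) && all(v <= dm)

# GLCM oracle: enumerate every ordered in-mask voxel pair at Chebyshev
# distance 1 and accumulate the joint grey-level histogram.
oracle_glcm <- function(L) {
  dm <- dim(L)
  nb <- max(L, na.rm = TRUE)
  P <- matrix(0, nb, nb)
  for (x in seq_len(dm[1])) for (y in seq_len(dm[2])) for (z in seq_len(dm[3])) {
    if (is.na(L[x, y, z])) next
    for (k in seq_len(nrow(all_offsets26))) {
      v <- c(x, y, z) + all_offsets26[k, ]
      if (!in_bounds(v, dm)) next
      lj <- L[v[1], v[2], v[3]]
      if (is.na(lj)) next
      P[L[x, y, z], lj] <- P[L[x, y, z], lj] + 1
    }
  }
  P <- P / sum(P)
  i <- row(P); j <- col(P)
  mu <- sum(i * P)
  sig2 <- sum((i - mu)^2 * P)
  list(P = P,
       inverse_difference = sum(P / (1 + abs(i - j))),
       asm = sum(P^2),
       variance = sum((i - mu)^2 * P),
       correlation = if (sig2 > 0) sum((i - mu) * (j - mu) * P) / sig2 else NA,
       joint_entropy = -sum(ifelse(P > 0, P * log2(P), 0)),
       dissimilarity = sum(abs(i - j) * P))
}

# NGLDM oracle: per-voxel neighbourhood means by direct looping.
oracle_ngldm <- function(L) {
  dm <- dim(L)
  lev_all <- integer(0); dev_all <- numeric(0)
  for (x in seq_len(dm[1])) for (y in seq_len(dm[2])) for (z in seq_len(dm[3])) {
    if (is.na(L[x, y, z])) next
    nb <- numeric(0)
    for (k in seq_len(nrow(all_offsets26))) {
      v <- c(x, y, z) + all_offsets26[k, ]
      if (in_bounds(v, dm) && !is.na(L[v[1], v[2], v[3]]))
        nb <- c(nb, L[v[1], v[2], v[3]])
    }
    if (length(nb) == 0) next
    lev_all <- c(lev_all, L[x, y, z])
    dev_all <- c(dev_all, abs(L[x, y, z] - mean(nb)))
  }
  lv <- sort(unique(lev_all))
  N <- length(lev_all)
  p_i <- sapply(lv, function(g) sum(lev_all == g)) / N
  s_i <- sapply(lv, function(g) sum(dev_all[lev_all == g]))
  Ng <- length(lv)
  coarseness <- min(1 / sum(p_i * s_i), 1e6)
  contrast <- if (Ng > 1) {
    acc <- 0
    for (a in seq_len(Ng)) for (b in seq_len(Ng))
      acc <- acc + p_i[a] * p_i[b] * (lv[a] - lv[b])^2
    acc / (Ng * (Ng - 1)) * sum(s_i) / N
  } else 0
  den <- 0
  for (a in seq_len(Ng)) for (b in seq_len(Ng))
    if (a != b) den <- den + abs(lv[a] * p_i[a] - lv[b] * p_i[b])
  busyness <- if (den > 0) sum(p_i * s_i) / den else NA
  list(coarseness = coarseness, contrast = contrast, busyness = busyness)
}

# GLZLM oracle: zones as igraph connected components of the equal-level
# 26-adjacency graph.
oracle_glzlm <- function(L) {
  dm <- dim(L)
  idx <- which(!is.na(L))
  pos <- arrayInd(idx, dm)
  key <- function(v) paste(v, collapse = ",")
  id <- setNames(seq_along(idx), apply(pos, 1, key))
  edges <- integer(0)
  for (r in seq_along(idx)) {
    for (k in seq_len(nrow(all_offsets26))) {
      v <- pos[r, ] + all_offsets26[k, ]
      if (!in_bounds(v, dm)) next
      other <- id[key(v)]
      if (is.na(other)) next
      if (L[idx[r]] == L[idx[other]] && other > r)
        edges <- c(edges, r, other)
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)
  zl <- sapply(seq_len(comp$no), function(cc) L[idx[comp$membership == cc]][1])
  zs <- as.integer(comp$csize)
  n_z <- comp$no; n_v <- length(idx)
  sum_over <- function(f) {
    acc <- 0
    for (q in seq_len(n_z)) acc <- acc + f(zl[q], zs[q])
    acc
  }
  gl <- sapply(sort(unique(zl)), function(i) sum(zl == i))
  sz <- sapply(sort(unique(zs)), function(j) sum(zs == j))
  list(SZE = sum_over(function(i, j) 1 / j^2) / n_z,
       LZE = sum_over(function(i, j) j^2) / n_z,
       LGZE = sum_over(function(i, j) 1 / i^2) / n_z,
       HGZE = sum_over(function(i, j) i^2) / n_z,
       SZLGE = sum_over(function(i, j) 1 / (i^2 * j^2)) / n_z,
       SZHGE = sum_over(function(i, j) i^2 / j^2) / n_z,
       LZLGE = sum_over(function(i, j) j^2 / i^2) / n_z,
       LZHGE = sum_over(function(i, j) i^2 * j^2) / n_z,
       GLNU = sum(gl^2) / n_z,
       ZLNU = sum(sz^2) / n_z,
       ZP = n_z / n_v)
}

# Small phantom parameters for fast tests.
small_phantom <- function(grid_shape = c(32, 32, 80), ...) {
  phantom_params(grid_shape = grid_shape, voxel_spacing_mm = c(2, 2, 2), ...)
}

expect_feature_equal <- function(actual, expected, tol = 1e-10) {
  expect_equal(unname(actual), unname(expected), tolerance = tol)
}
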