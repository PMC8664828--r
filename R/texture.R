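#' Absolute SUV discretization specification
#'
#' Fixed-bin absolute discretization of SUV for texture-matrix computation:
#' `n_bins` left-closed bins of width `(suv_max - suv_min) / n_bins` over the
#' stated SUV range, with values above `suv_max` clamped into the top bin.
#' The defaults (64 bins over 0-30 SUV) give a bin width of 0.46875 SUV.
#'
#' @param n_bins Number of grey levels (>= 2).
#' @param suv_min,suv_max SUV range; `suv_max > suv_min`.
#' @return A `discretization_spec` list with the derived `bin_width`.
#' @export
discretization_spec <- function(n_bins = 64L, suv_min = 0, suv_max = 30) {
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("`n_bins` must be at least 2")
  if (!(suv_max > suv_min)) stop("`suv_max` must exceed `suv_min`")
  structure(list(n_bins = n_bins, suv_min = suv_min, suv_max = suv_max,
                 bin_width = (suv_max - suv_min) / n_bins),
            class = "discretization_spec")
}

#' The 26 radiomic feature names
#'
#' Column order of the feature table: six conventional PET parameters, six
#' grey-level co-occurrence (GLCM) features, three neighbourhood grey-level
#' difference (NGLDM) features, and eleven grey-level size-zone (GLZLM)
#' features.
#'
#' @return Character vector of length 26.
#' @export
radiomic_feature_names <- function() {
  c("SUVmax", "SUVpeak", "SUVskewness", "SUVkurtosis", "SUVexcess_kurtosis",
    "TLG_mL",
    "inverse_difference_GLCM", "angular_second_moment_GLCM", "variance_GLCM",
    "correlation_GLCM", "joint_entropy_GLCM", "dissimilarity_GLCM",
    "coarseness_NGLDM", "contrast_NGLDM", "busyness_NGLDM",
    "SZE_GLZLM", "LZE_GLZLM", "LGZE_GLZLM", "HGZE_GLZLM", "SZLGE_GLZLM",
    "SZHGE_GLZLM", "LZLGE_GLZLM", "LZHGE_GLZLM", "GLNU_GLZLM", "ZLNU_GLZLM",
    "ZP_GLZLM")
}

#' Resample a PET volume to a target spacing
#'
#' Trilinear interpolation at the voxel centres of a new grid covering the
#' same physical extent (preserved to within one voxel). The new grid has
#' `round(n * spacing / target)` voxels per axis and shares the volume's
#' physical corner; values beyond the source centres are clamped to the edge
#' value.
#'
#' @param pet A [volume_grid()].
#' @param target_spacing Target voxel size in mm along x, y, z (default the
#'   4 x 4 mm in-plane, 2 mm axial analysis spacing).
#' @return A resampled [volume_grid()].
#' @export
resample_pet <- function(pet, target_spacing = c(4, 4, 2)) {
  stopifnot(inherits(pet, "volume_grid"))
  t <- as.numeric(target_spacing)
  if (length(t) != 3L || any(!is.finite(t)) || any(t <= 0))
    stop("`target_spacing` must be three positive spacings in mm")
  dm <- dim(pet$data)
  n_new <- pmax(1L, as.integer(round(dm * pet$spacing / t)))
  ax <- lapply(1:3, function(a) {
    # world coords of new centres, mapped to fractional source indices
    w <- (pet$origin[a] - pet$spacing[a] / 2) + (seq_len(n_new[a]) - 0.5) * t[a]
    f <- (w - pet$origin[a]) / pet$spacing[a] + 1
    f <- pmin(pmax(f, 1), dm[a])
    i0 <- pmin(floor(f), max(dm[a] - 1L, 1L))
    list(i0 = as.integer(i0), frac = f - i0, n = n_new[a])
  })
  i1 <- lapply(1:3, function(a) pmin(ax[[a]]$i0 + 1L, dm[a]))
  w1 <- lapply(1:3, function(a) ax[[a]]$frac)
  acc <- array(0, n_new)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wx <- if (dx) w1[[1]] else 1 - w1[[1]]
    wy <- if (dy) w1[[2]] else 1 - w1[[2]]
    wz <- if (dz) w1[[3]] else 1 - w1[[3]]
    wt <- outer(outer(wx, wy), wz)
    if (all(wt == 0)) next
    sub <- pet$data[if (dx) i1[[1]] else ax[[1]]$i0,
                    if (dy) i1[[2]] else ax[[2]]$i0,
                    if (dz) i1[[3]] else ax[[3]]$i0, drop = FALSE]
    acc <- acc + wt * array(sub, n_new)
  }
  new_origin <- (pet$origin - pet$spacing / 2) + t / 2
  volume_grid(acc, t, new_origin)
}

#' Discretize PET values inside a VOI
#'
#' Maps each in-mask SUV to a grey level `1 + floor((SUV - suv_min) /
#' bin_width)`, clamped to `[1, n_bins]` (so `SUV = suv_max` and anything
#' above it map to the top level).
#'
#' @param pet A [volume_grid()] in SUV.
#' @param voi A [skeleton_voi()] on the same grid.
#' @param spec A [discretization_spec()].
#' @return A `discretized_voi`: integer `levels` array (NA outside the
#'   mask), the logical `mask`, `spacing` and the spec.
#' @export
discretize <- function(pet, voi, spec = discretization_spec()) {
  stopifnot(inherits(pet, "volume_grid"), inherits(voi, "skeleton_voi"),
            inherits(spec, "discretization_spec"))
  if (!identical(dim(pet$data), dim(voi$mask)))
    stop("PET volume and VOI mask are on different grids")
  if (!any(voi$mask)) stop("cannot discretize an empty VOI")
  lev <- array(NA_integer_, dim(pet$data))
  v <- pet$data[voi$mask]
  g <- 1L + as.integer(floor((v - spec$suv_min) / spec$bin_width))
  lev[voi$mask] <- pmin(pmax(g, 1L), spec$n_bins)
  structure(list(levels = lev, mask = voi$mask, spacing = voi$spacing,
                 spec = spec), class = "discretized_voi")
}

#' Conventional PET features inside a VOI
#'
#' Computes SUVmax, SUVpeak (mean SUV over the ~1 mL sphere of voxel centres
#' around the hottest in-mask voxel), skewness and kurtosis of the in-mask
#' SUV histogram (population central moments by default), excess kurtosis,
#' and TLG (mean SUV times mask volume in mL).
#'
#' Zero-variance SUV distributions leave skewness and kurtosis undefined;
#' they are returned as NA with an explanatory flag rather than a silent 0.
#'
#' @param pet A [volume_grid()] in SUV.
#' @param voi A [skeleton_voi()] on the same grid.
#' @param peak_in_mask Restrict the SUVpeak sphere to in-mask voxels.
#' @param sample_moments Use sample (n-1 denominator, bias-adjusted)
#'   skewness/kurtosis instead of population moments.
#' @return List with `values` (named numeric) and `flags` (character).
#' @export
conventional_features <- function(pet, voi, peak_in_mask = TRUE,
                                  sample_moments = FALSE) {
  stopifnot(inherits(pet, "volume_grid"), inherits(voi, "skeleton_voi"))
  if (!any(voi$mask)) stop("VOI is empty")
  flags <- character()
  suv <- pet$data[voi$mask]
  n <- length(suv)
  suv_max <- max(suv)

  # 1 mL sphere at the hottest in-mask voxel (ties: lowest linear index)
  hot <- which(voi$mask)[which.max(suv)]
  ctr <- (arrayInd(hot, dim(pet$data))[1, ] - 0.5) * voi$spacing
  r <- (3 * 1000 / (4 * pi))^(1 / 3)
  rv <- pmax(0L, floor(r / voi$spacing))
  dm <- dim(pet$data)
  ai <- arrayInd(hot, dm)[1, ]
  rng <- lapply(1:3, function(a) max(1L, ai[a] - rv[a] - 1L):min(dm[a], ai[a] + rv[a] + 1L))
  grid <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  cmm <- sweep(grid - 0.5, 2, voi$spacing, `*`)
  d2 <- (cmm[, 1] - ctr[1])^2 + (cmm[, 2] - ctr[2])^2 + (cmm[, 3] - ctr[3])^2
  sel <- grid[d2 <= r^2, , drop = FALSE]
  lin <- sel[, 1] + (sel[, 2] - 1L) * dm[1] + (sel[, 3] - 1L) * dm[1] * dm[2]
  if (peak_in_mask) lin <- lin[voi$mask[lin]]
  suv_peak <- mean(pet$data[lin])

  m <- mean(suv)
  if (sample_moments && n > 3) {
    s2 <- stats::var(suv)
    if (s2 <= 0) {
      skew <- kurt <- NA_real_
      flags <- c(flags, "zero-variance SUV distribution: skewness/kurtosis undefined")
    } else {
      g1 <- mean((suv - m)^3) / mean((suv - m)^2)^1.5
      g2 <- mean((suv - m)^4) / mean((suv - m)^2)^2 - 3
      skew <- g1 * sqrt(n * (n - 1)) / (n - 2)
      kurt <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3)) + 3
    }
  } else {
    m2 <- mean((suv - m)^2)
    if (m2 <= 0) {
      skew <- kurt <- NA_real_
      flags <- c(flags, "zero-variance SUV distribution: skewness/kurtosis undefined")
    } else {
      skew <- mean((suv - m)^3) / m2^1.5
      kurt <- mean((suv - m)^4) / m2^2
    }
  }
  vol_ml <- n * prod(voi$spacing) / 1000
  list(values = c(SUVmax = suv_max, SUVpeak = suv_peak, SUVskewness = skew,
                  SUVkurtosis = kurt, SUVexcess_kurtosis = kurt - 3,
                  TLG_mL = m * vol_ml),
       flags = flags)
}

# Pooled symmetric GLCM over the 13 distance-1 directions, both orientations,
# both voxels in-mask. Returns the normalized n_bins x n_bins matrix.
glcm_matrix <- function(d) {
  stopifnot(inherits(d, "discretized_voi"))
  nb <- d$spec$n_bins
  bb <- mask_bbox(d$mask)
  if (is.null(bb)) stop("VOI is empty")
  L <- d$levels[bb[[1]], bb[[2]], bb[[3]], drop = FALSE]
  dm <- dim(L)
  counts <- numeric(nb * nb)
  offs <- offsets13()
  for (k in seq_len(nrow(offs))) {
    o <- offs[k, ]
    rng_a <- rng_b <- vector("list", 3L)
    ok <- TRUE
    for (axis in 1:3) {
      lo <- max(1L, 1L - o[axis]); hi <- min(dm[axis], dm[axis] - o[axis])
      if (lo > hi) { ok <- FALSE; break }
      rng_a[[axis]] <- lo:hi
      rng_b[[axis]] <- (lo + o[axis]):(hi + o[axis])
    }
    if (!ok) next
    a <- L[rng_a[[1]], rng_a[[2]], rng_a[[3]]]
    b <- L[rng_b[[1]], rng_b[[2]], rng_b[[3]]]
    keep <- !is.na(a) & !is.na(b)
    if (!any(keep)) next
    idx <- (a[keep] - 1L) * nb + b[keep]
    tab <- tabulate(idx, nb * nb)
    counts <- counts + tab
  }
  P <- matrix(counts, nb, nb, byrow = TRUE)
  P <- P + t(P)                       # both orientations of every pair
  tot <- sum(P)
  if (tot == 0) stop("no adjacent in-mask voxel pair for the GLCM")
  P / tot
}

#' GLCM texture features
#'
#' Features of a single co-occurrence matrix pooling all 13 spatial
#' directions at distance one voxel: inverse difference, angular second
#' moment, variance (joint form), correlation, joint entropy (base 2) and
#' dissimilarity. With a single grey level in the VOI the correlation is
#' degenerate and returned as NA with a flag.
#'
#' @param d A `discretized_voi` from [discretize()].
#' @return List with `values` (named numeric) and `flags`.
#' @export
glcm_features <- function(d) {
  P <- glcm_matrix(d)
  nb <- nrow(P)
  flags <- character()
  i <- matrix(seq_len(nb), nb, nb)
  j <- t(i)
  p_i <- rowSums(P)
  mu <- sum(seq_len(nb) * p_i)
  sig2 <- sum((seq_len(nb) - mu)^2 * p_i)
  pos <- P > 0
  variance <- sum((i - mu)^2 * P)
  corr <- if (sig2 > 0) (sum(i * j * P) - mu^2) / sig2 else {
    flags <- c(flags, "single grey level: GLCM correlation degenerate")
    NA_real_
  }
  list(values = c(
    inverse_difference_GLCM = sum(P / (1 + abs(i - j))),
    angular_second_moment_GLCM = sum(P^2),
    variance_GLCM = variance,
    correlation_GLCM = corr,
    joint_entropy_GLCM = -sum(P[pos] * log2(P[pos])),
    dissimilarity_GLCM = sum(abs(i - j) * P)),
    flags = flags)
}

#' NGLDM texture features
#'
#' Neighbourhood grey-level difference features (coarseness, contrast,
#' busyness) in the Amadasun-King formulation on the full 26-voxel
#' neighbourhood restricted to in-mask voxels. Voxels with no in-mask
#' neighbour are skipped. For a flat VOI the coarseness denominator is zero
#' and the documented cap of `1e6` is reported; busyness is NA with a flag,
#' and contrast is 0.
#'
#' @param d A `discretized_voi` from [discretize()].
#' @return List with `values` (named numeric) and `flags`.
#' @export
ngldm_features <- function(d) {
  stopifnot(inherits(d, "discretized_voi"))
  bb <- mask_bbox(d$mask)
  if (is.null(bb)) stop("VOI is empty")
  L <- d$levels[bb[[1]], bb[[2]], bb[[3]], drop = FALSE]
  inm <- !is.na(L)
  Lz <- L; Lz[!inm] <- 0L
  S <- array(0, dim(L)); C <- array(0, dim(L))
  offs <- offsets26()
  for (k in seq_len(nrow(offs))) {
    S <- S + shift_array3(Lz, offs[k, ], fill = 0L)
    C <- C + shift_array3(array(as.integer(inm), dim(L)), offs[k, ], fill = 0L)
  }
  use <- inm & C > 0
  if (!any(use)) stop("no in-mask voxel has an in-mask neighbour")
  lev <- L[use]
  dev <- abs(lev - S[use] / C[use])
  n_i <- tapply(rep(1, length(lev)), lev, sum)
  s_i <- tapply(dev, lev, sum)
  levels_present <- as.numeric(names(n_i))
  N <- sum(n_i)
  p_i <- as.numeric(n_i) / N
  s_i <- as.numeric(s_i)
  Ng <- length(levels_present)
  flags <- character()

  denom_coar <- sum(p_i * s_i)
  coarseness <- if (denom_coar > 0) min(1 / denom_coar, 1e6) else {
    flags <- c(flags, "flat neighbourhood differences: coarseness capped")
    1e6
  }
  contrast <- if (Ng > 1) {
    dif2 <- outer(levels_present, levels_present, `-`)^2
    sum(outer(p_i, p_i) * dif2) / (Ng * (Ng - 1)) * sum(s_i) / N
  } else {
    flags <- c(flags, "single grey level: NGLDM contrast degenerate (0)")
    0
  }
  ip <- levels_present * p_i
  denom_busy <- sum(abs(outer(ip, ip, `-`))[outer(seq_len(Ng), seq_len(Ng), `!=`)])
  busyness <- if (denom_busy > 0) sum(p_i * s_i) / denom_busy else {
    flags <- c(flags, "busyness denominator zero: reported as NA")
    NA_real_
  }
  list(values = c(coarseness_NGLDM = coarseness, contrast_NGLDM = contrast,
                  busyness_NGLDM = busyness),
       flags = flags)
}

# Zone table of a discretized VOI: maximal 26-connected components of equal
# grey level. Returns a data.frame (level, size, count).
glzlm_zones <- function(d) {
  stopifnot(inherits(d, "discretized_voi"))
  bb <- mask_bbox(d$mask)
  if (is.null(bb)) stop("VOI is empty")
  L <- d$levels[bb[[1]], bb[[2]], bb[[3]], drop = FALSE]
  out <- list()
  for (g in sort(unique(L[!is.na(L)]))) {
    m <- !is.na(L) & L == g
    lab <- label_components_3d(m)
    sizes <- tabulate(lab[lab > 0L])
    tab <- table(sizes)
    out[[length(out) + 1L]] <- data.frame(level = g,
                                          size = as.integer(names(tab)),
                                          count = as.integer(tab))
  }
  do.call(rbind, out)
}

#' GLZLM (size-zone) texture features
#'
#' The eleven grey-level size-zone features (SZE, LZE, LGZE, HGZE, SZLGE,
#' SZHGE, LZLGE, LZHGE, grey-level non-uniformity, zone-length
#' non-uniformity, zone percentage) computed from maximal 26-connected
#' equal-level zones within the mask.
#'
#' @param d A `discretized_voi` from [discretize()].
#' @return List with `values` (named numeric) and `flags`.
#' @export
glzlm_features <- function(d) {
  z <- glzlm_zones(d)
  n_z <- sum(z$count)
  n_v <- sum(d$mask)
  i <- z$level; j <- z$size; c_ <- z$count
  gl_marg <- tapply(c_, i, sum)
  sz_marg <- tapply(c_, j, sum)
  list(values = c(
    SZE_GLZLM = sum(c_ / j^2) / n_z,
    LZE_GLZLM = sum(c_ * j^2) / n_z,
    LGZE_GLZLM = sum(c_ / i^2) / n_z,
    HGZE_GLZLM = sum(c_ * i^2) / n_z,
    SZLGE_GLZLM = sum(c_ / (i^2 * j^2)) / n_z,
    SZHGE_GLZLM = sum(c_ * i^2 / j^2) / n_z,
    LZLGE_GLZLM = sum(c_ * j^2 / i^2) / n_z,
    LZHGE_GLZLM = sum(c_ * i^2 * j^2) / n_z,
    GLNU_GLZLM = sum(as.numeric(gl_marg)^2) / n_z,
    ZLNU_GLZLM = sum(as.numeric(sz_marg)^2) / n_z,
    ZP_GLZLM = n_z / n_v),
    flags = character())
}

#' Feature-extraction configuration
#'
#' All tunable parameters of the segmentation + texture chain, with the
#' analysis defaults: 120 HU bone threshold, axial crop fractions 0.02-0.88
#' of the skeleton span, 2500 HU prosthesis cut with a 10 mm margin,
#' 4 x 4 x 2 mm resampling, and 64-bin discretization over 0-30 SUV.
#'
#' @param hu_threshold,fill,closing_brush See [segment_skeleton()].
#' @param crop_fractions See [crop_axial_extent()].
#' @param prosthesis_hu_cut,prosthesis_margin_mm See [exclude_prosthesis()].
#' @param target_spacing_mm See [resample_pet()].
#' @param n_bins,suv_min,suv_max See [discretization_spec()].
#' @param peak_in_mask,sample_moments See [conventional_features()].
#' @param spill_suv Optional SUV threshold for the adjacent-uptake check
#'   ([check_adjacent_uptake()]); NULL disables it.
#' @return An `extraction_config` list.
#' @export
extraction_config <- function(hu_threshold = 120, fill = TRUE,
                              closing_brush = 3L,
                              crop_fractions = c(0.02, 0.88),
                              prosthesis_hu_cut = 2500,
                              prosthesis_margin_mm = 10,
                              target_spacing_mm = c(4, 4, 2),
                              n_bins = 64L, suv_min = 0, suv_max = 30,
                              peak_in_mask = TRUE, sample_moments = FALSE,
                              spill_suv = NULL) {
  structure(list(hu_threshold = hu_threshold, fill = fill,
                 closing_brush = closing_brush,
                 crop_fractions = crop_fractions,
                 prosthesis_hu_cut = prosthesis_hu_cut,
                 prosthesis_margin_mm = prosthesis_margin_mm,
                 target_spacing_mm = target_spacing_mm,
                 n_bins = n_bins, suv_min = suv_min, suv_max = suv_max,
                 peak_in_mask = peak_in_mask, sample_moments = sample_moments,
                 spill_suv = spill_suv),
            class = "extraction_config")
}

# Run one pipeline stage, prefixing any error with the stage name.
run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("[", stage, "] ", conditionMessage(e), call. = FALSE))
}

#' Extract all 26 features for one subject
#'
#' Runs the full chain on a paired CT/PET subject: skeleton segmentation on
#' CT, axial cropping, prosthesis exclusion, PET resampling, mask transfer,
#' discretization, then conventional, GLCM, NGLDM and GLZLM features under a
#' single discretization specification. Errors name the failing stage.
#'
#' @param ct,pet Paired [volume_grid()]s (HU and SUV).
#' @param config An [extraction_config()].
#' @return One-row data.frame with the 26 columns of
#'   [radiomic_feature_names()]; degenerate-feature flags are attached as
#'   `attr(, "flags")`.
#' @export
extract_features <- function(ct, pet, config = extraction_config()) {
  stopifnot(inherits(config, "extraction_config"))
  voi <- run_stage("segment_skeleton",
                   segment_skeleton(ct, config$hu_threshold, config$fill,
                                    config$closing_brush))
  voi <- run_stage("crop_axial_extent",
                   crop_axial_extent(voi, config$crop_fractions[1],
                                     config$crop_fractions[2]))
  voi <- run_stage("exclude_prosthesis",
                   exclude_prosthesis(voi, ct, config$prosthesis_hu_cut,
                                      config$prosthesis_margin_mm))
  pet_rs <- run_stage("resample_pet", resample_pet(pet, config$target_spacing_mm))
  voi_pet <- run_stage("transfer_to_pet", transfer_to_pet(voi, pet_rs))
  if (!any(voi_pet$mask))
    stop("[transfer_to_pet] skeleton VOI is empty on the PET grid")
  if (!is.null(config$spill_suv))
    run_stage("adjacent_uptake_check",
              check_adjacent_uptake(voi_pet, pet_rs, config$spill_suv))

  conv <- run_stage("conventional_features",
                    conventional_features(pet_rs, voi_pet, config$peak_in_mask,
                                          config$sample_moments))
  spec <- discretization_spec(config$n_bins, config$suv_min, config$suv_max)
  d <- run_stage("discretize", discretize(pet_rs, voi_pet, spec))
  glcm <- run_stage("glcm_features", glcm_features(d))
  ngldm <- run_stage("ngldm_features", ngldm_features(d))
  glzlm <- run_stage("glzlm_features", glzlm_features(d))

  values <- c(conv$values, glcm$values, ngldm$values, glzlm$values)
  out <- as.data.frame(as.list(values[radiomic_feature_names()]))
  attr(out, "flags") <- c(conv$flags, glcm$flags, ngldm$flags, glzlm$flags)
  out
}

#' Extract features for a whole phantom cohort
#'
#' Streams subjects: each CT/PET pair is generated from the truth table with
#' its per-subject child seed, features are extracted, and the volumes are
#' discarded, so memory stays flat regardless of cohort size.
#'
#' @param truth Truth table from [generate_truth_table()].
#' @param params [phantom_params()] used for every subject.
#' @param seed Master seed of the cohort (child seeds derive from it).
#' @param config An [extraction_config()].
#' @return Data.frame: `subject_id` plus the 26 feature columns.
#' @export
extract_features_cohort <- function(truth, params = phantom_params(),
                                    seed = 1L, config = extraction_config()) {
  rows <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    subj <- generate_subject(params, truth[i, ], child_seed(seed, i))
    fv <- extract_features(subj$ct, subj$pet, config)
    rows[[i]] <- cbind(subject_id = truth$subject_id[i], fv)
  }
  do.call(rbind, rows)
}
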