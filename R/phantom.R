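#' Phantom generation parameters
#'
#' Parameters of the synthetic CT/PET subject generator. The phantom is a
#' stylized skeleton — a vertical spine column with a cortical shell and a
#' marrow core, a pelvis slab with a marrow interior, and two solid femoral
#' stubs — embedded in soft tissue. It exercises the mask-then-texture chain;
#' it is not anatomical.
#'
#' Geometry is defined relative to the grid's physical extent so the same
#' template scales to smaller test grids. Defaults place the phantom on a
#' 64 x 64 x 160 voxel grid at 2 mm isotropic spacing (128 x 128 x 320 mm),
#' so that resampling to the 4 x 4 x 2 mm analysis spacing is a genuine
#' operation.
#'
#' Disease contrast has two controllable mechanisms: focal hot spheres
#' (`n_focal_lesions`, `lesion_suv`, `lesion_radius_mm`) emulating obvious
#' focal bone uptake, and a diffuse inflation of marrow SUV variance
#' (`diffuse_sd_multiplier`) emulating heterogeneous infiltration without
#' focal lesions.
#'
#' @param grid_shape Voxels per axis (x, y, z).
#' @param voxel_spacing_mm Voxel size in mm; all positive.
#' @param bone_hu,marrow_hu,soft_tissue_hu Mean HU of cortical bone, marrow
#'   and background soft tissue.
#' @param ct_noise_sd Additive Gaussian CT noise (HU).
#' @param marrow_suv_mean,marrow_suv_sd Baseline marrow uptake distribution.
#' @param soft_suv_mean,bone_suv_mean Background and cortical-bone SUV.
#' @param n_focal_lesions Number of focal hot spheres planted in marrow.
#' @param lesion_suv SUV of focal spheres; must be at least
#'   `marrow_suv_mean` when lesions are requested.
#' @param lesion_radius_mm Focal sphere radius (mm).
#' @param diffuse_sd_multiplier Factor (>= 1) inflating marrow SUV standard
#'   deviation for diffusely involved subjects.
#' @param prosthesis Plant a hip-prosthesis blob (>= 3000 HU) at the right
#'   femoral head.
#' @param prosthesis_hu HU value of the prosthesis blob.
#' @param noise_sd Additive Gaussian PET noise (SUV); the PET field is
#'   clipped at 0 afterwards.
#' @return A `phantom_params` list.
#' @export
phantom_params <- function(grid_shape = c(64, 64, 160),
                           voxel_spacing_mm = c(2, 2, 2),
                           bone_hu = 700, marrow_hu = 60, soft_tissue_hu = 40,
                           ct_noise_sd = 5,
                           marrow_suv_mean = 1.5, marrow_suv_sd = 0.3,
                           soft_suv_mean = 0.7, bone_suv_mean = 0.5,
                           n_focal_lesions = 0L, lesion_suv = 6,
                           lesion_radius_mm = 8,
                           diffuse_sd_multiplier = 1,
                           prosthesis = FALSE, prosthesis_hu = 3200,
                           noise_sd = 0.1) {
  p <- list(grid_shape = as.integer(grid_shape),
            voxel_spacing_mm = as.numeric(voxel_spacing_mm),
            bone_hu = bone_hu, marrow_hu = marrow_hu,
            soft_tissue_hu = soft_tissue_hu, ct_noise_sd = ct_noise_sd,
            marrow_suv_mean = marrow_suv_mean, marrow_suv_sd = marrow_suv_sd,
            soft_suv_mean = soft_suv_mean, bone_suv_mean = bone_suv_mean,
            n_focal_lesions = as.integer(n_focal_lesions),
            lesion_suv = lesion_suv, lesion_radius_mm = lesion_radius_mm,
            diffuse_sd_multiplier = diffuse_sd_multiplier,
            prosthesis = isTRUE(prosthesis), prosthesis_hu = prosthesis_hu,
            noise_sd = noise_sd)
  if (length(p$grid_shape) != 3L || any(p$grid_shape < 8L))
    stop("`grid_shape` must be three axis sizes of at least 8 voxels")
  if (length(p$voxel_spacing_mm) != 3L || any(p$voxel_spacing_mm <= 0))
    stop("`voxel_spacing_mm` must be three positive spacings")
  if (p$n_focal_lesions > 0L && p$lesion_suv < p$marrow_suv_mean)
    stop("`lesion_suv` must be >= `marrow_suv_mean` when lesions are planted")
  if (p$diffuse_sd_multiplier < 1)
    stop("`diffuse_sd_multiplier` must be >= 1")
  if (p$noise_sd < 0 || p$marrow_suv_sd < 0)
    stop("noise standard deviations must be non-negative")
  class(p) <- "phantom_params"
  p
}

#' Ground-truth tissue masks of the phantom template
#'
#' Deterministic geometry of the stylized skeleton: cortical bone shell,
#' marrow interior and (optionally) the prosthesis blob, on the grid defined
#' by `params`. `skeleton = bone | marrow` is the reference mask used to
#' score segmentation accuracy.
#'
#' @param params A [phantom_params()].
#' @return List of logical arrays `bone`, `marrow`, `prosthesis`, `skeleton`.
#' @export
phantom_truth_masks <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  n <- params$grid_shape; s <- params$voxel_spacing_mm
  ext <- n * s
  xc <- (seq_len(n[1]) - 0.5) * s[1]
  yc <- (seq_len(n[2]) - 0.5) * s[2]
  zc <- (seq_len(n[3]) - 0.5) * s[3]
  cx <- ext[1] / 2; cy <- ext[2] / 2
  rmin <- min(ext[1], ext[2])

  r2_spine <- outer((xc - cx)^2, (yc - cy)^2, `+`)
  in_z <- function(lo, hi) zc >= lo * ext[3] & zc <= hi * ext[3]
  cyl <- function(r2, radius, zlo, zhi) {
    m <- array(FALSE, n)
    zi <- which(in_z(zlo, zhi))
    if (length(zi)) m[, , zi] <- array(r2 <= radius^2, c(n[1], n[2], length(zi)))
    m
  }
  box <- function(xl, xh, yl, yh, zl, zh) {
    m <- array(FALSE, n)
    xi <- xc >= xl * ext[1] & xc <= xh * ext[1]
    yi <- yc >= yl * ext[2] & yc <= yh * ext[2]
    zi <- in_z(zl, zh)
    m[xi, yi, zi] <- TRUE
    m
  }

  spine_outer <- cyl(r2_spine, 0.11 * rmin, 0.275, 0.99)
  spine_core  <- cyl(r2_spine, 0.077 * rmin, 0.285, 0.98)
  pelvis_outer <- box(0.19, 0.81, 0.36, 0.64, 0.175, 0.30)
  pelvis_core  <- box(0.23, 0.77, 0.40, 0.60, 0.195, 0.28)
  femur <- array(FALSE, n)
  for (sgn in c(-1, 1)) {
    r2f <- outer((xc - (cx + sgn * 0.22 * ext[1]))^2, (yc - cy)^2, `+`)
    femur <- femur | cyl(r2f, 0.06 * rmin, 0.0125, 0.20)
  }

  marrow <- spine_core | pelvis_core
  bone <- (spine_outer | pelvis_outer | femur) & !marrow

  prosthesis <- array(FALSE, n)
  if (params$prosthesis) {
    ctr <- c(cx + 0.22 * ext[1], cy, 0.19 * ext[3])
    pr <- 0.09 * rmin
    d2 <- outer(outer((xc - ctr[1])^2, (yc - ctr[2])^2, `+`),
                (zc - ctr[3])^2, `+`)
    prosthesis <- d2 <= pr^2
    bone <- bone & !prosthesis
    marrow <- marrow & !prosthesis
  }
  list(bone = bone, marrow = marrow, prosthesis = prosthesis,
       skeleton = bone | marrow)
}

#' Generate one synthetic CT/PET subject
#'
#' Builds the paired CT and PET volumes on an identical grid. The CT holds
#' the stylized skeleton (cortical shell, marrow core, optional prosthesis
#' blob) over a soft-tissue background. The PET holds Gaussian marrow uptake
#' plus, depending on the subject's truth record, focal hot spheres (visually
#' positive disease) and/or diffusely inflated marrow variance (biopsy-positive
#' diffuse infiltration). Bitwise reproducible for a fixed seed.
#'
#' When `truth` is supplied, effect application follows its status fields:
#' focal lesions are planted only for `pet_visual == "+"` subjects, the
#' diffuse multiplier is applied only for `bmb == "+"` subjects (scaled by
#' `infiltration_burden` relative to a 0.35 reference burden), and negative
#' subjects receive neither. With `truth = NULL` the parameters are applied
#' literally.
#'
#' @param params A [phantom_params()].
#' @param truth Optional one-row truth record (see [generate_truth_table()]).
#' @param seed Integer seed; the caller's RNG state is untouched.
#' @return List with `volume_grid`s `ct` and `pet` plus the `truth_masks`.
#' @export
generate_subject <- function(params, truth = NULL, seed = 1L) {
  stopifnot(inherits(params, "phantom_params"))
  masks <- phantom_truth_masks(params)
  n <- params$grid_shape; s <- params$voxel_spacing_mm

  n_focal <- params$n_focal_lesions
  sd_mult <- params$diffuse_sd_multiplier
  if (!is.null(truth)) {
    positive <- identical(as.character(truth$bone_status), "positive")
    visual_pos <- identical(as.character(truth$pet_visual), "+")
    bmb_pos <- identical(as.character(truth$bmb), "+")
    n_focal <- if (positive && visual_pos) max(1L, n_focal) else 0L
    sd_mult <- if (positive && bmb_pos) {
      burden <- as.numeric(truth$infiltration_burden)
      max(1, 1 + (sd_mult - 1) * burden / 0.35)
    } else 1
  }

  with_seed(seed, {
    ct <- array(stats::rnorm(prod(n), params$soft_tissue_hu, params$ct_noise_sd), n)
    ct[masks$bone] <- ct[masks$bone] - params$soft_tissue_hu + params$bone_hu
    ct[masks$marrow] <- ct[masks$marrow] - params$soft_tissue_hu + params$marrow_hu
    if (params$prosthesis) ct[masks$prosthesis] <- params$prosthesis_hu

    pet <- array(params$soft_suv_mean, n)
    pet[masks$bone] <- params$bone_suv_mean
    nm <- sum(masks$marrow)
    pet[masks$marrow] <- stats::rnorm(nm, params$marrow_suv_mean,
                                      params$marrow_suv_sd * sd_mult)

    if (n_focal > 0L) {
      marrow_idx <- which(masks$marrow)
      if (length(marrow_idx) == 0L)
        stop("cannot place focal lesions: phantom has no marrow voxels")
      centres <- sample(marrow_idx, n_focal, replace = n_focal > length(marrow_idx))
      ai <- arrayInd(centres, n)
      w <- which(masks$marrow, arr.ind = TRUE)
      wmm <- sweep(w - 0.5, 2, s, `*`)
      for (k in seq_len(nrow(ai))) {
        cmm <- (ai[k, ] - 0.5) * s
        d2 <- (wmm[, 1] - cmm[1])^2 + (wmm[, 2] - cmm[2])^2 + (wmm[, 3] - cmm[3])^2
        hit <- which(masks$marrow)[d2 <= params$lesion_radius_mm^2]
        pet[hit] <- pmax(pet[hit], params$lesion_suv)
      }
    }

    if (params$noise_sd > 0)
      pet <- pet + array(stats::rnorm(prod(n), 0, params$noise_sd), n)
    pet[pet < 0] <- 0

    list(ct = volume_grid(ct, s), pet = volume_grid(pet, s),
         truth_masks = masks)
  })
}

#' Generate the per-subject ground-truth table of a cohort
#'
#' Assigns bone status by prevalence, splits positives among the
#' biopsy/visual subgroups (BMB-/PET+, BMB+/PET-, BMB+/PET+; default split
#' 4:14:12), plants an infiltration burden for positives, and draws
#' biomarkers. Haemoglobin carries a planted negative monotone dependence on
#' infiltration burden; LDH a mild positive one; white cells and platelets
#' are uninformative noise.
#'
#' The composite gold standard holds by construction: `bone_status` is
#' `"positive"` iff biopsy or visual PET is positive.
#'
#' @param n_subjects Cohort size.
#' @param prevalence Fraction of bone-positive subjects, in `[0, 1]`.
#' @param subgroup_split Relative sizes of the BMB-/PET+, BMB+/PET- and
#'   BMB+/PET+ subgroups among positives.
#' @param seed Integer seed.
#' @return A data.frame with one row per subject: `subject_id`, `bmb`,
#'   `pet_visual`, `bone_status`, `infiltration_burden`, `haemoglobin_g_dl`,
#'   `wbc_g_l`, `platelets_g_l`, `ldh_ui_l`.
#' @export
generate_truth_table <- function(n_subjects, prevalence = 30 / 66,
                                 subgroup_split = c(4, 14, 12), seed = 1L) {
  if (prevalence < 0 || prevalence > 1) stop("`prevalence` must be in [0, 1]")
  if (n_subjects < 1) stop("`n_subjects` must be positive")
  n_pos <- round(n_subjects * prevalence)
  n_neg <- n_subjects - n_pos

  # largest-remainder apportionment of positives among the three subgroups
  w <- subgroup_split / sum(subgroup_split)
  base <- floor(w * n_pos)
  rem <- n_pos - sum(base)
  if (rem > 0) {
    ord <- order(w * n_pos - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }

  bmb <- c(rep("-", n_neg), rep(c("-", "+", "+"), times = base))
  pet_visual <- c(rep("-", n_neg), rep(c("+", "-", "+"), times = base))

  with_seed(seed, {
    ord <- sample.int(n_subjects)
    bmb <- bmb[ord]; pet_visual <- pet_visual[ord]
    bone_status <- ifelse(bmb == "+" | pet_visual == "+", "positive", "negative")
    burden <- ifelse(bone_status == "positive", stats::runif(n_subjects, 0.1, 0.6), 0)
    data.frame(
      subject_id = sprintf("S%03d", seq_len(n_subjects)),
      bmb = bmb, pet_visual = pet_visual, bone_status = bone_status,
      infiltration_burden = burden,
      haemoglobin_g_dl = stats::rnorm(n_subjects, 13.3 - 3 * burden, 1.5),
      wbc_g_l = pmax(0.5, stats::rnorm(n_subjects, 6.8, 2.9)),
      platelets_g_l = pmax(10, stats::rnorm(n_subjects, 225, 105)),
      ldh_ui_l = pmax(40, stats::rnorm(n_subjects, 200 + 150 * burden, 60)),
      stringsAsFactors = FALSE)
  })
}

#' Generate a full phantom cohort
#'
#' Draws the truth table, then generates each subject's CT/PET pair with a
#' per-subject child seed (`(1009 * seed + 7919 * i) mod (2^31 - 1)`), so any
#' subject can be regenerated independently of the rest of the cohort.
#'
#' @inheritParams generate_truth_table
#' @param params Base [phantom_params()]; per-subject effects follow each
#'   subject's truth record (see [generate_subject()]).
#' @param out_dir If non-NULL, write per-subject NIfTI volumes
#'   (`<id>_ct.nii.gz`, `<id>_pet.nii.gz`), `truth.csv` and a
#'   `phantom_params.json` sidecar there.
#' @param return_volumes Keep generated volumes in the returned list (only
#'   sensible for small cohorts/grids).
#' @return List with `truth` (data.frame), `params`, `seed`, and — when
#'   `return_volumes` — `volumes`, a per-subject list of `ct`/`pet` pairs.
#' @export
generate_cohort <- function(n_subjects, prevalence = 30 / 66,
                            params = phantom_params(),
                            subgroup_split = c(4, 14, 12), seed = 1L,
                            out_dir = NULL, return_volumes = FALSE) {
  truth <- generate_truth_table(n_subjects, prevalence, subgroup_split, seed)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  volumes <- if (return_volumes) vector("list", n_subjects) else NULL
  for (i in seq_len(n_subjects)) {
    if (is.null(out_dir) && !return_volumes) break
    subj <- generate_subject(params, truth[i, ], child_seed(seed, i))
    if (!is.null(out_dir)) {
      write_volume(subj$ct, file.path(out_dir, paste0(truth$subject_id[i], "_ct.nii.gz")))
      write_volume(subj$pet, file.path(out_dir, paste0(truth$subject_id[i], "_pet.nii.gz")))
    }
    if (return_volumes) volumes[[i]] <- subj[c("ct", "pet")]
  }
  if (!is.null(out_dir)) {
    utils::write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
    jsonlite::write_json(unclass(params), file.path(out_dir, "phantom_params.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out <- list(truth = truth, params = params, seed = seed)
  if (return_volumes) {
    names(volumes) <- truth$subject_id
    out$volumes <- volumes
  }
  out
}

#' Simulate a radiomic feature table with planted informative features
#'
#' Table-level generator for feature-selection experiments: 26 standard
#' normal feature columns, of which `informative` receive a mean shift of
#' `effect_sd` (in within-group SD units) between classes, signed to mirror
#' the directions of the published signature (busyness decreases in
#' positives, the three GLCM features increase).
#'
#' @param n Number of subjects.
#' @param informative Names of informative columns (default: the four
#'   features of the published signature).
#' @param effect_sd Standardized mean difference planted in informative
#'   columns.
#' @param prevalence Fraction of positive labels.
#' @param seed Integer seed.
#' @return List with `features` (n x 26 data.frame) and binary `labels`.
#' @export
simulate_feature_table <- function(n, informative = c("variance_GLCM",
                                                      "correlation_GLCM",
                                                      "joint_entropy_GLCM",
                                                      "busyness_NGLDM"),
                                   effect_sd = 1, prevalence = 0.5, seed = 1L) {
  nm <- radiomic_feature_names()
  stopifnot(all(informative %in% nm))
  with_seed(seed, {
    labels <- as.integer(seq_len(n) <= round(n * prevalence))
    labels <- sample(labels)
    x <- matrix(stats::rnorm(n * length(nm)), n, length(nm),
                dimnames = list(NULL, nm))
    for (f in informative) {
      sgn <- if (f == "busyness_NGLDM") -1 else 1
      x[, f] <- x[, f] + sgn * effect_sd * labels
    }
    list(features = as.data.frame(x), labels = labels)
  })
}
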