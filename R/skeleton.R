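#' Skeleton volume of interest
#'
#' A binary mask on a voxel grid together with the provenance of how it was
#' produced (crop fractions, prosthesis exclusions). Constructed by
#' [segment_skeleton()] and refined by [crop_axial_extent()],
#' [exclude_prosthesis()] and [transfer_to_pet()].
#'
#' @param mask Logical 3-D array.
#' @param spacing Voxel spacing in mm.
#' @param origin World coordinate of the first voxel centre.
#' @param crop_fractions Axial crop recorded as `(z_low, z_high)` fractions,
#'   or NULL if uncropped.
#' @param excluded_regions List describing removed prosthesis components.
#' @param source Imaging source of the mask, `"CT"`.
#' @return A `skeleton_voi` object.
#' @export
skeleton_voi <- function(mask, spacing, origin = c(0, 0, 0),
                         crop_fractions = NULL, excluded_regions = list(),
                         source = "CT") {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  structure(list(mask = mask, spacing = as.numeric(spacing),
                 origin = as.numeric(origin),
                 crop_fractions = crop_fractions,
                 excluded_regions = excluded_regions, source = source),
            class = "skeleton_voi")
}

#' @export
print.skeleton_voi <- function(x, ...) {
  cat("<skeleton_voi> ", sum(x$mask), " voxels (",
      format(sum(x$mask) * prod(x$spacing) / 1000, digits = 4), " mL) on a ",
      paste(dim(x$mask), collapse = " x "), " grid\n", sep = "")
  if (!is.null(x$crop_fractions))
    cat("  axial crop: [", x$crop_fractions[1], ", ", x$crop_fractions[2], "]\n", sep = "")
  if (length(x$excluded_regions))
    cat("  prosthesis components excluded:", length(x$excluded_regions), "\n")
  invisible(x)
}

#' Segment the skeleton from CT
#'
#' Thresholds the CT at `hu_threshold`, optionally applies per-axial-slice
#' morphological closing and hole filling so the marrow interior of cortical
#' shells is included in the mask, and retains the largest 26-connected
#' component(s). Fully deterministic.
#'
#' @param ct A [volume_grid()] in Hounsfield units.
#' @param hu_threshold Bone threshold in HU (default 120).
#' @param fill Include shell interiors via per-slice closing + hole filling.
#' @param closing_brush Width (voxels, odd) of the 2-D box brush used for
#'   per-slice closing before hole filling.
#' @param keep_components How many of the largest connected components to
#'   retain (default 1).
#' @return A [skeleton_voi()] on the CT grid. An empty mask (no voxel above
#'   threshold) is returned with a warning, not an error.
#' @export
segment_skeleton <- function(ct, hu_threshold = 120, fill = TRUE,
                             closing_brush = 3L, keep_components = 1L) {
  stopifnot(inherits(ct, "volume_grid"))
  if (!is.finite(hu_threshold)) stop("`hu_threshold` must be finite")
  bin <- ct$data >= hu_threshold
  if (!any(bin)) {
    warning("no CT voxel at or above ", hu_threshold, " HU; returning an empty mask")
    return(skeleton_voi(bin, ct$spacing, ct$origin))
  }
  if (fill) {
    num <- array(as.numeric(bin), dim(bin))
    if (closing_brush >= 3L)
      num <- EBImage::closing(num, EBImage::makeBrush(as.integer(closing_brush), "box"))
    num <- EBImage::fillHull(num)
    bin <- num > 0.5
  }
  lab <- label_components_3d(bin)
  sizes <- tabulate(lab[lab > 0L])
  keep <- order(sizes, decreasing = TRUE)[seq_len(min(keep_components, length(sizes)))]
  mask <- array(lab %in% keep, dim(bin))
  skeleton_voi(mask, ct$spacing, ct$origin)
}

#' Crop a skeleton VOI to an axial sub-extent
#'
#' Zeroes the mask outside `[z_low_frac, z_high_frac]` of the skeleton's own
#' axial span (not the grid's), approximating the analysis extent running
#' from the C3 vertebra to the upper third of the femurs. The fractions are
#' recorded in the VOI provenance.
#'
#' @param voi A [skeleton_voi()].
#' @param z_low_frac,z_high_frac Fractions in `[0, 1]` with
#'   `z_low_frac < z_high_frac`; 0 is the inferior end of the mask span.
#' @return The cropped [skeleton_voi()].
#' @export
crop_axial_extent <- function(voi, z_low_frac = 0.02, z_high_frac = 0.88) {
  stopifnot(inherits(voi, "skeleton_voi"))
  if (!(z_low_frac >= 0 && z_low_frac < z_high_frac && z_high_frac <= 1))
    stop("crop fractions must satisfy 0 <= z_low_frac < z_high_frac <= 1")
  voi$crop_fractions <- c(z_low_frac, z_high_frac)
  zs <- which(apply(voi$mask, 3, any))
  if (length(zs) == 0L) return(voi)
  z1 <- min(zs); z2 <- max(zs)
  lo <- z1 + z_low_frac * (z2 - z1)
  hi <- z1 + z_high_frac * (z2 - z1)
  drop_z <- which(seq_len(dim(voi$mask)[3]) < lo - 1e-9 |
                    seq_len(dim(voi$mask)[3]) > hi + 1e-9)
  if (length(drop_z)) voi$mask[, , drop_z] <- FALSE
  voi
}

#' Exclude prosthesis regions from a skeleton VOI
#'
#' Finds 26-connected components of CT voxels at or above `hu_cut`
#' (metal-bright, default 2500 HU), dilates each by `margin_mm` in physical
#' space, and removes the dilated regions from the mask to avoid PET
#' attenuation-correction artefacts around hip prostheses. Removals are
#' logged in the VOI provenance; a CT without metal-bright voxels passes
#' through unchanged.
#'
#' @param voi A [skeleton_voi()] on the CT grid.
#' @param ct The source [volume_grid()] in HU.
#' @param hu_cut Metal threshold in HU.
#' @param margin_mm Safety margin (mm, >= 0) dilating each component.
#' @return The [skeleton_voi()] with prosthesis zones removed.
#' @export
exclude_prosthesis <- function(voi, ct, hu_cut = 2500, margin_mm = 10) {
  stopifnot(inherits(voi, "skeleton_voi"), inherits(ct, "volume_grid"))
  if (margin_mm < 0) stop("`margin_mm` must be >= 0")
  metal <- ct$data >= hu_cut
  if (!any(metal)) return(voi)
  lab <- label_components_3d(metal)
  for (comp in seq_len(max(lab))) {
    region <- lab == comp
    n_core <- sum(region)
    if (margin_mm > 0) region <- dilate_mm(region, ct$spacing, margin_mm)
    removed <- sum(voi$mask & region)
    voi$mask <- voi$mask & !region
    voi$excluded_regions <- c(voi$excluded_regions,
                              list(list(component = comp, hu_cut = hu_cut,
                                        margin_mm = margin_mm,
                                        metal_voxels = n_core,
                                        mask_voxels_removed = removed)))
  }
  voi
}

#' Transfer a CT-derived VOI to the PET grid
#'
#' Resamples the binary mask to the PET grid by nearest neighbour: each PET
#' voxel takes the mask value at the CT voxel whose centre is nearest to the
#' PET voxel centre, so binary masks stay binary.
#'
#' @param voi A [skeleton_voi()] on the CT grid.
#' @param pet A [volume_grid()] defining the target grid.
#' @return A [skeleton_voi()] on the PET grid (provenance carried over).
#' @export
transfer_to_pet <- function(voi, pet) {
  stopifnot(inherits(voi, "skeleton_voi"), inherits(pet, "volume_grid"))
  src_ext <- rbind(lo = voi$origin - voi$spacing / 2,
                   hi = voi$origin + (dim(voi$mask) - 1) * voi$spacing + voi$spacing / 2)
  dst_ext <- volume_extent(pet)
  if (any(dst_ext["lo", ] >= src_ext["hi", ] | dst_ext["hi", ] <= src_ext["lo", ]))
    stop("CT and PET grids do not overlap in physical space")
  idx <- lapply(1:3, function(ax) {
    w <- pet$origin[ax] + (seq_len(dim(pet$data)[ax]) - 1) * pet$spacing[ax]
    f <- round((w - voi$origin[ax]) / voi$spacing[ax]) + 1
    pmin(pmax(f, 1L), dim(voi$mask)[ax])
  })
  mask <- voi$mask[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  dim(mask) <- dim(pet$data)
  skeleton_voi(mask, pet$spacing, pet$origin,
               crop_fractions = voi$crop_fractions,
               excluded_regions = voi$excluded_regions, source = voi$source)
}

#' Warn about hot uptake adjacent to the VOI
#'
#' Reports PET voxels in the one-voxel outer shell of the mask whose SUV
#' exceeds `suv_threshold` — a screening aid for lymph-node spill-in near the
#' skeleton. The mask is never edited automatically.
#'
#' @param voi A [skeleton_voi()] on the PET grid.
#' @param pet The PET [volume_grid()].
#' @param suv_threshold SUV above which a shell voxel is flagged.
#' @return Number of flagged shell voxels, invisibly; warns when positive.
#' @export
check_adjacent_uptake <- function(voi, pet, suv_threshold = 4) {
  stopifnot(inherits(voi, "skeleton_voi"), inherits(pet, "volume_grid"))
  shell <- dilate_mm(voi$mask, voi$spacing, max(voi$spacing)) & !voi$mask
  n_hot <- sum(pet$data[shell] > suv_threshold)
  if (n_hot > 0)
    warning(n_hot, " voxel(s) adjacent to the skeleton VOI exceed ",
            suv_threshold, " SUV; check for lymph-node spill-in")
  invisible(n_hot)
}
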