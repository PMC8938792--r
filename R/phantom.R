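#' @title Synthetic sinus-CT phantoms
#' @description Seeded generator of head-CT-like volumes containing the 12
#'   scored sinonasal cavities as disjoint ellipsoids embedded in soft tissue
#'   behind a thin bone shell, with a controllable opacification fraction per
#'   cavity and exact voxel-level ground truth. The phantoms stand in for
#'   clinical CT so that segmentation, volumetry and scoring can be exercised
#'   end to end with a known answer.
#' @name phantom
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Construct a CT volume container
#'
#' @param data 3D numeric array of intensities (Hounsfield-unit scale).
#' @param spacing_mm per-axis voxel size in mm (length 3).
#' @param axes orientation tag: what each array axis runs along. Defaults to
#'   `c("LR", "PA", "IS")` (left-right, posterior-anterior i.e.
#'   anteroposterior, inferior-superior); coronal slices are planes of
#'   constant second-axis index.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(data, spacing_mm = c(1, 1, 1),
                      axes = c("LR", "PA", "IS")) {
  stopifnot(length(dim(data)) == 3, length(spacing_mm) == 3,
            all(spacing_mm > 0))
  structure(list(data = data, spacing_mm = as.numeric(spacing_mm),
                 axes = axes), class = "ct_volume")
}

#' Construct a label-map container aligned to a volume
#'
#' @param data 3D integer array; 0 = background, 1..12 = region class ids.
#' @inheritParams ct_volume
#' @return An object of class `ct_labelmap`.
#' @export
ct_labelmap <- function(data, spacing_mm = c(1, 1, 1),
                        axes = c("LR", "PA", "IS")) {
  stopifnot(length(dim(data)) == 3)
  storage.mode(data) <- "integer"
  structure(list(data = data, spacing_mm = as.numeric(spacing_mm),
                 axes = axes), class = "ct_labelmap")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat("<ct_volume> ", paste(dim(x$data), collapse = "x"),
      " voxels, spacing ", paste(x$spacing_mm, collapse = "x"),
      " mm, axes ", paste(x$axes, collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' @export
print.ct_labelmap <- function(x, ...) {
  cat("<ct_labelmap> ", paste(dim(x$data), collapse = "x"),
      " voxels, ", length(setdiff(unique(as.vector(x$data)), 0L)),
      " labelled regions\n", sep = "")
  invisible(x)
}

#' Describe one cavity of a phantom
#'
#' @param region_id one of [sinus_regions()] (or any identifier for ad-hoc
#'   test geometries).
#' @param center_mm cavity centre in mm (length 3).
#' @param radii_mm semi-axes in mm (ellipsoid) or half-widths (box).
#' @param opac_fraction fraction of the cavity filled with mucosa-intensity
#'   (disease) tissue, filled from the cavity wall inward; in `[0, 1]`.
#' @param shape `"ellipsoid"` (default) or `"box"`.
#' @return A `region_geometry` list.
#' @export
region_geometry <- function(region_id, center_mm, radii_mm,
                            opac_fraction = 0, shape = c("ellipsoid", "box")) {
  shape <- match.arg(shape)
  stopifnot(length(center_mm) == 3, length(radii_mm) == 3, all(radii_mm > 0),
            is.numeric(opac_fraction), length(opac_fraction) == 1)
  if (opac_fraction < 0 || opac_fraction > 1)
    stop("opac_fraction must be in [0, 1]")
  structure(list(region_id = as.character(region_id),
                 center_mm = as.numeric(center_mm),
                 radii_mm = as.numeric(radii_mm),
                 opac_fraction = opac_fraction, shape = shape),
            class = "region_geometry")
}

#' Canonical cavity geometries for a grid
#'
#' Places the 12 sinonasal cavities of the canonical head layout into a grid,
#' optionally rescaling each cavity's radii and jittering its centre.
#'
#' @param grid_shape voxels per axis (length 3).
#' @param spacing_mm voxel size in mm (length 3).
#' @param opac_fractions per-region opacification fractions: a named numeric
#'   vector (missing regions default to 0), an unnamed length-12 vector in
#'   [sinus_regions()] order, or a single number applied to all regions.
#' @param volume_scale named vector of per-region cavity-volume multipliers
#'   relative to [region_reference_volumes()] at the default head extent;
#'   radii scale with its cube root, clamped to `[0.42, 1.95]` in volume to
#'   keep cavities disjoint.
#' @param center_jitter_frac per-axis uniform centre jitter, as a fraction of
#'   the grid extent.
#' @return List of [region_geometry()] objects in class-id order.
#' @export
sinus_region_geometries <- function(grid_shape = c(32, 32, 32),
                                    spacing_mm = c(3, 3, 3),
                                    opac_fractions = 0,
                                    volume_scale = NULL,
                                    center_jitter_frac = 0) {
  lay <- sinus_canonical_layout()
  extent <- grid_shape * spacing_mm
  regs <- sinus_regions()
  if (is.null(names(opac_fractions))) {
    if (length(opac_fractions) == 1)
      opac_fractions <- setNames(rep(opac_fractions, 12), regs)
    else if (length(opac_fractions) == 12)
      opac_fractions <- setNames(opac_fractions, regs)
    else
      stop("unnamed opac_fractions must have length 1 or 12")
  }
  vs <- setNames(rep(1, 12), regs)
  if (!is.null(volume_scale)) vs[names(volume_scale)] <- volume_scale
  vs <- pmin(pmax(vs, 0.42), 1.95)
  lapply(seq_len(nrow(lay)), function(i) {
    rid <- lay$region_id[i]
    ctr <- c(lay$cx[i], lay$cy[i], lay$cz[i])
    if (center_jitter_frac > 0)
      ctr <- ctr + runif(3, -center_jitter_frac, center_jitter_frac)
    rad <- c(lay$rx[i], lay$ry[i], lay$rz[i]) * vs[[rid]]^(1 / 3)
    of <- if (rid %in% names(opac_fractions)) opac_fractions[[rid]] else 0
    region_geometry(rid, center_mm = ctr * extent, radii_mm = rad * extent,
                    opac_fraction = of)
  })
}

#' Specify a synthetic sinus-CT phantom
#'
#' @inheritParams sinus_region_geometries
#' @param regions list of [region_geometry()] objects; defaults to the
#'   canonical 12-cavity head layout.
#' @param noise_sd standard deviation of additive Gaussian intensity noise
#'   (HU). Default 15, a plausible soft-tissue CT noise level.
#' @param hu_air,hu_mucosa,hu_bone mean intensities of air, mucosa/soft
#'   tissue and bone. Defaults -1000, +40, +700 HU.
#' @param bone_shell_scale the bone wall occupies normalised cavity radii
#'   `(1, bone_shell_scale]`.
#' @param seed integer seed; identical spec + seed gives bit-identical output.
#' @return A `phantom_spec` list, validated against its invariants.
#' @export
phantom_spec <- function(grid_shape = c(32, 32, 32), spacing_mm = c(3, 3, 3),
                         regions = NULL, opac_fractions = 0,
                         noise_sd = 15, hu_air = -1000, hu_mucosa = 40,
                         hu_bone = 700, bone_shell_scale = 1.22, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, length(spacing_mm) == 3)
  if (any(grid_shape < 16)) stop("grid_shape must be >= 16 along every axis")
  if (any(spacing_mm <= 0)) stop("spacing_mm must be positive")
  if (!(hu_air < hu_mucosa && hu_mucosa < hu_bone))
    stop("intensities must satisfy hu_air < hu_mucosa < hu_bone")
  if (is.null(regions))
    regions <- sinus_region_geometries(grid_shape, spacing_mm,
                                       opac_fractions = opac_fractions)
  ofr <- vapply(regions, `[[`, numeric(1), "opac_fraction")
  if (any(ofr < 0 | ofr > 1)) stop("opacification fractions must be in [0, 1]")
  structure(list(grid_shape = grid_shape, spacing_mm = as.numeric(spacing_mm),
                 regions = regions, noise_sd = noise_sd, hu_air = hu_air,
                 hu_mucosa = hu_mucosa, hu_bone = hu_bone,
                 bone_shell_scale = bone_shell_scale, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Normalised squared radius of every voxel centre w.r.t. one geometry,
# restricted to the geometry's bounding box. Returns flat voxel indices of
# inside voxels plus their rho^2 (wall proximity = high rho).
rasterize_region <- function(geom, grid_shape, spacing_mm, scale = 1) {
  ctr <- geom$center_mm
  rad <- geom$radii_mm * scale
  lo <- pmax(1L, floor((ctr - rad) / spacing_mm + 0.5))
  hi <- pmin(grid_shape, ceiling((ctr + rad) / spacing_mm + 0.5))
  if (any(lo > hi)) return(list(idx = integer(0), rho2 = numeric(0)))
  ax <- lapply(1:3, function(a) ((lo[a]:hi[a]) - 0.5) * spacing_mm[a])
  d1 <- (ax[[1]] - ctr[1]) / rad[1]
  d2 <- (ax[[2]] - ctr[2]) / rad[2]
  d3 <- (ax[[3]] - ctr[3]) / rad[3]
  n1 <- length(d1); n2 <- length(d2); n3 <- length(d3)
  if (geom$shape == "box") {
    inside1 <- abs(d1) <= 1; inside2 <- abs(d2) <= 1; inside3 <- abs(d3) <= 1
    rho2 <- outer(outer(pmax(abs(d1), 0), pmax(abs(d2), 0), pmax),
                  pmax(abs(d3), 0), pmax)^2
    ok <- outer(outer(inside1, inside2, `&`), inside3, `&`)
  } else {
    rho2 <- outer(outer(d1^2, d2^2, `+`), d3^2, `+`)
    ok <- rho2 <= 1
  }
  ii <- which(ok)
  if (!length(ii)) return(list(idx = integer(0), rho2 = numeric(0)))
  coord <- arrayInd(ii, c(n1, n2, n3))
  flat <- (lo[1] - 1L + coord[, 1]) +
    as.numeric(grid_shape[1]) * ((lo[2] - 2L + coord[, 2]) +
      as.numeric(grid_shape[2]) * (lo[3] - 2L + coord[, 3]))
  list(idx = flat, rho2 = rho2[ii])
}

#' Generate a synthetic sinus-CT phantom
#'
#' Rasterises the cavities of `spec` into a label map, realises each cavity's
#' opacification fraction by filling voxels from the cavity wall inward
#' (mucosal-thickening pattern: voxels ordered by decreasing normalised
#' radius, ties broken by voxel index), surrounds each cavity with a bone
#' shell, embeds everything in soft tissue and adds Gaussian intensity noise.
#'
#' @param spec a [phantom_spec()].
#' @return List with elements `volume` ([ct_volume]), `labels`
#'   ([ct_labelmap]) and `truth`, a data frame of exact per-region voxel
#'   counts, volumes (mL), opacification ratios and score contributions (see
#'   [region_volumes()] for the same table estimated from data).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gs <- spec$grid_shape
  nvox <- prod(gs)
  lab <- integer(nvox)
  owner <- character(0)
  cav <- vector("list", length(spec$regions))
  for (i in seq_along(spec$regions)) {
    g <- spec$regions[[i]]
    r <- rasterize_region(g, gs, spec$spacing_mm)
    clash <- lab[r$idx] != 0L
    if (any(clash)) {
      other <- spec$regions[[lab[r$idx][which(clash)[1]]]]$region_id
      stop("overlapping regions: ", g$region_id, " collides with ", other)
    }
    lab[r$idx] <- i
    cav[[i]] <- r
  }
  # bone shell: inside scaled ellipsoid but not in any cavity
  bone <- logical(nvox)
  for (i in seq_along(spec$regions)) {
    g <- spec$regions[[i]]
    r <- rasterize_region(g, gs, spec$spacing_mm, scale = spec$bone_shell_scale)
    bone[r$idx] <- TRUE
  }
  bone[lab != 0L] <- FALSE

  # opacification: fill quota voxels from the wall inward
  diseased <- logical(nvox)
  truth <- data.frame(region_id = vapply(spec$regions, `[[`, character(1),
                                         "region_id"),
                      total_vox = 0, disease_vox = 0, stringsAsFactors = FALSE)
  for (i in seq_along(spec$regions)) {
    r <- cav[[i]]
    n <- length(r$idx)
    truth$total_vox[i] <- n
    quota <- round(spec$regions[[i]]$opac_fraction * n)
    if (quota > 0 && n > 0) {
      ord <- order(-r$rho2, r$idx)
      diseased[r$idx[ord[seq_len(quota)]]] <- TRUE
      truth$disease_vox[i] <- quota
    }
  }

  intens <- rep(spec$hu_mucosa, nvox)       # background soft tissue
  intens[bone] <- spec$hu_bone
  incav <- lab != 0L
  intens[incav] <- ifelse(diseased[incav], spec$hu_mucosa, spec$hu_air)
  if (spec$noise_sd > 0)
    intens <- intens + with_seed(spec$seed, rnorm(nvox, 0, spec$noise_sd))

  vol_ml <- prod(spec$spacing_mm) / 1000
  truth$air_vox <- truth$total_vox - truth$disease_vox
  truth$total_ml <- truth$total_vox * vol_ml
  truth$air_ml <- truth$air_vox * vol_ml
  truth$disease_ml <- truth$disease_vox * vol_ml
  truth$ratio <- ifelse(truth$total_vox > 0,
                        truth$disease_vox / truth$total_vox, 0)
  truth$vmlms_sub <- 2 * truth$ratio
  truth$tlms_sub <- tlms_grade(truth$ratio, truth$region_id)

  dim(intens) <- gs
  dim(lab) <- gs
  list(volume = ct_volume(intens, spec$spacing_mm),
       labels = ct_labelmap(lab, spec$spacing_mm),
       truth = truth)
}

#' Reslice a volume into coronal planes
#'
#' Cuts the volume (and an optional aligned label map) into 2D coronal
#' slices, i.e. planes of constant index along the anteroposterior axis of
#' the orientation tag. Stacking the slices back with
#' [stack_segmentations()] reconstructs the input exactly.
#'
#' @param volume a [ct_volume()].
#' @param labelmap optional aligned [ct_labelmap()].
#' @return List with `images` (list of 2D matrices, in-plane axes =
#'   left-right by inferosuperior), `labels` (or `NULL`), `axis` (the array
#'   axis sliced along), `spacing_mm` and `n`.
#' @export
reslice_coronal <- function(volume, labelmap = NULL) {
  stopifnot(inherits(volume, "ct_volume"))
  if (is.null(volume$axes)) stop("volume has no axis-orientation tag")
  ax <- match("PA", volume$axes)
  if (is.na(ax)) stop("orientation tag lacks an anteroposterior (PA) axis")
  n <- dim(volume$data)[ax]
  slice_fun <- switch(ax,
                      function(a, k) a[k, , ],
                      function(a, k) a[, k, ],
                      function(a, k) a[, , k])
  images <- lapply(seq_len(n), function(k) slice_fun(volume$data, k))
  labels <- NULL
  if (!is.null(labelmap)) {
    stopifnot(identical(dim(labelmap$data), dim(volume$data)))
    labels <- lapply(seq_len(n), function(k) slice_fun(labelmap$data, k))
  }
  list(images = images, labels = labels, axis = ax,
       spacing_mm = volume$spacing_mm, n = n)
}

#' Write a phantom to NIfTI + JSON ground truth
#'
#' @param phantom result of [generate_phantom()].
#' @param dir output directory (created if absent).
#' @param prefix file-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_phantom <- function(phantom, dir, prefix = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pv <- file.path(dir, paste0(prefix, "_image.nii.gz"))
  pl <- file.path(dir, paste0(prefix, "_labels.nii.gz"))
  pt <- file.path(dir, paste0(prefix, "_truth.json"))
  write_nifti_volume(phantom$volume, pv)
  write_nifti_volume(phantom$labels, pl)
  jsonlite::write_json(phantom$truth, pt, digits = NA, auto_unbox = TRUE)
  invisible(c(image = pv, labels = pl, truth = pt))
}

write_nifti_volume <- function(x, path) {
  img <- RNifti::asNifti(x$data)
  RNifti::pixdim(img) <- x$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a CT volume / label map from NIfTI
#'
#' @param path NIfTI file.
#' @param axes orientation tag to attach (the phantom writer uses the
#'   default LR/PA/IS axis order).
#' @return A [ct_volume()] (`read_ct_volume`) or [ct_labelmap()]
#'   (`read_ct_labelmap`).
#' @export
read_ct_volume <- function(path, axes = c("LR", "PA", "IS")) {
  img <- RNifti::readNifti(path)
  a <- array(as.numeric(img), dim = dim(img))
  ct_volume(a, RNifti::pixdim(img)[1:3], axes)
}

#' @rdname read_ct_volume
#' @export
read_ct_labelmap <- function(path, axes = c("LR", "PA", "IS")) {
  img <- RNifti::readNifti(path)
  a <- array(as.integer(img), dim = dim(img))
  ct_labelmap(a, RNifti::pixdim(img)[1:3], axes)
}
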