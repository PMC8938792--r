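#' @title Volumetry and Lund-Mackay scoring
#' @description Stacks per-slice segmentations back into 3D, partitions each
#'   labelled cavity into air and disease voxels by an intensity threshold,
#'   and computes the continuous volume-based modified Lund-Mackay score
#'   (VMLMs; 2 x opacification ratio per region, summed, range 0-24) and an
#'   automated traditional Lund-Mackay score (TLMs; 0/1/2 grades, OMC graded
#'   0/2, summed, range 0-24).
#' @name volumetrics
NULL

#' Traditional Lund-Mackay grade from an opacification ratio
#'
#' Sinuses are graded 0 (clear, ratio below `partial_low`), 1 (partial) or
#' 2 (complete, ratio above `complete_high`). The ostiomeatal complex is
#' graded 0 or 2 only (2 if more than half occluded), per the standard
#' rubric. The rubric itself is categorical; the numeric cut-offs that
#' automate it are exposed as parameters.
#'
#' @param ratio opacification ratio(s) in `[0, 1]`.
#' @param region_id matching region identifier(s); OMC regions are detected
#'   by the `"OMC"` prefix.
#' @param partial_low,complete_high cut-offs for grades 0/1 and 1/2.
#' @return Integer grades, same length as `ratio`.
#' @export
tlms_grade <- function(ratio, region_id, partial_low = 0.05,
                       complete_high = 0.95) {
  if (!(partial_low > 0 && partial_low < complete_high && complete_high < 1))
    stop("need 0 < partial_low < complete_high < 1")
  omc <- grepl("^OMC", region_id)
  g <- ifelse(ratio < partial_low, 0L, ifelse(ratio > complete_high, 2L, 1L))
  g[omc] <- ifelse(ratio[omc] > 0.5, 2L, 0L)
  as.integer(g)
}

#' Stack 2D segmented slices into a 3D label map
#'
#' Inverse of [reslice_coronal()]: slices are stacked along the
#' anteroposterior (second) array axis, so `n` slices of `a x b` give an
#' `a x n x b` grid in the LR/PA/IS axis convention.
#'
#' @param slices list of 2D integer matrices, ordered anterior to posterior,
#'   all of identical dimensions.
#' @param spacing_mm per-axis voxel size (mm) of the reconstructed grid.
#' @return A [ct_labelmap()] (or [ct_volume()] when `slices` are numeric
#'   images rather than labels).
#' @export
stack_segmentations <- function(slices, spacing_mm = c(1, 1, 1)) {
  stopifnot(length(slices) >= 1)
  d <- dim(slices[[1]])
  if (!all(vapply(slices, function(s) identical(dim(s), d), logical(1))))
    stop("inconsistent slice dimensions")
  n <- length(slices)
  arr <- array(0, dim = c(d[1], n, d[2]))
  for (k in seq_len(n)) arr[, k, ] <- slices[[k]]
  if (all(vapply(slices, function(s) is.integer(s) || all(s == round(s)),
                 logical(1))))
    ct_labelmap(arr, spacing_mm)
  else ct_volume(arr, spacing_mm)
}

#' Per-region volumes and opacification ratios
#'
#' For every region: total volume = labelled voxel count x voxel volume;
#' air volume = labelled voxels whose intensity is below `hu_threshold`;
#' disease volume = the remainder. Volumes in mL (1 mL = 1000 mm^3).
#'
#' @param labelmap a [ct_labelmap()].
#' @param volume the aligned intensity [ct_volume()].
#' @param hu_threshold intensity (HU) separating air from soft
#'   tissue/disease; default -400.
#' @param regions region identifiers expected; a region absent from the
#'   label map is reported with zero volumes and `missing = TRUE` (with a
#'   warning), never dropped.
#' @return Data frame with one row per region: voxel counts, volumes (mL),
#'   `ratio` (disease/total), `vmlms_sub`, `tlms_sub` and `missing`.
#' @export
region_volumes <- function(labelmap, volume, hu_threshold = -400,
                           regions = sinus_regions()) {
  stopifnot(inherits(labelmap, "ct_labelmap"), inherits(volume, "ct_volume"),
            identical(dim(labelmap$data), dim(volume$data)))
  vox_ml <- prod(labelmap$spacing_mm) / 1000
  lab <- as.vector(labelmap$data)
  intens <- as.vector(volume$data)
  out <- data.frame(region_id = regions, total_vox = 0L, air_vox = 0L,
                    disease_vox = 0L, stringsAsFactors = FALSE)
  cls <- region_class_id_safe(regions)
  for (i in seq_along(regions)) {
    sel <- lab == cls[i]
    out$total_vox[i] <- sum(sel)
    out$air_vox[i] <- sum(intens[sel] < hu_threshold)
  }
  out$disease_vox <- out$total_vox - out$air_vox
  out$total_ml <- out$total_vox * vox_ml
  out$air_ml <- out$air_vox * vox_ml
  out$disease_ml <- out$disease_vox * vox_ml
  out$ratio <- ifelse(out$total_vox > 0, out$disease_vox / out$total_vox, 0)
  out$vmlms_sub <- 2 * out$ratio
  out$tlms_sub <- tlms_grade(out$ratio, out$region_id)
  out$missing <- out$total_vox == 0L
  if (any(out$missing))
    warning("regions absent from label map: ",
            paste(out$region_id[out$missing], collapse = ", "))
  out
}

region_class_id_safe <- function(regions) {
  m <- match(regions, sinus_regions())
  ifelse(is.na(m), seq_along(regions), m)
}

#' Volume-based modified Lund-Mackay score
#'
#' Each region contributes twice its opacification ratio (so a fully
#' opacified region scores 2, matching the traditional grade range) and the
#' contributions are summed over the 12 regions, giving a continuous score
#' on `[0, 24]`.
#'
#' @param reports per-region report (data frame from [region_volumes()] or
#'   a phantom's `truth` table; needs `region_id` and `ratio`).
#' @return List with `per_region` (region_id, ratio, `vmlms_sub`) and
#'   `total`.
#' @export
vmlms <- function(reports) {
  stopifnot(all(c("region_id", "ratio") %in% names(reports)))
  sub <- 2 * reports$ratio
  list(per_region = data.frame(region_id = reports$region_id,
                               ratio = reports$ratio, vmlms_sub = sub,
                               stringsAsFactors = FALSE),
       total = sum(sub))
}

#' Automated traditional Lund-Mackay score
#'
#' Applies [tlms_grade()] to each region's opacification ratio and sums the
#' grades (integer score on `[0, 24]`).
#'
#' @inheritParams vmlms
#' @inheritParams tlms_grade
#' @return List with `per_region` (region_id, ratio, `tlms_sub`) and
#'   `total`.
#' @export
tlms <- function(reports, partial_low = 0.05, complete_high = 0.95) {
  stopifnot(all(c("region_id", "ratio") %in% names(reports)))
  sub <- tlms_grade(reports$ratio, reports$region_id, partial_low,
                    complete_high)
  list(per_region = data.frame(region_id = reports$region_id,
                               ratio = reports$ratio, tlms_sub = sub,
                               stringsAsFactors = FALSE),
       total = sum(sub))
}

#' Triangulated surface of one region
#'
#' Extracts the closed boundary surface of a region's binary voxel mask as
#' a triangle mesh (every exposed voxel face contributes two outward-facing
#' triangles, with vertices at voxel corners in mm). The enclosed mesh
#' volume, by the divergence theorem, equals the voxel-counted volume
#' exactly.
#'
#' @param labelmap a [ct_labelmap()].
#' @param region_id region to reconstruct.
#' @return List with `vertices` (V x 3 matrix, mm) and `faces` (F x 3
#'   integer matrix, 1-based, outward orientation).
#' @export
reconstruct_surface <- function(labelmap, region_id) {
  stopifnot(inherits(labelmap, "ct_labelmap"))
  cls <- region_class_id_safe(region_id)[1]
  mask <- labelmap$data == cls
  if (!any(mask)) stop("region ", region_id, " is empty")
  d <- dim(mask)
  sp <- labelmap$spacing_mm
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask

  quads <- list()
  # For each axis, faces where the padded mask changes between neighbours.
  for (a in 1:3) {
    dp <- dim(pad)
    idx_lo <- slice.index(array(0L, dp - c(a == 1, a == 2, a == 3)), a)
    m1 <- do.call(`[`, c(list(pad), lapply(1:3, function(j)
      if (j == a) 1:(dp[j] - 1) else 1:dp[j])))
    m2 <- do.call(`[`, c(list(pad), lapply(1:3, function(j)
      if (j == a) 2:dp[j] else 1:dp[j])))
    diff_pos <- which(m1 & !m2)  # face with outward normal +a
    diff_neg <- which(!m1 & m2)  # outward normal -a
    for (sgn in c(1, -1)) {
      ww <- if (sgn > 0) diff_pos else diff_neg
      if (!length(ww)) next
      co <- arrayInd(ww, dp - c(a == 1, a == 2, a == 3))
      # face plane position in original voxel coordinates (corner units):
      # voxel i (unpadded) spans [i-1, i]; padded index p = i + 1.
      plane <- co[, a] - 1L
      other <- setdiff(1:3, a)
      lo1 <- co[, other[1]] - 2L
      lo2 <- co[, other[2]] - 2L
      quads[[length(quads) + 1]] <-
        list(axis = a, sgn = sgn, plane = plane, lo1 = lo1, lo2 = lo2,
             other = other)
    }
  }
  verts <- new.env(hash = TRUE)
  vcount <- 0L
  vlist <- list()
  vid <- function(p) {
    key <- paste(p, collapse = ",")
    id <- verts[[key]]
    if (is.null(id)) {
      vcount <<- vcount + 1L
      verts[[key]] <- vcount
      vlist[[vcount]] <<- p
      id <- vcount
    }
    id
  }
  faces <- list()
  for (q in quads) {
    for (i in seq_along(q$plane)) {
      p <- numeric(3)
      p[q$axis] <- q$plane[i]
      c00 <- p; c00[q$other] <- c(q$lo1[i], q$lo2[i])
      c10 <- p; c10[q$other] <- c(q$lo1[i] + 1, q$lo2[i])
      c01 <- p; c01[q$other] <- c(q$lo1[i], q$lo2[i] + 1)
      c11 <- p; c11[q$other] <- c(q$lo1[i] + 1, q$lo2[i] + 1)
      v00 <- vid(c00); v10 <- vid(c10); v01 <- vid(c01); v11 <- vid(c11)
      # orientation: for +normal along axis a, order so the cross product
      # points along +a; axes (other[1], other[2], a) form a cyclic frame
      # whose handedness depends on a (axis 2 has reversed parity).
      flip <- xor(q$sgn < 0, q$axis == 2)
      if (!flip) {
        faces[[length(faces) + 1]] <- c(v00, v10, v11)
        faces[[length(faces) + 1]] <- c(v00, v11, v01)
      } else {
        faces[[length(faces) + 1]] <- c(v00, v11, v10)
        faces[[length(faces) + 1]] <- c(v00, v01, v11)
      }
    }
  }
  V <- do.call(rbind, vlist)
  V <- sweep(V, 2, sp, `*`)
  list(vertices = V, faces = do.call(rbind, faces))
}

#' Signed volume enclosed by a triangle mesh
#'
#' Divergence-theorem volume: sum of signed tetrahedron volumes
#' `det(v1, v2, v3) / 6` over faces. Positive for outward-oriented closed
#' meshes.
#'
#' @param mesh list with `vertices` and `faces` as returned by
#'   [reconstruct_surface()].
#' @return Volume in the cube of the vertex units (mm^3 here).
#' @export
mesh_volume <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  v1 <- V[F[, 1], , drop = FALSE]
  v2 <- V[F[, 2], , drop = FALSE]
  v3 <- V[F[, 3], , drop = FALSE]
  cr <- cbind(v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2],
              v2[, 3] * v3[, 1] - v2[, 1] * v3[, 3],
              v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])
  sum(rowSums(v1 * cr)) / 6
}

#' Write a mesh as ASCII STL
#'
#' @param mesh list with `vertices` and `faces`.
#' @param path output file.
#' @param name solid name.
#' @return Invisibly, `path`.
#' @export
write_stl <- function(mesh, path, name = "region") {
  V <- mesh$vertices; F <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("solid", name), con)
  for (i in seq_len(nrow(F))) {
    tri <- V[F[i, ], , drop = FALSE]
    n <- c((tri[2, 2] - tri[1, 2]) * (tri[3, 3] - tri[1, 3]) -
             (tri[2, 3] - tri[1, 3]) * (tri[3, 2] - tri[1, 2]),
           (tri[2, 3] - tri[1, 3]) * (tri[3, 1] - tri[1, 1]) -
             (tri[2, 1] - tri[1, 1]) * (tri[3, 3] - tri[1, 3]),
           (tri[2, 1] - tri[1, 1]) * (tri[3, 2] - tri[1, 2]) -
             (tri[2, 2] - tri[1, 2]) * (tri[3, 1] - tri[1, 1]))
    nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
    writeLines(c(sprintf("  facet normal %g %g %g", n[1], n[2], n[3]),
                 "    outer loop",
                 sprintf("      vertex %g %g %g", tri[, 1], tri[, 2],
                         tri[, 3]),
                 "    endloop", "  endfacet"), con)
  }
  writeLines(paste("endsolid", name), con)
  invisible(path)
}
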