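#' Sinonasal region scheme
#'
#' Twelve scored sinonasal compartments: the five paired sinuses (maxillary,
#' anterior ethmoid, posterior ethmoid, frontal, sphenoid) plus the paired
#' ostiomeatal complex (OMC), each left/right. Segmentation class ids are
#' 0 = background and 1..12 for the regions in this fixed order.
#'
#' @return Character vector of the 12 region identifiers, in scoring order.
#' @export
sinus_regions <- function() {
  as.vector(t(outer(c("Max", "AE", "PE", "Fro", "Sph", "OMC"),
                    c("L", "R"), paste, sep = "-")))
}

#' @rdname sinus_regions
#' @param region_id character vector of region identifiers.
#' @return `region_class_id()`: the integer class id (1-12) of each region.
#' @export
region_class_id <- function(region_id) {
  m <- match(region_id, sinus_regions())
  if (anyNA(m)) stop("unknown region id: ",
                     paste(region_id[is.na(m)], collapse = ", "))
  m
}

# Canonical head layout in fractional coordinates of the grid extent.
# x: left-right (left = low x), y: anteroposterior (anterior = low y),
# z: inferosuperior (inferior = low z). `dx` is the lateral offset of each
# paired cavity from the mid-sagittal plane. Fractional radii are sized so
# that at the default 96 mm head extent the cavity volumes land on the
# published adult means (maxillary ~14 mL, ethmoids ~1.4 mL, frontal
# ~1.4 mL, sphenoid ~3.4 mL); the OMC, which the scoring rubric treats as a
# compartment without an agreed volumetric definition, is modelled as a
# small 0.8 mL cavity.
sinus_canonical_layout <- function() {
  base <- data.frame(
    sinus = c("Max", "AE", "PE", "Fro", "Sph", "OMC"),
    dx = c(0.30, 0.07, 0.17, 0.13, 0.09, 0.08),
    cy = c(0.40, 0.33, 0.62, 0.20, 0.78, 0.38),
    cz = c(0.34, 0.70, 0.62, 0.86, 0.44, 0.26),
    rx = c(0.1157, 0.0531, 0.0551, 0.0653, 0.0743, 0.0448),
    ry = c(0.2104, 0.1063, 0.1002, 0.0871, 0.1238, 0.0896),
    rz = c(0.1578, 0.0712, 0.0671, 0.0653, 0.0990, 0.0538),
    stringsAsFactors = FALSE
  )
  out <- do.call(rbind, lapply(seq_len(nrow(base)), function(i) {
    b <- base[i, ]
    data.frame(
      region_id = paste0(b$sinus, c("-L", "-R")),
      cx = c(0.5 - b$dx, 0.5 + b$dx), cy = b$cy, cz = b$cz,
      rx = b$rx, ry = b$ry, rz = b$rz,
      stringsAsFactors = FALSE
    )
  }))
  out[order(region_class_id(out$region_id)), , drop = FALSE]
}

#' Reference mean cavity volumes (mL)
#'
#' Published adult mean volumes per region used to calibrate the phantom
#' geometry and the cohort generator (maxillary ~14.3 mL down to ethmoid
#' ~1.4 mL); the OMC has no published volumetric reference and is assigned
#' a nominal 0.8 mL.
#'
#' @return Named numeric vector over [sinus_regions()].
#' @export
region_reference_volumes <- function() {
  c("Max-L" = 14.26, "Max-R" = 14.39, "AE-L" = 1.49, "AE-R" = 1.49,
    "PE-L" = 1.35, "PE-R" = 1.40, "Fro-L" = 1.42, "Fro-R" = 1.34,
    "Sph-L" = 3.32, "Sph-R" = 3.43, "OMC-L" = 0.80, "OMC-R" = 0.80)
}
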