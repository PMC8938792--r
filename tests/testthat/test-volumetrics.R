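# Volumetry, Lund-Mackay scoring and surface reconstruction.

make_box_lab <- function(dims, spacing, region = "Max-L", fill = NULL) {
  a <- array(0L, dims)
  if (is.null(fill)) a[] <- 0L else do.call(`[<-`, c(list(a), fill))
  ct_labelmap(a, spacing)
}

test_that("a 1000-voxel cube at 1 mm spacing is exactly 1 mL", {
  a <- array(0L, c(12, 12, 12))
  a[2:11, 2:11, 2:11] <- 1L  # 10^3 voxels
  lm <- ct_labelmap(a, c(1, 1, 1))
  vol <- ct_volume(array(-1000, c(12, 12, 12)), c(1, 1, 1))
  rep_ <- suppressWarnings(region_volumes(lm, vol))
  expect_equal(rep_$total_ml[rep_$region_id == "Max-L"], 1.0)
  expect_equal(rep_$disease_ml[rep_$region_id == "Max-L"], 0.0)
})

test_that("anisotropic spacing scales the voxel volume", {
  a <- array(0L, c(20, 20, 20))
  a[1:10, 1:10, 1:10] <- 1L  # 1000 voxels
  lm <- ct_labelmap(a, c(0.5, 1, 0.5))  # 0.25 mm^3 per voxel
  vol <- ct_volume(array(-1000, c(20, 20, 20)), c(0.5, 1, 0.5))
  rep_ <- suppressWarnings(region_volumes(lm, vol))
  expect_equal(rep_$total_ml[1], 0.25)
})

test_that("air/disease partition follows the intensity threshold", {
  a <- array(0L, c(16, 16, 16)); a[1:10, 1:10, 1:10] <- 1L
  hu <- array(-1000, c(16, 16, 16))
  hu[1:10, 1:10, 1:4] <- 40  # 400 of 1000 labelled voxels diseased
  lm <- ct_labelmap(a, c(1, 1, 1)); vol <- ct_volume(hu, c(1, 1, 1))
  rep_ <- suppressWarnings(region_volumes(lm, vol, hu_threshold = -400))
  expect_equal(rep_$disease_vox[1], 400L)
  expect_equal(rep_$air_vox[1], 600L)
  expect_equal(rep_$ratio[1], 0.4)
  expect_equal(rep_$vmlms_sub[1], 0.8)
})

test_that("missing regions are flagged, warned about, never dropped", {
  a <- array(0L, c(16, 16, 16)); a[1:4, 1:4, 1:4] <- 1L
  lm <- ct_labelmap(a, c(1, 1, 1))
  vol <- ct_volume(array(-1000, dim(a)), c(1, 1, 1))
  expect_warning(rep_ <- region_volumes(lm, vol), "absent")
  expect_equal(nrow(rep_), 12)
  expect_true(all(rep_$missing[-1]))
  expect_false(rep_$missing[1])
  expect_true(all(rep_$total_vox[-1] == 0))
})

test_that("tlms_grade enumerates the grading rule", {
  # a paranasal sinus: clear / partial / complete
  expect_identical(tlms_grade(c(0.02, 0.5, 0.97), rep("Max-L", 3)),
                   c(0L, 1L, 2L))
  # boundary behaviour at the cut-offs (closed at the cut)
  expect_identical(tlms_grade(c(0.05, 0.95), rep("Fro-R", 2)), c(1L, 1L))
  # OMC is binary 0/2 around one half
  expect_identical(tlms_grade(c(0.49, 0.51), c("OMC-L", "OMC-R")),
                   c(0L, 2L))
  expect_error(tlms_grade(0.5, "Max-L", partial_low = 0.9,
                          complete_high = 0.1), "partial_low")
})

test_that("vmlms is bounded, additive over regions, monotone in ratios", {
  regs <- sinus_regions()
  mk <- function(r) data.frame(region_id = regs, ratio = r)
  expect_equal(vmlms(mk(rep(0, 12)))$total, 0)
  expect_equal(vmlms(mk(rep(1, 12)))$total, 24)
  set.seed(8)
  r1 <- runif(12)
  v1 <- vmlms(mk(r1))
  expect_equal(v1$total, sum(v1$per_region$vmlms_sub))
  expect_true(v1$total >= 0 && v1$total <= 24)
  # monotone: raising any single ratio raises the total
  for (i in c(1, 5, 12)) {
    r2 <- r1; r2[i] <- min(1, r1[i] + 0.1)
    expect_gt(vmlms(mk(r2))$total, v1$total)
  }
})

test_that("VMLMs equals TLMs at ratio extremes 0 and 1", {
  regs <- sinus_regions()
  r <- c(rep(0, 6), rep(1, 6))
  d <- data.frame(region_id = regs, ratio = r)
  expect_equal(vmlms(d)$total, tlms(d)$total)
  expect_equal(vmlms(d)$total, 12)
})

test_that("stack_segmentations rejects inconsistent slices and round-trips", {
  s1 <- matrix(1L, 4, 4); s2 <- matrix(2L, 4, 5)
  expect_error(stack_segmentations(list(s1, s2)), "inconsistent")
  sl <- lapply(1:6, function(k) matrix(k, 4, 3))
  st <- stack_segmentations(sl, c(1, 1, 1))
  expect_equal(dim(st$data), c(4, 6, 3))
  # per-slice histograms are preserved
  for (k in 1:6) expect_true(all(st$data[, k, ] == k))
})

test_that("cuberille mesh volume matches voxel volume exactly (cube)", {
  a <- array(0L, c(10, 10, 10)); a[3:7, 3:7, 3:7] <- 1L
  lm <- ct_labelmap(a, c(2, 2, 2))
  mesh <- reconstruct_surface(lm, "Max-L")
  expect_equal(mesh_volume(mesh), sum(a) * 8)
  # closed, consistently oriented: every edge appears exactly twice,
  # once in each direction
  F <- mesh$faces
  ed <- rbind(F[, 1:2], F[, 2:3], F[, c(3, 1)])
  key <- paste(ed[, 1], ed[, 2])
  rkey <- paste(ed[, 2], ed[, 1])
  expect_true(all(key %in% rkey))
  expect_false(any(duplicated(key)))
})

test_that("cuberille mesh volume matches voxel count for a digital sphere", {
  d <- c(24, 24, 24)
  co <- as.matrix(expand.grid(1:24, 1:24, 1:24))
  r2 <- rowSums(sweep(co - 0.5, 2, c(12, 12, 12), `-`)^2)
  a <- array(0L, d); a[r2 <= 8^2] <- 1L
  lm <- ct_labelmap(a, c(1, 1, 1))
  mesh <- reconstruct_surface(lm, "Max-L")
  expect_equal(mesh_volume(mesh), sum(a))
  # and the voxel count is within 5% of the analytic sphere volume
  expect_lt(abs(sum(a) - 4 / 3 * pi * 8^3) / (4 / 3 * pi * 8^3), 0.05)
})

test_that("STL export writes a well-formed ASCII solid", {
  a <- array(0L, c(6, 6, 6)); a[2:4, 2:4, 2:4] <- 1L
  mesh <- reconstruct_surface(ct_labelmap(a, c(1, 1, 1)), "Max-L")
  p <- tempfile(fileext = ".stl")
  write_stl(mesh, p, name = "maxL")
  txt <- readLines(p)
  expect_equal(txt[1], "solid maxL")
  expect_equal(txt[length(txt)], "endsolid maxL")
  expect_equal(sum(grepl("^  facet normal", txt)), nrow(mesh$faces))
  unlink(p)
})

test_that("phantom truth agrees with region_volumes on the clean phantom", {
  sp <- phantom_spec(noise_sd = 0, opac_fractions = stats::setNames(
    seq(0.05, 0.60, length.out = 12), sinus_regions()), seed = 21)
  ph <- generate_phantom(sp)
  rep_ <- region_volumes(ph$labels, ph$volume)
  expect_equal(rep_$total_vox, ph$truth$total_vox)
  expect_equal(rep_$disease_vox, ph$truth$disease_vox)
  expect_equal(vmlms(rep_)$total, sum(ph$truth$vmlms_sub))
  expect_equal(tlms(rep_)$total, sum(ph$truth$tlms_sub))
})
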