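# Cohort generator: covariates, volumes, opacification, symptom scores.

test_that("generate_cohort is deterministic and validates n", {
  a <- generate_cohort(6, seed = 3)
  b <- generate_cohort(6, seed = 3)
  expect_identical(a$records, b$records)
  c <- generate_cohort(6, seed = 4)
  expect_false(identical(a$records$height_cm, c$records$height_cm))
  expect_error(generate_cohort(0), "positive")
})

test_that("records carry one phantom spec per subject", {
  co <- generate_cohort(5, seed = 9)
  expect_equal(nrow(co$records), 5)
  expect_length(co$specs, 5)
  expect_true(all(vapply(co$specs, inherits, logical(1), "phantom_spec")))
  expect_true(all(c("subject_id", "sex", "height_cm", "surgery",
                    "responder", "snot22_pre", "snot22_post",
                    "vmlms_true", "total_volume") %in% names(co$records)))
})

test_that("sex ratio, surgery fraction and responders match the model", {
  md <- cohort_model()
  co <- generate_cohort(600, seed = 5)
  r <- co$records
  expect_equal(mean(r$sex == "M"), md$male_fraction, tolerance = 0.07)
  expect_equal(mean(r$surgery), md$surgery_fraction, tolerance = 0.07)
  # responders: exact count among surgical subjects, none among controls
  n_surg <- sum(r$surgery)
  expect_equal(sum(r$responder), round(md$responder_fraction * n_surg))
  expect_true(all(!r$responder[!r$surgery]))
  # every responder satisfies the 25% rule; controls do not respond
  expect_true(all(responder(r$snot22_pre, r$snot22_post)[r$responder]))
  expect_true(all(!responder(r$snot22_pre, r$snot22_post)[!r$surgery]))
})

test_that("male cavities are larger on average and sided volumes plausible", {
  co <- generate_cohort(400, seed = 6)
  r <- co$records
  vt <- cohort_volume_table()
  for (col in c("vol_Max_L", "vol_Fro_R", "vol_Sph_R")) {
    m_mean <- mean(r[[col]][r$sex == "M"])
    f_mean <- mean(r[[col]][r$sex == "F"])
    expect_gt(m_mean, f_mean)
  }
  # sample means land near the configured population means
  expect_equal(mean(r$vol_Max_L[r$sex == "M"]),
               vt$mean_m[vt$region_id == "Max-L"], tolerance = 0.15)
  expect_equal(mean(r$vol_Max_L[r$sex == "F"]),
               vt$mean_f[vt$region_id == "Max-L"], tolerance = 0.15)
})

test_that("surgical subjects are more opacified than controls", {
  co <- generate_cohort(300, seed = 7)
  r <- co$records
  expect_gt(mean(r$vmlms_true[r$surgery]), mean(r$vmlms_true[!r$surgery]))
  ot <- cohort_opac_table()
  expect_lt(abs(mean(r$opac_Max_L[r$surgery]) -
                  ot$mean_surg[ot$region_id == "Max-L"]), 0.12)
  # opacification fractions live in [0, 1], vmlms in [0, 24]
  oc <- as.matrix(r[, grep("^opac_", names(r))])
  expect_true(all(oc >= 0 & oc <= 1))
  expect_true(all(r$vmlms_true >= 0 & r$vmlms_true <= 24))
})

test_that("height drives volume with the documented coefficient", {
  md <- cohort_model()
  co <- generate_cohort(800, seed = 8)
  r <- co$records
  fit <- lm(total_volume ~ height_cm + I(sex == "M"), data = r)
  b_true <- cohort_height_coef(md)
  ci <- confint(fit)["height_cm", ]
  expect_gt(b_true, 0)
  expect_true(ci[1] <= b_true && b_true <= ci[2])
  # zero height share removes the height effect given sex
  md0 <- cohort_model(height_share = 0)
  co0 <- generate_cohort(800, model = md0, seed = 8)
  fit0 <- lm(total_volume ~ height_cm + I(sex == "M"), data = co0$records)
  ci0 <- confint(fit0)["height_cm", ]
  expect_true(ci0[1] <= 0 && 0 <= ci0[2])
  expect_equal(cohort_height_coef(md0), 0)
})

test_that("phantom specs reproduce each subject's opacification", {
  co <- generate_cohort(3, seed = 10)
  i <- 2
  ph <- generate_phantom(co$specs[[i]])
  want <- as.numeric(co$records[i, paste0("opac_",
                                          gsub("-", "_", sinus_regions()))])
  # realised ratio is the quota-rounded version of the requested fraction
  expect_lt(max(abs(ph$truth$ratio - want)), 0.5 / min(ph$truth$total_vox))
  # and cavity volumes scale with the subject's drawn volumes
  vol_cols <- paste0("vol_", gsub("-", "_", sinus_regions()))
  drawn <- as.numeric(co$records[i, vol_cols])
  big <- order(-drawn)[1:2]; small <- order(drawn)[1:2]
  expect_true(all(ph$truth$total_ml[big] > ph$truth$total_ml[small]))
})

test_that("cohort CSV round-trips the records", {
  co <- generate_cohort(4, seed = 11)
  p <- tempfile(fileext = ".csv")
  write_cohort_csv(co, p)
  r <- read.csv(p, stringsAsFactors = FALSE)
  expect_equal(nrow(r), 4)
  expect_equal(r$vmlms_true, co$records$vmlms_true, tolerance = 1e-9)
  unlink(p)
})

test_that("rbeta_mom reproduces requested moments and caps infeasible SDs", {
  set.seed(12)
  x <- rbeta_mom(20000, 0.3, 0.1)
  expect_equal(mean(x), 0.3, tolerance = 0.01)
  expect_equal(sd(x), 0.1, tolerance = 0.01)
  # an SD above the Bernoulli bound is capped, not an error
  y <- rbeta_mom(5000, 0.5, 10)
  expect_true(all(y >= 0 & y <= 1))
})
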