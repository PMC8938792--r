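#' @title Synthetic patient cohorts
#' @description Generates cohorts of synthetic subjects whose covariates and
#'   per-region sinus volumes follow the structure reported for adult CT
#'   series: male volumes exceed female volumes, volume rises with body
#'   height, subjects selected for surgery carry heavier opacification, and
#'   post-operative symptom improvement is coupled to the continuous
#'   opacification burden. Each subject comes with a [phantom_spec()] that
#'   realises their anatomy, so the whole pipeline can run on generated data.
#' @name cohort
NULL

#' Reference sinus volumes by region and sex
#'
#' Group means and standard deviations of cavity volume (mL) per region and
#' sex; the covariate model is calibrated to reproduce these group means.
#'
#' @return Data frame with columns `region_id`, `mean_m`, `mean_f`, `sd_m`,
#'   `sd_f`.
#' @export
cohort_volume_table <- function() {
  regs <- sinus_regions()
  data.frame(
    region_id = regs,
    mean_m = c(15.39, 15.50, 1.60, 1.57, 1.47, 1.50, 1.68, 1.64, 3.64, 3.81,
               0.85, 0.85),
    mean_f = c(11.88, 12.04, 1.28, 1.34, 1.13, 1.21, 0.91, 0.77, 2.70, 2.70,
               0.65, 0.65),
    sd_m = c(6.27, 6.45, 0.72, 0.57, 0.57, 0.61, 1.30, 1.33, 2.04, 2.47,
             0.30, 0.30),
    sd_f = c(5.06, 5.17, 0.52, 0.50, 0.54, 0.57, 0.92, 0.69, 1.77, 1.90,
             0.25, 0.25),
    stringsAsFactors = FALSE
  )
}

#' Reference opacification ratios by region and surgical group
#'
#' Mean/SD of the opacification ratio per region for surgical and
#' non-surgical subjects, calibrated so the expected continuous score totals
#' land at 11.65 (surgery) and 4.34 (no surgery). Values are the reference
#' per-region volume-score means divided by 2.
#'
#' @return Data frame with columns `region_id`, `mean_surg`, `sd_surg`,
#'   `mean_ctrl`, `sd_ctrl`.
#' @export
cohort_opac_table <- function() {
  regs <- sinus_regions()
  data.frame(
    region_id = regs,
    mean_surg = c(0.555, 0.660, 0.660, 0.665, 0.425, 0.385, 0.470, 0.510,
                  0.235, 0.220, 0.440, 0.600),
    sd_surg = c(0.360, 0.365, 0.220, 0.225, 0.250, 0.220, 0.345, 0.355,
                0.260, 0.245, 0.500, 0.495),
    mean_ctrl = c(0.200, 0.185, 0.340, 0.345, 0.235, 0.235, 0.135, 0.155,
                  0.085, 0.085, 0.095, 0.075),
    sd_ctrl = c(0.250, 0.230, 0.095, 0.115, 0.125, 0.105, 0.070, 0.105,
                0.050, 0.040, 0.200, 0.180),
    stringsAsFactors = FALSE
  )
}

#' Reference per-region mean sub-scores by surgical group
#'
#' The per-region mean opacification sub-scores that calibrate the cohort
#' generator, on the score scale (0-2 per region): continuous volume-based
#' sub-scores (`vmlms_*`, twice the mean opacification ratio) and
#' categorical-grade means (`tlms_*`). Totals are additive: summing a
#' column over the 12 regions gives that group's expected total score.
#'
#' @return Data frame with columns `region_id`, `tlms_surg`, `vmlms_surg`,
#'   `tlms_ctrl`, `vmlms_ctrl`.
#' @export
reference_score_table <- function() {
  ot <- cohort_opac_table()
  data.frame(
    region_id = ot$region_id,
    tlms_surg = c(1.36, 1.56, 1.70, 1.64, 1.26, 1.22, 1.30, 1.34, 0.78,
                  0.66, 0.88, 1.20),
    vmlms_surg = 2 * ot$mean_surg,
    tlms_ctrl = c(0.53, 0.56, 1.04, 1.06, 1.00, 1.02, 0.67, 0.70, 0.21,
                  0.23, 0.19, 0.15),
    vmlms_ctrl = 2 * ot$mean_ctrl,
    stringsAsFactors = FALSE
  )
}

#' Covariate model for the cohort generator
#'
#' The volume of region r is linear-Gaussian in height and sex:
#' `V_r = a_r + b_r * height + s_r * male + eps_r`, with `b_r` and `s_r`
#' chosen so the male/female group means match the calibration table and a
#' fraction `height_share` of the sex gap is carried by height (so height
#' and volume are positively correlated, and the height effect survives
#' adjustment for sex).
#'
#' @param height_share fraction of the male-female volume gap attributed to
#'   height (0 = no height effect; default 0.6).
#' @param male_fraction fraction of male subjects (default 111/175).
#' @param surgery_fraction fraction of subjects undergoing surgery
#'   (default 50/175).
#' @param responder_fraction fraction of surgical subjects meeting the 25%
#'   symptom-reduction rule (default 0.6).
#' @param symptom_coupling log-odds slope linking a subject's standardised
#'   continuous opacification score to their responder odds (default 1.2;
#'   0 decouples symptoms from opacification).
#' @param mean_height,sd_height named (`M`, `F`) height distributions (cm).
#' @param mean_weight,sd_weight named (`M`, `F`) weight distributions (kg).
#' @param mean_age,sd_age named (`M`, `F`) age distributions (years).
#' @return A `cohort_model` list of generator parameters.
#' @export
cohort_model <- function(height_share = 0.6, male_fraction = 111 / 175,
                         surgery_fraction = 50 / 175,
                         responder_fraction = 0.6, symptom_coupling = 1.2,
                         mean_height = c(M = 171.06, F = 159.33),
                         sd_height = c(M = 7.64, F = 5.54),
                         mean_weight = c(M = 71.16, F = 58.06),
                         sd_weight = c(M = 11.1, F = 10.71),
                         mean_age = c(M = 46.19, F = 51.16),
                         sd_age = c(M = 16.35, F = 14.31)) {
  structure(list(height_share = height_share, male_fraction = male_fraction,
                 surgery_fraction = surgery_fraction,
                 responder_fraction = responder_fraction,
                 symptom_coupling = symptom_coupling,
                 mean_height = mean_height, sd_height = sd_height,
                 mean_weight = mean_weight, sd_weight = sd_weight,
                 mean_age = mean_age, sd_age = sd_age,
                 volumes = cohort_volume_table(),
                 opac = cohort_opac_table()),
            class = "cohort_model")
}

#' Generator height coefficient implied by a cohort model
#'
#' @param model a [cohort_model()].
#' @param region_id regions to sum over (default: all 12, i.e. the
#'   coefficient of total sinus volume on height).
#' @return Volume slope on height, mL per cm.
#' @export
cohort_height_coef <- function(model, region_id = sinus_regions()) {
  vt <- model$volumes
  dH <- model$mean_height[["M"]] - model$mean_height[["F"]]
  sel <- vt$region_id %in% region_id
  sum(model$height_share * (vt$mean_m[sel] - vt$mean_f[sel]) / dH)
}

# moment-matched Beta draw, with SD capped below the feasible maximum
rbeta_mom <- function(n, mean, sd) {
  mean <- pmin(pmax(mean, 0.02), 0.98)
  cap <- 0.8 * sqrt(mean * (1 - mean))
  sd <- pmin(sd, cap)
  v <- sd^2
  k <- mean * (1 - mean) / v - 1
  rbeta(n, mean * k, (1 - mean) * k)
}

#' Generate a synthetic cohort
#'
#' Draws `n` subjects (covariates, per-region true volumes, opacification
#' fractions, pre/post symptom scores, surgery flag) and a matching
#' [phantom_spec()] for each. The number of responders among surgical
#' subjects is exactly `round(responder_fraction * n_surgery)`; which
#' subjects respond is sampled with odds increasing in their continuous
#' opacification score (strength `symptom_coupling`).
#'
#' @param n number of subjects (>= 1).
#' @param model a [cohort_model()].
#' @param grid_shape,spacing_mm phantom grid (default 32^3 at 3 mm: a
#'   96 mm head extent at reduced resolution, so cavity volumes stay on the
#'   adult mL scale).
#' @param seed integer seed.
#' @param specs build a [phantom_spec()] per subject (default TRUE). Set
#'   FALSE for statistics-only cohorts: the records are identical and the
#'   costly cavity-placement checks are skipped.
#' @return List with `records` (one row per subject) and `specs` (list of
#'   [phantom_spec()], one per subject; `NULL` when `specs = FALSE`).
#' @export
generate_cohort <- function(n, model = cohort_model(),
                            grid_shape = c(32, 32, 32),
                            spacing_mm = c(3, 3, 3), seed = 1L,
                            specs = TRUE) {
  if (!is.numeric(n) || length(n) != 1 || n < 1)
    stop("n must be a positive count")
  n <- as.integer(n)
  stopifnot(inherits(model, "cohort_model"))
  with_seed(seed, {
    sex <- ifelse(runif(n) < model$male_fraction, "M", "F")
    height <- rnorm(n, model$mean_height[sex], model$sd_height[sex])
    weight <- rnorm(n, model$mean_weight[sex], model$sd_weight[sex])
    age <- pmin(pmax(rnorm(n, model$mean_age[sex], model$sd_age[sex]), 18), 90)
    surgery <- runif(n) < model$surgery_fraction

    vt <- model$volumes
    regs <- vt$region_id
    dH <- model$mean_height[["M"]] - model$mean_height[["F"]]
    vols <- matrix(0, n, length(regs), dimnames = list(NULL, regs))
    for (i in seq_along(regs)) {
      gap <- vt$mean_m[i] - vt$mean_f[i]
      b <- model$height_share * gap / dH
      s_off <- (1 - model$height_share) * gap
      a <- vt$mean_f[i] - b * model$mean_height[["F"]]
      mu_sex <- ifelse(sex == "M", vt$mean_m[i], vt$mean_f[i])
      sd_sex <- ifelse(sex == "M", vt$sd_m[i], vt$sd_f[i])
      sd_h <- model$sd_height[sex]
      resid_sd <- sqrt(pmax(sd_sex^2 - (b * sd_h)^2, (0.3 * sd_sex)^2))
      v <- a + b * height + s_off * (sex == "M") + rnorm(n, 0, resid_sd)
      vols[, i] <- pmax(v, 0.1 * mu_sex)
    }

    ot <- model$opac
    opac <- matrix(0, n, length(regs), dimnames = list(NULL, regs))
    for (i in seq_along(regs)) {
      m <- ifelse(surgery, ot$mean_surg[i], ot$mean_ctrl[i])
      s <- ifelse(surgery, ot$sd_surg[i], ot$sd_ctrl[i])
      opac[, i] <- rbeta_mom(n, m, s)
    }
    vmlms_true <- 2 * rowSums(opac)

    snot_pre <- ifelse(surgery,
                       pmin(pmax(rnorm(n, 42, 10), 18), 65),
                       pmin(pmax(rnorm(n, 20, 8), 2), 110))
    snot_post <- snot_pre
    is_resp <- rep(FALSE, n)
    surg_idx <- which(surgery)
    if (length(surg_idx) > 0) {
      k <- round(model$responder_fraction * length(surg_idx))
      if (k > 0) {
        z <- scale(vmlms_true[surg_idx])[, 1]
        if (any(!is.finite(z))) z <- rep(0, length(surg_idx))
        w <- exp(model$symptom_coupling * z)
        chosen <- if (k >= length(surg_idx)) surg_idx
                  else surg_idx[sample.int(length(surg_idx), k, prob = w)]
        is_resp[chosen] <- TRUE
      }
      red <- ifelse(is_resp[surg_idx], runif(length(surg_idx), 0.30, 0.60),
                    runif(length(surg_idx), 0.00, 0.20))
      snot_post[surg_idx] <- snot_pre[surg_idx] * (1 - red)
    }
    ctrl_idx <- which(!surgery)
    if (length(ctrl_idx) > 0)
      snot_post[ctrl_idx] <- pmax(
        snot_pre[ctrl_idx] * (1 + runif(length(ctrl_idx), -0.1, 0.1)), 0)

    records <- data.frame(
      subject_id = sprintf("S%04d", seq_len(n)),
      age = age, sex = sex, height_cm = height, weight_kg = weight,
      surgery = surgery, responder = is_resp,
      snot22_pre = snot_pre, snot22_post = snot_post,
      vmlms_true = vmlms_true,
      stringsAsFactors = FALSE
    )
    colnames(vols) <- paste0("vol_", gsub("-", "_", regs))
    colnames(opac) <- paste0("opac_", gsub("-", "_", regs))
    records <- cbind(records, as.data.frame(vols), as.data.frame(opac))
    records$total_volume <- rowSums(vols)

    build_specs <- isTRUE(specs)
    refvol <- region_reference_volumes()
    spec_seeds <- sample.int(.Machine$integer.max, n)
    specs_out <- if (!build_specs) NULL else lapply(seq_len(n), function(s) {
      vscale <- setNames(as.numeric(vols[s, ]) / refvol[regs], regs)
      of <- setNames(as.numeric(opac[s, ]), regs)
      # deterministic per-subject jitter; retry with fresh jitter in the
      # rare case a scaled cavity pair collides
      for (attempt in 1:20) {
        regions <- with_seed(spec_seeds[s] + attempt - 1L,
                             sinus_region_geometries(
                               grid_shape, spacing_mm, opac_fractions = of,
                               volume_scale = vscale,
                               center_jitter_frac = 0.01))
        spec <- phantom_spec(grid_shape, spacing_mm, regions = regions,
                             seed = spec_seeds[s])
        ok <- tryCatch({ check_disjoint(spec); TRUE },
                       error = function(e) FALSE)
        if (ok) return(spec)
      }
      stop("could not place disjoint cavities for subject ", s)
    })
    list(records = records, specs = specs_out)
  })
}

# cheap disjointness screen: rasterize labels only
check_disjoint <- function(spec) {
  gs <- spec$grid_shape
  lab <- integer(prod(gs))
  for (i in seq_along(spec$regions)) {
    r <- rasterize_region(spec$regions[[i]], gs, spec$spacing_mm)
    if (any(lab[r$idx] != 0L))
      stop("overlap: ", spec$regions[[i]]$region_id)
    lab[r$idx] <- i
  }
  invisible(TRUE)
}

#' Write a cohort table as CSV
#'
#' @param cohort result of [generate_cohort()].
#' @param path output CSV file.
#' @return Invisibly, `path`.
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(cohort$records, path, row.names = FALSE)
  invisible(path)
}
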