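# Splits, pseudo-labelling, loss-mixture partition, self-training plumbing.

test_that("make_split applies floor rounding to both pools", {
  sp <- make_split(sprintf("L%02d", 1:50), sprintf("U%03d", 1:125),
                   labeled_ratio = 0.8, selftrain_fraction = 0.2, seed = 7)
  expect_length(sp$labeled_train, 40)
  expect_length(sp$labeled_val, 10)
  expect_length(sp$unlabeled_selftrain, 25)
  expect_length(sp$unlabeled_test, 100)
  # partitions: no leakage between any subsets
  all_ids <- c(sp$labeled_train, sp$labeled_val, sp$unlabeled_selftrain,
               sp$unlabeled_test)
  expect_false(anyDuplicated(all_ids) > 0)
  expect_setequal(c(sp$labeled_train, sp$labeled_val), sprintf("L%02d", 1:50))
  expect_setequal(c(sp$unlabeled_selftrain, sp$unlabeled_test),
                  sprintf("U%03d", 1:125))
})

test_that("make_split is deterministic in the seed and validates input", {
  a <- make_split(1:10, 11:30, seed = 3)
  b <- make_split(1:10, 11:30, seed = 3)
  expect_identical(a$labeled_train, b$labeled_train)
  expect_identical(a$unlabeled_selftrain, b$unlabeled_selftrain)
  expect_error(make_split(integer(0), 1:5), "empty")
  expect_error(make_split(1:5, 4:8), "disjoint")
  expect_error(make_split(1:5, 6:10, labeled_ratio = 1), "labeled_ratio")
  expect_error(make_split(1:5, 6:10, selftrain_fraction = 0),
               "selftrain_fraction")
})

test_that("split JSON round-trips", {
  sp <- make_split(1:10, 11:30, seed = 5)
  p <- tempfile(fileext = ".json")
  write_split_json(sp, p)
  j <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(j$labeled_train, sp$labeled_train)
  expect_equal(j$unlabeled_test, sp$unlabeled_test)
  unlink(p)
})

test_that("pseudo_label masks low-confidence pixels and reports coverage", {
  cfg <- seg_config(base_width = 4, depth = 2, se_reduction = 2,
                    atrous_rates = c(1, 2))
  m <- build_segnet(cfg, seed = 1)
  img <- matrix(rnorm(32 * 32, -500, 300), 32, 32)
  # the max class probability is always >= 1/K, so tau = 1/K retains all
  pl_lo <- pseudo_label(m, list(img), tau = 1 / cfg$n_classes)
  expect_equal(pl_lo$coverage, 1)
  expect_false(anyNA(pl_lo$labels[[1]]))
  pl_hi <- pseudo_label(m, list(img), tau = 0.999999)
  expect_lte(pl_hi$coverage, pl_lo$coverage)
  expect_error(pseudo_label(m, list(img), tau = 0), "tau")
  expect_error(pseudo_label(m, list(img), tau = 1.2), "tau")
})

test_that("coverage is monotone non-increasing in tau (property)", {
  cfg <- seg_config(base_width = 4, depth = 2, se_reduction = 2,
                    atrous_rates = c(1, 2))
  m <- build_segnet(cfg, seed = 2)
  imgs <- lapply(1:3, function(i) matrix(rnorm(32 * 32, -500, 400), 32, 32))
  taus <- c(0.1, 0.3, 0.5, 0.7, 0.9, 0.99)
  cov <- vapply(taus, function(t) pseudo_label(m, imgs, tau = t)$coverage,
                numeric(1))
  expect_true(all(diff(cov) <= 1e-12))
})

test_that("entropy of a uniform 13-class map is log(13); one-hot is 0", {
  K <- 13
  p_unif <- array(1 / K, c(4, 4, K))
  expect_equal(entropy_term(p_unif), log(K), tolerance = 1e-12)
  p_hot <- array(0, c(4, 4, K)); p_hot[, , 3] <- 1
  expect_equal(entropy_term(p_hot), 0)
  # list input averages over maps
  expect_equal(entropy_term(list(p_unif, p_hot)), log(K) / 2)
})

test_that("loss mixture separates two clearly distinct loss groups", {
  set.seed(4)
  losses <- c(rnorm(30, 0.1, 0.02), rnorm(10, 1.0, 0.05))
  part <- fit_loss_mixture(losses)
  expect_true(all(part$clean[1:30]))
  expect_true(all(!part$clean[31:40]))
  expect_lt(part$means[1], part$means[2])
  expect_false(part$degenerate)
  # posterior sums: clean flag consistent with posterior >= 0.5
  expect_identical(part$clean, part$posterior_clean >= 0.5)
})

test_that("EM log-likelihood trace is non-decreasing (property)", {
  set.seed(9)
  for (rep in 1:10) {
    losses <- c(rexp(25, 10), 0.8 + rexp(15, 5))
    part <- fit_loss_mixture(losses)
    if (length(part$loglik) > 1)
      expect_true(all(diff(part$loglik) >= -1e-8))
  }
})

test_that("degenerate equal-loss input marks everything clean", {
  part <- fit_loss_mixture(rep(0.5, 10))
  expect_true(part$degenerate)
  expect_true(all(part$clean))
  expect_error(fit_loss_mixture(c(1, 2, 3)), "at least 4")
})

test_that("loss mixture agrees with mclust on a well-separated sample", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))  # Mclust needs its namespace attached
  set.seed(11)
  losses <- c(rnorm(40, 0.2, 0.03), rnorm(20, 0.9, 0.04))
  part <- fit_loss_mixture(losses)
  x <- (losses - min(losses)) / diff(range(losses))
  mc <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  lo <- which.min(mc$parameters$mean)
  mc_clean <- mc$classification == lo
  expect_identical(unname(part$clean), unname(mc_clean))
})

test_that("self_train never touches labels of the unlabeled pool and logs rounds", {
  cfg <- seg_config(base_width = 4, depth = 2, se_reduction = 2,
                    atrous_rates = c(1, 2))
  m <- build_segnet(cfg, seed = 3)
  ph <- generate_phantom(phantom_spec(seed = 14))
  sl <- reslice_coronal(ph$volume, ph$labels)
  lab <- list(images = sl$images[1:6], labels = sl$labels[1:6])
  unl <- list(images = sl$images[7:12])
  val <- list(images = sl$images[13:14], labels = sl$labels[13:14])
  train_segnet(m, lab$images, lab$labels, epochs = 1, batch_size = 4,
               lr = 1e-3, seed = 1)
  st <- self_train(m, lab, unl, val = val, rounds = 2, tau = 0.5,
                   epochs_per_round = 1, batch_size = 4, lr = 5e-4, seed = 1)
  expect_s3_class(st, "train_state")
  expect_equal(nrow(st$history), 2)
  expect_true(all(c("round", "coverage", "clean_fraction", "val_loss",
                    "val_dice") %in% names(st$history)))
  expect_length(st$partitions, 2)
  # the unlabeled pool object itself was never given labels
  expect_null(unl$labels)
  expect_error(self_train(m, lab, unl, rounds = 0), "rounds")
})
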