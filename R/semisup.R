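#' @title Semi-supervised self-training
#' @description Supervised warm-up on the labelled pool, confidence-filtered
#'   pseudo-labelling of the unlabelled self-training pool, a two-component
#'   Gaussian-mixture partition of per-slice losses into clean and noisy
#'   sets, and iterated retraining on labelled + clean pseudo-labelled
#'   slices.
#' @name semisup
NULL

#' Split subjects into labelled/unlabelled pools
#'
#' The labelled pool is split into training and validation subsets by
#' `labeled_ratio` (count = `floor(ratio * n)`, remainder to validation);
#' `selftrain_fraction` of the unlabelled pool (count = `floor(fraction *
#' n)`) goes to self-training, the rest to testing. Deterministic under
#' `seed`.
#'
#' @param labeled_ids,unlabeled_ids character/integer vectors of subject
#'   ids; must be non-empty and disjoint.
#' @param labeled_ratio fraction of labelled subjects used for training
#'   (in (0, 1); e.g. 0.8 sends 40 of 50 subjects to training and 10 to
#'   validation).
#' @param selftrain_fraction fraction of unlabelled subjects used for
#'   self-training (e.g. 0.2 of 125 subjects = 25).
#' @param seed integer seed.
#' @return A `data_split` list with `labeled_train`, `labeled_val`,
#'   `unlabeled_selftrain`, `unlabeled_test`.
#' @export
make_split <- function(labeled_ids, unlabeled_ids, labeled_ratio = 0.8,
                       selftrain_fraction = 0.2, seed = 1L) {
  if (length(labeled_ids) == 0 || length(unlabeled_ids) == 0)
    stop("empty id pool")
  if (anyDuplicated(c(labeled_ids, unlabeled_ids)))
    stop("id pools must be disjoint and duplicate-free")
  if (!(labeled_ratio > 0 && labeled_ratio < 1))
    stop("labeled_ratio must be in (0, 1): validation must be non-empty")
  if (!(selftrain_fraction > 0 && selftrain_fraction < 1))
    stop("selftrain_fraction must be in (0, 1)")
  with_seed(seed, {
    n_tr <- floor(labeled_ratio * length(labeled_ids))
    if (n_tr == 0) stop("labeled_ratio leaves no training subjects")
    tr <- sort(sample(seq_along(labeled_ids), n_tr))
    n_st <- floor(selftrain_fraction * length(unlabeled_ids))
    if (n_st == 0) stop("selftrain_fraction leaves no self-training subjects")
    st <- sort(sample(seq_along(unlabeled_ids), n_st))
    structure(list(labeled_train = labeled_ids[tr],
                   labeled_val = labeled_ids[-tr],
                   unlabeled_selftrain = unlabeled_ids[st],
                   unlabeled_test = unlabeled_ids[-st],
                   labeled_ratio = labeled_ratio,
                   selftrain_fraction = selftrain_fraction,
                   seed = as.integer(seed)),
              class = "data_split")
  })
}

#' @export
print.data_split <- function(x, ...) {
  cat(sprintf("<data_split> labeled %d train / %d val; unlabeled %d self-train / %d test\n",
              length(x$labeled_train), length(x$labeled_val),
              length(x$unlabeled_selftrain), length(x$unlabeled_test)))
  invisible(x)
}

#' Write a split manifest as JSON
#'
#' @param split a `data_split`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_split_json <- function(split, path) {
  jsonlite::write_json(unclass(split), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Confidence-filtered pseudo-labels
#'
#' For each unlabelled slice, the predicted class with maximum probability
#' becomes the pseudo-label; pixels whose maximum class probability falls
#' below the confidence threshold `tau` are masked as ignore (`NA`).
#'
#' @param model a `seg_model`.
#' @param slices list of 2D intensity matrices.
#' @param tau confidence threshold in (0, 1].
#' @return A `pseudo_label_set`: `labels` (list of 2D matrices with `NA`
#'   at unretained pixels), `coverage` (overall fraction of pixels
#'   retained), `per_slice_coverage`, `tau`.
#' @export
pseudo_label <- function(model, slices, tau = 0.9) {
  if (!(tau > 0 && tau <= 1)) stop("tau must be in (0, 1]")
  labs <- vector("list", length(slices))
  cov <- numeric(length(slices))
  for (i in seq_along(slices)) {
    pr <- predict_slice(model, slices[[i]])
    pmax_ <- apply(pr$probs, c(1, 2), max)
    keep <- pmax_ >= tau
    li <- pr$labels
    li[!keep] <- NA_integer_
    labs[[i]] <- li
    cov[i] <- mean(keep)
  }
  structure(list(labels = labs, coverage = mean(cov),
                 per_slice_coverage = cov, tau = tau),
            class = "pseudo_label_set")
}

#' Mean per-pixel Shannon entropy of probability maps
#'
#' The quantity whose minimisation sharpens the class distribution on
#' unlabelled data; hard pseudo-labels minimise it implicitly, so its
#' explicit weight defaults to 0 in training.
#'
#' @param prob_maps a probability array (last-but-one or last dim = classes)
#'   or list of `H x W x K` arrays.
#' @return Mean of `-sum(p * log p)` over pixels (natural log).
#' @export
entropy_term <- function(prob_maps) {
  ent_one <- function(p) {
    K <- dim(p)[length(dim(p))]
    m <- matrix(p, ncol = K)
    -mean(rowSums(ifelse(m > 0, m * log(m), 0)))
    }
  if (is.list(prob_maps)) mean(vapply(prob_maps, ent_one, numeric(1)))
  else ent_one(prob_maps)
}

#' Two-component mixture partition of per-sample losses
#'
#' Min-max normalises the losses and fits a two-component univariate
#' Gaussian mixture by expectation-maximisation (components initialised at
#' the 25th and 75th loss percentiles, equal weights, shared initial
#' variance; tolerance 1e-6 on the log-likelihood, at most `max_iter`
#' iterations). Samples with posterior >= 0.5 under the lower-mean
#' component are "clean"; the rest are "noisy". If all losses are equal the
#' fit is degenerate and every sample is clean.
#'
#' @param losses numeric vector of per-sample losses (length >= 4).
#' @param max_iter maximum EM iterations.
#' @param tol log-likelihood convergence tolerance.
#' @return A `loss_partition`: `clean` (logical), `clean_ids`/`noisy_ids`
#'   (indices or names), mixture parameters (`means`, `sds`, `weights` --
#'   component 1 is the lower-mean, clean component), `posterior_clean`,
#'   `loglik` (per-iteration trace, non-decreasing).
#' @export
fit_loss_mixture <- function(losses, max_iter = 200, tol = 1e-6) {
  n <- length(losses)
  if (n < 4) stop("need at least 4 samples")
  ids <- names(losses) %||% seq_along(losses)
  rng <- range(losses)
  if (diff(rng) < .Machine$double.eps * 100) {
    return(structure(list(clean = rep(TRUE, n), clean_ids = ids,
                          noisy_ids = ids[0],
                          means = c(0, 0), sds = c(0, 0),
                          weights = c(1, 0),
                          posterior_clean = rep(1, n),
                          loglik = numeric(0), degenerate = TRUE),
                     class = "loss_partition"))
  }
  x <- (losses - rng[1]) / diff(rng)
  mu <- as.numeric(quantile(x, c(0.25, 0.75)))
  sg <- rep(max(sd(x) / 2, 1e-3), 2)
  w <- c(0.5, 0.5)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * dnorm(x, mu[1], sg[1])
    d2 <- w[2] * dnorm(x, mu[2], sg[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    ll_trace <- c(ll_trace, ll)
    r1 <- d1 / tot
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
    ll_old <- ll
    n1 <- sum(r1); n2 <- n - n1
    if (n1 < 1e-8 || n2 < 1e-8) break
    w <- c(n1, n2) / n
    mu <- c(sum(r1 * x) / n1, sum((1 - r1) * x) / n2)
    sg <- sqrt(pmax(c(sum(r1 * (x - mu[1])^2) / n1,
                      sum((1 - r1) * (x - mu[2])^2) / n2), 1e-6))
  }
  lo <- which.min(mu)
  post_clean <- if (lo == 1) r1 else 1 - r1
  clean <- post_clean >= 0.5
  ord <- if (lo == 1) 1:2 else 2:1
  structure(list(clean = clean, clean_ids = ids[clean],
                 noisy_ids = ids[!clean],
                 means = mu[ord], sds = sg[ord], weights = w[ord],
                 posterior_clean = post_clean, loglik = ll_trace,
                 degenerate = FALSE),
            class = "loss_partition")
}

#' @export
print.loss_partition <- function(x, ...) {
  cat(sprintf("<loss_partition> %d clean / %d noisy (component means %.3f / %.3f)\n",
              sum(x$clean), sum(!x$clean), x$means[1], x$means[2]))
  invisible(x)
}

#' Iterated pseudo-label self-training
#'
#' Starting from a supervised warm-up, each round (i) pseudo-labels the
#' self-training pool with the current model under confidence threshold
#' `tau`, (ii) fits the loss mixture over labelled + pseudo-labelled slices
#' and keeps the clean set, and (iii) retrains on labelled slices plus clean
#' pseudo-labelled slices (noisy slices are dropped from the supervised
#' term; with `lambda > 0` they contribute an entropy-minimisation term),
#' then logs validation metrics. Test-pool subjects are never trained on.
#'
#' @param model a warmed-up `seg_model` (modified in place).
#' @param labeled list with `images` and `labels` (lists of 2D matrices).
#' @param unlabeled list with `images` (the self-training pool).
#' @param val list with `images` and `labels` for per-round evaluation.
#' @param rounds number of self-training rounds K (>= 1).
#' @param tau pseudo-label confidence threshold.
#' @param lambda entropy-term weight for noisy slices.
#' @param epochs_per_round training epochs per round.
#' @param batch_size,lr passed to [train_segnet()].
#' @param seed integer seed.
#' @param verbose print progress.
#' @return A `train_state` list: `model`, `history` (one row per round:
#'   coverage, clean fraction, validation loss and Dice), `partitions`,
#'   `coverage`.
#' @export
self_train <- function(model, labeled, unlabeled, val = NULL, rounds = 3,
                       tau = 0.9, lambda = 0, epochs_per_round = 4,
                       batch_size = 8, lr = 5e-4, seed = 1L,
                       verbose = FALSE) {
  if (rounds < 1) stop("rounds must be >= 1")
  history <- list()
  partitions <- list()
  nlab <- length(labeled$images)
  for (k in seq_len(rounds)) {
    if (length(unlabeled$images) > 0) {
      pl <- pseudo_label(model, unlabeled$images, tau = tau)
      imgs <- c(labeled$images, unlabeled$images)
      labs <- c(labeled$labels, pl$labels)
      losses <- segnet_losses(model, imgs, labs, batch_size = batch_size)
      part <- fit_loss_mixture(losses)
      partitions[[k]] <- part
      wts <- rep(1, length(imgs))
      pseudo_idx <- nlab + seq_along(unlabeled$images)
      wts[pseudo_idx][!part$clean[pseudo_idx]] <- 0
      cov <- pl$coverage
      clean_frac <- mean(part$clean[pseudo_idx])
    } else {
      imgs <- labeled$images
      labs <- labeled$labels
      wts <- rep(1, length(imgs))
      cov <- NA_real_; clean_frac <- NA_real_
    }
    train_segnet(model, imgs, labs, epochs = epochs_per_round,
                 batch_size = batch_size, lr = lr, sample_weight = wts,
                 lambda_entropy = lambda, seed = seed + k,
                 verbose = FALSE)
    row <- data.frame(round = k, coverage = cov, clean_fraction = clean_frac)
    if (!is.null(val)) {
      ev <- segnet_eval(model, val$images, val$labels,
                        batch_size = batch_size)
      row$val_loss <- ev$loss
      row$val_dice <- ev$mean_dice
    }
    history[[k]] <- row
    if (verbose)
      message(sprintf("round %d: coverage %.2f clean %.2f%s", k,
                      cov, clean_frac,
                      if (!is.null(val))
                        sprintf(" val dice %.3f", row$val_dice) else ""))
  }
  structure(list(model = model, history = do.call(rbind, history),
                 partitions = partitions),
            class = "train_state")
}
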