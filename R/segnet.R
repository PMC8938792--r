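#' @title Encoder-decoder segmentation network
#' @description A compact semantic-segmentation architecture for per-slice
#'   sinus CT: an encoder of depthwise-separable convolution stages with
#'   squeeze-and-excitation channel gating (Mish inside the excitation) and
#'   residual additive skips, atrous spatial pyramid pooling at the
#'   bottleneck, and a decoder that upsamples bilinearly and concatenates
#'   encoder skips, ending in a 1x1 classification head at input
#'   resolution. Sized by configuration so a tiny instance trains on CPU.
#' @name segnet
NULL

#' Segmentation network configuration
#'
#' @param in_channels input image channels (1 for CT).
#' @param n_classes output classes; default 13 = background + 12 regions.
#' @param base_width channels of the first stage; stage s has
#'   `base_width * 2^(s-1)`.
#' @param depth number of encoder stages; stages after the first halve
#'   resolution, so the bottleneck sits at `1 / 2^(depth-1)` of the input
#'   (1/8 for the default depth 4).
#' @param se_reduction squeeze-and-excitation bottleneck ratio r (clamped so
#'   the excitation width is at least 1).
#' @param atrous_rates dilation rates of the pyramid; strictly increasing,
#'   first rate 1.
#' @param decoder_skip_stages encoder stages whose features are concatenated
#'   into the decoder (default: all).
#' @return A `seg_config` list.
#' @export
seg_config <- function(in_channels = 1, n_classes = 13, base_width = 16,
                       depth = 4, se_reduction = 16,
                       atrous_rates = c(1, 6, 12, 18),
                       decoder_skip_stages = NULL) {
  if (n_classes < 2) stop("n_classes must be >= 2")
  if (depth < 2) stop("depth must be >= 2")
  if (base_width < 2) stop("base_width must be >= 2")
  if (length(atrous_rates) < 1) stop("atrous_rates must be non-empty")
  if (atrous_rates[1] != 1) stop("first atrous rate must be 1")
  if (length(atrous_rates) > 1 && any(diff(atrous_rates) <= 0))
    stop("atrous_rates must be strictly increasing")
  if (is.null(decoder_skip_stages)) decoder_skip_stages <- seq_len(depth - 1)
  structure(list(in_channels = in_channels, n_classes = n_classes,
                 base_width = base_width, depth = depth,
                 se_reduction = se_reduction, atrous_rates = atrous_rates,
                 decoder_skip_stages = decoder_skip_stages),
            class = "seg_config")
}

stage_widths <- function(config) {
  config$base_width * 2^(seq_len(config$depth) - 1)
}

#' Build a segmentation model
#'
#' @param config a [seg_config()].
#' @param seed seed for weight initialisation.
#' @return A `seg_model` (configuration + parameter store).
#' @export
build_segnet <- function(config, seed = 1L) {
  stopifnot(inherits(config, "seg_config"))
  st <- new_store()
  w <- stage_widths(config)
  D <- config$depth
  with_seed(seed, {
    layers <- list()
    layers$stem <- list(
      ly_conv(st, "stem.conv", 3, config$in_channels, w[1]),
      ly_bn(st, "stem.bn", w[1]),
      list(type = "relu")
    )
    layers$enc <- list()
    for (s in 2:D) {
      nm <- paste0("enc", s)
      layers$enc[[s]] <- list(
        main1 = list(
          ly_dwconv(st, paste0(nm, ".dw1"), 3, w[s - 1], stride = 2),
          ly_bn(st, paste0(nm, ".dw1bn"), w[s - 1]),
          list(type = "relu"),
          ly_conv(st, paste0(nm, ".pw1"), 1, w[s - 1], w[s]),
          ly_bn(st, paste0(nm, ".pw1bn"), w[s]),
          list(type = "relu")
        ),
        main2 = list(
          ly_dwconv(st, paste0(nm, ".dw2"), 3, w[s]),
          ly_bn(st, paste0(nm, ".dw2bn"), w[s]),
          list(type = "relu"),
          ly_conv(st, paste0(nm, ".pw2"), 1, w[s], w[s]),
          ly_bn(st, paste0(nm, ".pw2bn"), w[s])
        ),
        se = ly_se(st, paste0(nm, ".se"), w[s], config$se_reduction),
        proj = list(
          ly_conv(st, paste0(nm, ".proj"), 1, w[s - 1], w[s], stride = 2),
          ly_bn(st, paste0(nm, ".projbn"), w[s])
        )
      )
    }
    ca <- w[D]
    layers$aspp <- list(
      branches = lapply(seq_along(config$atrous_rates), function(i) {
        r <- config$atrous_rates[i]
        nm <- paste0("aspp.b", i)
        list(ly_conv(st, nm, 3, w[D], ca, dilation = r),
             ly_bn(st, paste0(nm, "bn"), ca),
             list(type = "relu"))
      }),
      pool = list(ly_conv(st, "aspp.pool", 1, w[D], ca),
                  list(type = "relu")),
      fuse = list(
        ly_conv(st, "aspp.fuse", 1, ca * (length(config$atrous_rates) + 1),
                ca),
        ly_bn(st, "aspp.fusebn", ca),
        list(type = "relu")
      )
    )
    layers$dec <- list()
    cur_c <- ca
    for (s in rev(seq_len(D - 1))) {
      nm <- paste0("dec", s)
      inc <- cur_c + if (s %in% config$decoder_skip_stages) w[s] else 0
      layers$dec[[s]] <- list(
        reduce = list(ly_conv(st, paste0(nm, ".red"), 1, inc, w[s]),
                      ly_bn(st, paste0(nm, ".redbn"), w[s]),
                      list(type = "relu")),
        refine = list(ly_dwconv(st, paste0(nm, ".dw"), 3, w[s]),
                      ly_bn(st, paste0(nm, ".dwbn"), w[s]),
                      list(type = "relu"),
                      ly_conv(st, paste0(nm, ".pw"), 1, w[s], w[s]),
                      ly_bn(st, paste0(nm, ".pwbn"), w[s]),
                      list(type = "relu"))
      )
      cur_c <- w[s]
    }
    layers$head <- ly_conv(st, "head", 1, w[1], config$n_classes)
    structure(list(config = config, store = st, layers = layers),
              class = "seg_model")
  })
}

#' @export
print.seg_model <- function(x, ...) {
  np <- sum(vapply(x$store$params, length, numeric(1)))
  cat(sprintf("<seg_model> depth %d, base width %d, %d classes, %s parameters\n",
              x$config$depth, x$config$base_width, x$config$n_classes,
              format(np, big.mark = ",")))
  invisible(x)
}

#' Parameter count of a model
#' @param model a `seg_model`.
#' @return Total number of trainable parameters.
#' @export
n_params <- function(model) {
  sum(vapply(model$store$params, length, numeric(1)))
}

# --- chain helpers ---------------------------------------------------------

chain_fwd <- function(chain, store, x, train) {
  caches <- vector("list", length(chain))
  for (i in seq_along(chain)) {
    l <- chain[[i]]
    r <- switch(l$type,
                conv = fwd_conv(l, store, x),
                dwconv = fwd_dwconv(l, store, x),
                bn = fwd_bn(l, store, x, train),
                se = fwd_se(l, store, x),
                relu = fwd_relu(x),
                mish = fwd_mish(x),
                stop("unknown layer type ", l$type))
    x <- r$y
    caches[[i]] <- r$cache
  }
  list(y = x, caches = caches)
}

chain_bwd <- function(chain, store, caches, gy) {
  for (i in rev(seq_along(chain))) {
    l <- chain[[i]]
    gy <- switch(l$type,
                 conv = bwd_conv(l, store, caches[[i]], gy),
                 dwconv = bwd_dwconv(l, store, caches[[i]], gy),
                 bn = bwd_bn(l, store, caches[[i]], gy),
                 se = bwd_se(l, store, caches[[i]], gy),
                 relu = bwd_relu(caches[[i]], gy),
                 mish = bwd_mish(caches[[i]], gy))
  }
  gy
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(da[1] == db[1], da[2] == db[2], da[4] == db[4])
  y <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  y[, , seq_len(da[3]), ] <- a
  y[, , da[3] + seq_len(db[3]), ] <- b
  y
}

# --- full model forward / backward ----------------------------------------

segnet_forward <- function(model, x, train = TRUE) {
  st <- model$store
  D <- model$config$depth
  cache <- list()
  enc <- vector("list", D)
  r <- chain_fwd(model$layers$stem, st, x, train)
  enc[[1]] <- r$y
  cache$stem <- r$caches
  cache$enc <- vector("list", D)
  for (s in 2:D) {
    ly <- model$layers$enc[[s]]
    m1 <- chain_fwd(ly$main1, st, enc[[s - 1]], train)
    m2 <- chain_fwd(ly$main2, st, m1$y, train)
    se <- fwd_se(ly$se, st, m2$y)
    pj <- chain_fwd(ly$proj, st, enc[[s - 1]], train)
    pre <- se$y + pj$y
    act <- fwd_relu(pre)
    enc[[s]] <- act$y
    cache$enc[[s]] <- list(m1 = m1$caches, m2 = m2$caches, se = se$cache,
                           proj = pj$caches, act = act$cache)
  }
  # ASPP
  ab <- model$layers$aspp
  bott <- enc[[D]]
  db <- dim(bott)
  brs <- lapply(ab$branches, function(ch) chain_fwd(ch, st, bott, train))
  gap <- array(colMeans(array(bott, c(db[1] * db[2], db[3] * db[4]))),
               c(1, 1, db[3], db[4]))
  pl <- chain_fwd(ab$pool, st, gap, train)
  pl_tiled <- array(bc_ch(matrix(pl$y, dim(pl$y)[3], db[4]),
                          c(db[1], db[2], dim(pl$y)[3], db[4])),
                    c(db[1], db[2], dim(pl$y)[3], db[4]))
  cat_y <- brs[[1]]$y
  if (length(brs) > 1)
    for (i in 2:length(brs)) cat_y <- concat_ch(cat_y, brs[[i]]$y)
  cat_y <- concat_ch(cat_y, pl_tiled)
  fu <- chain_fwd(ab$fuse, st, cat_y, train)
  cache$aspp <- list(branches = lapply(brs, `[[`, "caches"),
                     pool = pl$caches, fuse = fu$caches,
                     dims = db, nb = length(brs),
                     ca = dim(brs[[1]]$y)[3], cpool = dim(pl$y)[3])
  cur <- fu$y
  # decoder
  cache$dec <- vector("list", D)
  for (s in rev(seq_len(D - 1))) {
    ly <- model$layers$dec[[s]]
    de <- dim(enc[[s]])
    up <- nn_bilinear_fwd(cur, de[1], de[2])
    updim <- dim(cur)
    skipped <- s %in% model$config$decoder_skip_stages
    z <- if (skipped) concat_ch(up, enc[[s]]) else up
    rd <- chain_fwd(ly$reduce, st, z, train)
    rf <- chain_fwd(ly$refine, st, rd$y, train)
    cache$dec[[s]] <- list(updim = updim, skipped = skipped,
                           nup = dim(up)[3], reduce = rd$caches,
                           refine = rf$caches)
    cur <- rf$y
  }
  hd <- fwd_conv(model$layers$head, st, cur)
  cache$head <- hd$cache
  cache$enc_feats <- if (train) enc else NULL
  list(logits = hd$y, cache = cache)
}

segnet_backward <- function(model, cache, glogits) {
  st <- model$store
  D <- model$config$depth
  g <- bwd_conv(model$layers$head, st, cache$head, glogits)
  genc <- vector("list", D)  # accumulated gradients w.r.t. encoder outputs
  for (s in seq_len(D - 1)) {
    ly <- model$layers$dec[[s]]
    cc <- cache$dec[[s]]
    g <- chain_bwd(ly$refine, st, cc$refine, g)
    g <- chain_bwd(ly$reduce, st, cc$reduce, g)
    if (cc$skipped) {
      gup <- g[, , seq_len(cc$nup), , drop = FALSE]
      gskip <- g[, , cc$nup + seq_len(dim(g)[3] - cc$nup), , drop = FALSE]
      genc[[s]] <- gskip
    } else gup <- g
    g <- nn_bilinear_bwd(gup, cc$updim[1], cc$updim[2])
  }
  # g is now gradient w.r.t. ASPP fuse output
  ac <- cache$aspp
  ab <- model$layers$aspp
  g <- chain_bwd(ab$fuse, st, ac$fuse, g)
  db <- ac$dims
  gbott <- array(0, db)
  off <- 0
  for (i in seq_len(ac$nb)) {
    gb <- g[, , off + seq_len(ac$ca), , drop = FALSE]
    off <- off + ac$ca
    gbott <- gbott + chain_bwd(ab$branches[[i]], st, ac$branches[[i]], gb)
  }
  gpool_tiled <- g[, , off + seq_len(ac$cpool), , drop = FALSE]
  gpool <- array(colSums(array(gpool_tiled,
                               c(db[1] * db[2], ac$cpool * db[4]))),
                 c(1, 1, ac$cpool, db[4]))
  ggap <- chain_bwd(ab$pool, st, ac$pool, gpool)
  gbott <- gbott + array(bc_ch(matrix(ggap, db[3], db[4]) / (db[1] * db[2]),
                               db), db)
  if (!is.null(genc[[D]])) gbott <- gbott + genc[[D]]
  genc[[D]] <- gbott
  for (s in D:2) {
    ly <- model$layers$enc[[s]]
    cc <- cache$enc[[s]]
    gpre <- bwd_relu(cc$act, genc[[s]])
    gproj <- chain_bwd(ly$proj, st, cc$proj, gpre)
    gse <- bwd_se(ly$se, st, cc$se, gpre)
    gm2 <- chain_bwd(ly$main2, st, cc$m2, gse)
    gm1 <- chain_bwd(ly$main1, st, cc$m1, gm2)
    gprev <- gproj + gm1
    genc[[s - 1]] <- if (is.null(genc[[s - 1]])) gprev
                     else genc[[s - 1]] + gprev
  }
  gx <- chain_bwd(model$layers$stem, st, cache$stem, genc[[1]])
  gx
}

# pad H and W up to a multiple of 2^(depth-1); returns padded array + dims
pad_to_multiple <- function(x, depth) {
  m <- 2^(depth - 1)
  d <- dim(x)
  H2 <- ceiling(d[1] / m) * m
  W2 <- ceiling(d[2] / m) * m
  if (H2 == d[1] && W2 == d[2]) return(list(x = x, H = d[1], W = d[2]))
  y <- array(0, c(H2, W2, d[3], d[4]))
  y[seq_len(d[1]), seq_len(d[2]), , ] <- x
  list(x = y, H = d[1], W = d[2])
}

#' Normalise CT intensities for the network
#'
#' Maps roughly `[-1000, 1000]` HU to `[0, 1]`.
#'
#' @param x intensity array (HU).
#' @return Scaled array.
#' @export
hu_normalize <- function(x) {
  (x + 1000) / 2000
}

#' Segment one 2D slice
#'
#' Runs the model in inference mode (batch statistics frozen, no
#' stochasticity: repeated calls are identical). Input is padded internally
#' to a multiple of the model's downsampling factor and the output cropped
#' back.
#'
#' @param model a `seg_model`.
#' @param slice 2D numeric matrix of raw intensities (HU).
#' @return List with `labels` (2D integer matrix of class ids, 0-based:
#'   argmax of the probabilities) and `probs` (H x W x K array; per-pixel
#'   probabilities, non-negative, summing to 1).
#' @export
predict_slice <- function(model, slice) {
  if (length(dim(slice)) != 2) stop("slice must be a 2D matrix")
  d <- dim(slice)
  x <- array(hu_normalize(slice), c(d[1], d[2], 1, 1))
  p <- pad_to_multiple(x, model$config$depth)
  out <- segnet_forward(model, p$x, train = FALSE)
  lg <- out$logits
  sm <- nn_softmax_xent(lg,
                        array(-1L, c(dim(lg)[1], dim(lg)[2], 1)),
                        want_probs = TRUE)
  probs <- sm$probs[seq_len(d[1]), seq_len(d[2]), , 1, drop = FALSE]
  dim(probs) <- c(d[1], d[2], dim(lg)[3])
  labels <- apply(probs, c(1, 2), which.max) - 1L
  list(labels = matrix(as.integer(labels), d[1], d[2]), probs = probs)
}

# Assemble a list of slices/labels into batch arrays. Labels are 0-based
# class ids; NA means ignore.
make_batch <- function(images, labels = NULL) {
  d <- dim(images[[1]])
  n <- length(images)
  x <- array(0, c(d[1], d[2], 1, n))
  for (i in seq_len(n)) x[, , 1, i] <- hu_normalize(images[[i]])
  y <- NULL
  if (!is.null(labels)) {
    y <- array(-1L, c(d[1], d[2], n))
    for (i in seq_len(n)) {
      li <- labels[[i]]
      li[is.na(li)] <- -1L
      y[, , i] <- as.integer(li)
    }
  }
  list(x = x, y = y)
}

#' Train a segmentation model
#'
#' Minimises per-pixel softmax cross-entropy (pixels labelled `NA` are
#' ignored) with Adam. Optionally adds an entropy-minimisation term
#' (weight `lambda_entropy`) computed on samples flagged as unsupervised
#' via zero `sample_weight`, encouraging confident predictions on them.
#'
#' @param model a `seg_model` (modified in place; also returned).
#' @param images list of 2D matrices (raw HU), all the same size.
#' @param labels list of 2D integer matrices (class ids 0-based, `NA` =
#'   ignore), aligned with `images`.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param sample_weight per-slice weight of the supervised term (default 1);
#'   0 drops a slice from the supervised loss.
#' @param class_weights `"balanced"` (default: inverse-square-root label
#'   frequency over the training labels, mean-normalised and clamped to
#'   `[0.25, 25]` -- the sinonasal regions occupy a small fraction of each
#'   slice, and unweighted cross-entropy lets the background dominate),
#'   `NULL` for unweighted, or a numeric vector of length `n_classes`.
#' @param lambda_entropy weight of the entropy term on zero-weight slices.
#' @param val optional list(images, labels) evaluated each epoch.
#' @param seed seed controlling shuffling.
#' @param verbose print per-epoch losses.
#' @return Invisibly, a data frame of training history (epoch, mean
#'   training loss, optional validation loss and Dice).
#' @export
train_segnet <- function(model, images, labels, epochs = 10, batch_size = 8,
                         lr = 1e-3, sample_weight = NULL,
                         class_weights = "balanced",
                         lambda_entropy = 0, val = NULL, seed = 1L,
                         verbose = FALSE) {
  stopifnot(length(images) == length(labels))
  n <- length(images)
  if (is.null(sample_weight)) sample_weight <- rep(1, n)
  K <- model$config$n_classes
  if (identical(class_weights, "balanced")) {
    cnt <- numeric(K)
    for (l in labels) {
      t <- tabulate(l[!is.na(l)] + 1L, nbins = K)
      cnt <- cnt + t
    }
    w <- 1 / sqrt(pmax(cnt, 1))
    w <- w / mean(w)
    class_weights <- pmin(pmax(w, 0.25), 25)
  }
  if (!is.null(class_weights)) {
    stopifnot(length(class_weights) == K)
    cw <- as.numeric(class_weights)
  } else cw <- numeric(0)
  opt <- model$store$opt
  if (is.null(opt)) {
    opt <- new_adam(model$store, lr = lr)
    model$store$opt <- opt
  }
  opt$lr <- lr
  hist <- list()
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      tot <- 0; nb <- 0
      for (start in seq(1, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, n)]
        b <- make_batch(images[idx], labels[idx])
        p <- pad_to_multiple(b$x, model$config$depth)
        ypad <- array(-1L, c(dim(p$x)[1], dim(p$x)[2], length(idx)))
        ypad[seq_len(p$H), seq_len(p$W), ] <- b$y
        w <- sample_weight[idx]
        ypad[, , w == 0] <- -1L     # unsupervised slices: no CE pixels
        zero_grads(model$store)
        fw <- segnet_forward(model, p$x, train = TRUE)
        sm <- nn_softmax_xent(fw$logits, ypad,
                              want_probs = lambda_entropy > 0,
                              class_weights = cw)
        gl <- sm$glogits
        nsup <- sum(w > 0)
        if (nsup > 0) {
          for (i in seq_along(idx))
            gl[, , , i] <- gl[, , , i] * (w[i] / nsup)
        }
        loss <- if (nsup > 0) sum(sm$loss * w) / nsup else 0
        if (lambda_entropy > 0 && any(w == 0)) {
          pr <- sm$probs
          K <- dim(pr)[3]
          uns <- which(w == 0)
          npx <- dim(pr)[1] * dim(pr)[2]
          for (i in uns) {
            pi <- pr[, , , i, drop = FALSE]
            lp <- log(pmax(pi, 1e-12))
            Hent <- -apply(pi * lp, c(1, 2, 4), sum)
            loss <- loss + lambda_entropy * mean(Hent) / length(uns)
            gH <- -pi * (lp + rep(Hent, times = K))
            gl[, , , i] <- gl[, , , i] +
              lambda_entropy * gH[, , , 1] / (npx * length(uns))
          }
        }
        segnet_backward(model, fw$cache, gl)
        adam_step(opt, model$store)
        tot <- tot + loss; nb <- nb + 1
      }
      row <- data.frame(epoch = ep, train_loss = tot / nb)
      if (!is.null(val)) {
        vl <- segnet_eval(model, val$images, val$labels,
                          batch_size = batch_size)
        row$val_loss <- vl$loss
        row$val_dice <- vl$mean_dice
      }
      hist[[ep]] <- row
      if (verbose)
        message(sprintf("epoch %d: loss %.4f%s", ep, row$train_loss,
                        if (!is.null(val))
                          sprintf(" val %.4f dice %.3f", row$val_loss,
                                  row$val_dice) else ""))
    }
  })
  invisible(do.call(rbind, hist))
}

#' Evaluate loss and Dice on a slice set
#'
#' @param model a `seg_model`.
#' @param images,labels slice set as in [train_segnet()].
#' @param batch_size forward-pass batch size.
#' @return List: `loss` (mean per-slice cross-entropy), `per_slice_loss`,
#'   `mean_dice` (over non-background classes present).
#' @export
segnet_eval <- function(model, images, labels, batch_size = 8) {
  n <- length(images)
  losses <- numeric(n)
  pred_all <- integer(0); ref_all <- integer(0)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    b <- make_batch(images[idx], labels[idx])
    p <- pad_to_multiple(b$x, model$config$depth)
    ypad <- array(-1L, c(dim(p$x)[1], dim(p$x)[2], length(idx)))
    ypad[seq_len(p$H), seq_len(p$W), ] <- b$y
    fw <- segnet_forward(model, p$x, train = FALSE)
    sm <- nn_softmax_xent(fw$logits, ypad, want_probs = TRUE)
    losses[idx] <- sm$loss
    lab <- apply(sm$probs, c(1, 2, 4), which.max) - 1L
    for (j in seq_along(idx)) {
      ref <- ypad[, , j]
      keep <- ref >= 0
      pred_all <- c(pred_all, lab[, , j][keep])
      ref_all <- c(ref_all, ref[keep])
    }
  }
  md <- if (length(ref_all))
    seg_metrics(pred_all, ref_all)$mean_dice else NA_real_
  list(loss = mean(losses), per_slice_loss = losses, mean_dice = md)
}

#' Per-slice losses under the current model
#'
#' Inference-mode cross-entropy of each slice against its (possibly pseudo)
#' labels; the inputs to the loss-mixture partition.
#'
#' @inheritParams segnet_eval
#' @return Numeric vector of per-slice mean losses.
#' @export
segnet_losses <- function(model, images, labels, batch_size = 8) {
  segnet_eval(model, images, labels, batch_size = batch_size)$per_slice_loss
}

#' Save / load a model checkpoint
#'
#' Parameters and batch-norm state are serialised with a JSON sidecar of
#' the configuration for reproducibility.
#'
#' @param model a `seg_model`.
#' @param path checkpoint path (`.rds`); the sidecar is `path` +
#'   `".json"`.
#' @return `save_segnet()`: invisibly, `path`; `load_segnet()`: the model.
#' @export
save_segnet <- function(model, path) {
  saveRDS(list(config = unclass(model$config), params = model$store$params,
               state = model$store$state), path)
  jsonlite::write_json(unclass(model$config), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_segnet
#' @export
load_segnet <- function(path) {
  obj <- readRDS(path)
  cfg <- do.call(seg_config, obj$config[names(obj$config) %in%
                                          names(formals(seg_config))])
  model <- build_segnet(cfg)
  stopifnot(setequal(names(model$store$params), names(obj$params)))
  model$store$params <- obj$params
  model$store$state <- obj$state
  model
}
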