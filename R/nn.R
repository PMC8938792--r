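#' @title Network building blocks
#' @description Minimal explicit-gradient layers used by the segmentation
#'   network: dense and depthwise-separable convolutions (im2col + GEMM in
#'   compiled code), batch normalisation, ReLU and Mish activations,
#'   squeeze-and-excitation channel gating, and bilinear resampling.
#'   Tensors are column-major arrays with dims `(H, W, C, N)`.
#' @name nn
NULL

#' Mish activation
#'
#' `mish(x) = x * tanh(softplus(x))` with `softplus(x) = log(1 + exp(x))`,
#' evaluated stably for large `|x|`. A smooth, non-monotone activation that
#' keeps activations bounded below and avoids saturation above.
#'
#' @param x numeric vector/array.
#' @return `mish()`: the elementwise activation; `mish_grad()`: its
#'   derivative.
#' @export
mish <- function(x) {
  x * tanh(softplus(x))
}

#' @rdname mish
#' @export
mish_grad <- function(x) {
  t <- tanh(softplus(x))
  t + x * (1 - t^2) * plogis(x)
}

softplus <- function(x) {
  ifelse(x > 20, x, log1p(exp(pmin(x, 20))))
}

# --- parameter store -------------------------------------------------------

new_store <- function() {
  e <- new.env(parent = emptyenv())
  e$params <- list()
  e$grads <- list()
  e$state <- list()   # batch-norm running statistics
  e
}

add_param <- function(store, name, value) {
  store$params[[name]] <- value
  store$grads[[name]] <- value * 0   # same shape and class as the parameter
  invisible(name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

zero_grads <- function(store) {
  for (nm in names(store$grads))
    store$grads[[nm]][] <- 0
  invisible(store)
}

# Kaiming-style fan-in initialisation
init_conv_w <- function(k, cin, cout) {
  array(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
        c(k, k, cin, cout))
}

# --- layer constructors (descriptors; parameters live in the store) --------

ly_conv <- function(store, name, k, cin, cout, stride = 1, dilation = 1) {
  add_param(store, paste0(name, ".w"), init_conv_w(k, cin, cout))
  add_param(store, paste0(name, ".b"), numeric(cout))
  list(type = "conv", name = name, k = k, cin = cin, cout = cout,
       stride = stride, dilation = dilation)
}

ly_dwconv <- function(store, name, k, c, stride = 1, dilation = 1) {
  add_param(store, paste0(name, ".w"),
            array(rnorm(k * k * c, 0, sqrt(2 / (k * k))), c(k, k, c)))
  add_param(store, paste0(name, ".b"), numeric(c))
  list(type = "dwconv", name = name, k = k, c = c, stride = stride,
       dilation = dilation)
}

ly_bn <- function(store, name, c, momentum = 0.1, eps = 1e-5) {
  add_param(store, paste0(name, ".gamma"), rep(1, c))
  add_param(store, paste0(name, ".beta"), numeric(c))
  store$state[[paste0(name, ".mean")]] <- numeric(c)
  store$state[[paste0(name, ".var")]] <- rep(1, c)
  list(type = "bn", name = name, c = c, momentum = momentum, eps = eps)
}

ly_se <- function(store, name, c, reduction) {
  cr <- max(1L, as.integer(floor(c / reduction)))
  add_param(store, paste0(name, ".w1"),
            matrix(rnorm(c * cr, 0, sqrt(2 / c)), c, cr))
  add_param(store, paste0(name, ".b1"), numeric(cr))
  add_param(store, paste0(name, ".w2"),
            matrix(rnorm(cr * c, 0, sqrt(2 / cr)), cr, c))
  add_param(store, paste0(name, ".b2"), numeric(c))
  list(type = "se", name = name, c = c, cr = cr)
}

# broadcast a per-channel (or per-channel-per-sample) quantity over (H, W)
bc_ch <- function(v, d) {
  # v: length C (recycled over N) or C x N matrix
  if (is.matrix(v)) rep(as.vector(v), each = d[1] * d[2])
  else rep(rep(v, each = d[1] * d[2]), times = d[4])
}

# --- forward / backward ----------------------------------------------------

fwd_conv <- function(layer, store, x) {
  w <- store$params[[paste0(layer$name, ".w")]]
  b <- store$params[[paste0(layer$name, ".b")]]
  y <- nn_conv2d_fwd(x, w, b, layer$stride, layer$dilation)
  list(y = y, cache = list(x = x))
}

bwd_conv <- function(layer, store, cache, gy) {
  w <- store$params[[paste0(layer$name, ".w")]]
  g <- nn_conv2d_bwd(cache$x, w, gy, layer$stride, layer$dilation)
  nw <- paste0(layer$name, ".w"); nb <- paste0(layer$name, ".b")
  store$grads[[nw] ] <- store$grads[[nw]] + g$gw
  store$grads[[nb] ] <- store$grads[[nb]] + g$gb
  g$gx
}

fwd_dwconv <- function(layer, store, x) {
  w <- store$params[[paste0(layer$name, ".w")]]
  b <- store$params[[paste0(layer$name, ".b")]]
  y <- nn_dwconv2d_fwd(x, w, b, layer$stride, layer$dilation)
  list(y = y, cache = list(x = x))
}

bwd_dwconv <- function(layer, store, cache, gy) {
  w <- store$params[[paste0(layer$name, ".w")]]
  g <- nn_dwconv2d_bwd(cache$x, w, gy, layer$stride, layer$dilation)
  nw <- paste0(layer$name, ".w"); nb <- paste0(layer$name, ".b")
  store$grads[[nw]] <- store$grads[[nw]] + g$gw
  store$grads[[nb]] <- store$grads[[nb]] + g$gb
  g$gx
}

fwd_bn <- function(layer, store, x, train) {
  d <- dim(x)
  gamma <- store$params[[paste0(layer$name, ".gamma")]]
  beta <- store$params[[paste0(layer$name, ".beta")]]
  xm <- array(x, c(d[1] * d[2], d[3], d[4]))
  if (train) {
    mu <- rowMeans(colMeans(xm))            # per-channel mean over H,W,N
    m2 <- rowMeans(colMeans(xm * xm))
    v <- pmax(m2 - mu^2, 0)
    nm <- paste0(layer$name, ".mean"); nv <- paste0(layer$name, ".var")
    store$state[[nm]] <- (1 - layer$momentum) * store$state[[nm]] +
      layer$momentum * mu
    store$state[[nv]] <- (1 - layer$momentum) * store$state[[nv]] +
      layer$momentum * v
  } else {
    mu <- store$state[[paste0(layer$name, ".mean")]]
    v <- store$state[[paste0(layer$name, ".var")]]
  }
  invstd <- 1 / sqrt(v + layer$eps)
  xhat <- (x - bc_ch(mu, d)) * bc_ch(invstd, d)
  y <- bc_ch(gamma, d) * xhat + bc_ch(beta, d)
  dim(y) <- d
  list(y = y, cache = list(xhat = xhat, invstd = invstd, d = d,
                           train = train))
}

bwd_bn <- function(layer, store, cache, gy) {
  d <- cache$d
  gamma <- store$params[[paste0(layer$name, ".gamma")]]
  M <- d[1] * d[2] * d[4]
  gym <- array(gy, c(d[1] * d[2], d[3], d[4]))
  xh <- array(cache$xhat, c(d[1] * d[2], d[3], d[4]))
  ggamma <- rowSums(colSums(gym * xh))
  gbeta <- rowSums(colSums(gym))
  ng <- paste0(layer$name, ".gamma"); nb <- paste0(layer$name, ".beta")
  store$grads[[ng]] <- store$grads[[ng]] + ggamma
  store$grads[[nb]] <- store$grads[[nb]] + gbeta
  if (cache$train) {
    gx <- bc_ch(gamma * cache$invstd / M, d) *
      (M * gy - bc_ch(gbeta, d) - cache$xhat * bc_ch(ggamma, d))
  } else {
    gx <- bc_ch(gamma * cache$invstd, d) * gy
  }
  dim(gx) <- d
  gx
}

fwd_relu <- function(x) {
  y <- pmax(x, 0)
  dim(y) <- dim(x)
  list(y = y, cache = x > 0)
}

bwd_relu <- function(cache, gy) {
  gy * cache
}

fwd_mish <- function(x) {
  list(y = array(mish(x), dim(x)), cache = x)
}

bwd_mish <- function(cache, gy) {
  gy * mish_grad(cache)
}

#' Squeeze-and-excitation forward pass (standalone)
#'
#' Squeeze: per-channel global average pooling. Excitation: a C -> C/r
#' linear map, Mish, a C/r -> C map, and a logistic gate in (0, 1) that
#' rescales the input channels multiplicatively.
#'
#' Exposed standalone (in addition to its use inside the network) so the
#' gating properties can be exercised directly.
#'
#' @param x array `(H, W, C, N)`.
#' @param w1,b1,w2,b2 excitation parameters (`C x Cr`, `Cr`, `Cr x C`, `C`).
#' @return List `y` (gated features), `gate` (`C x N`), `squeeze` (`C x N`).
#' @export
se_apply <- function(x, w1, b1, w2, b2) {
  d <- dim(x)
  xm <- array(x, c(d[1] * d[2], d[3] * d[4]))
  s <- matrix(colMeans(xm), d[3], d[4])
  z1 <- crossprod(w1, s) + b1
  a1 <- mish(z1)
  z2 <- crossprod(w2, a1) + b2
  g <- plogis(z2)
  y <- x * bc_ch(g, d)
  dim(y) <- d
  list(y = y, gate = g, squeeze = s, z1 = z1, a1 = a1, z2 = z2)
}

fwd_se <- function(layer, store, x) {
  p <- store$params
  n <- layer$name
  out <- se_apply(x, p[[paste0(n, ".w1")]], p[[paste0(n, ".b1")]],
                  p[[paste0(n, ".w2")]], p[[paste0(n, ".b2")]])
  list(y = out$y, cache = c(out, list(x = x)))
}

bwd_se <- function(layer, store, cache, gy) {
  d <- dim(cache$x)
  n <- layer$name
  p <- store$params
  # gate gradient: sum over spatial of gy * x
  gyx <- array(gy * cache$x, c(d[1] * d[2], d[3] * d[4]))
  gg <- matrix(colSums(gyx), d[3], d[4])
  gx <- gy * bc_ch(cache$gate, d)
  dz2 <- gg * cache$gate * (1 - cache$gate)
  da1 <- p[[paste0(n, ".w2")]] %*% dz2
  dz1 <- da1 * mish_grad(cache$z1)
  ds <- p[[paste0(n, ".w1")]] %*% dz1
  add_g <- function(nm, g) store$grads[[nm]] <- store$grads[[nm]] + g
  add_g(paste0(n, ".w2"), cache$a1 %*% t(dz2))
  add_g(paste0(n, ".b2"), rowSums(dz2))
  add_g(paste0(n, ".w1"), cache$squeeze %*% t(dz1))
  add_g(paste0(n, ".b1"), rowSums(dz1))
  gx <- gx + bc_ch(ds / (d[1] * d[2]), d)
  dim(gx) <- d
  gx
}

# --- Adam ------------------------------------------------------------------

new_adam <- function(store, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8, weight_decay = 0) {
  opt <- new.env(parent = emptyenv())
  opt$lr <- lr; opt$beta1 <- beta1; opt$beta2 <- beta2; opt$eps <- eps
  opt$wd <- weight_decay
  opt$t <- 0L
  opt$m <- lapply(store$grads, function(g) { g[] <- 0; g })
  opt$v <- opt$m
  opt
}

adam_step <- function(opt, store) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (nm in names(store$params)) {
    g <- store$grads[[nm]]
    if (opt$wd > 0) g <- g + opt$wd * store$params[[nm]]
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g^2
    store$params[[nm]] <- store$params[[nm]] -
      opt$lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + opt$eps)
  }
  invisible(opt)
}
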