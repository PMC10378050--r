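# Compact reference implementation of the encoder/heads network: stride-2
# 3x3 convolution blocks with rectifier activations (im2col + BLAS matrix
# products), global average pooling, a 2-layer projection perceptron and a
# linear classifier, with hand-derived backpropagation and Adam. Images are
# (h, w, 3, views) arrays; all embeddings live on the unit hypersphere.

#' Network architecture specification
#'
#' The encoder is a stack of 3x3 stride-2 convolution blocks (one per entry
#' of \code{channels}) followed by global average pooling, so the
#' representation dimension D_E equals the last channel count. The
#' projection head is a 2-layer perceptron (D_E -> hidden -> D_P) whose
#' unit-norm output feeds the contrastive loss only; the linear classifier
#' consumes the unit-norm representation and is the inference path. The
#' default is a small test CNN (D_E = 64) suitable for CPU-scale runs; a
#' full-scale backbone corresponds to wider channels with
#' \code{proj_hidden = 2048}.
#'
#' @param image_size Input side length; must be divisible by
#'   \code{2^length(channels)}.
#' @param channels Integer vector of block output channels.
#' @param proj_hidden Projection head hidden width.
#' @param d_p Projection output dimension (default 128).
#' @param n_classes Number of classes for the classifier head.
#' @param encoder Encoder family name; \code{"small_cnn"} is built in.
#' @return List of class \code{"am_model_spec"} (includes \code{d_e}).
#' @export
model_spec <- function(image_size = 64L, channels = c(8L, 16L, 32L, 64L),
                       proj_hidden = 128L, d_p = 128L, n_classes = 5L,
                       encoder = "small_cnn") {
  if (encoder != "small_cnn") stop("unknown encoder '", encoder, "'")
  if (image_size %% (2^length(channels)) != 0) {
    stop("image_size must be divisible by 2^", length(channels))
  }
  structure(list(image_size = as.integer(image_size),
                 channels = as.integer(channels),
                 d_e = as.integer(channels[length(channels)]),
                 proj_hidden = as.integer(proj_hidden), d_p = as.integer(d_p),
                 n_classes = as.integer(n_classes), encoder = encoder),
            class = "am_model_spec")
}

# im2col geometry for a 3x3/stride-2/pad-1 block on square h x h input
.conv_geom <- function(h, c_in) {
  hp <- h + 2L
  oh <- h %/% 2L
  ohi <- rep(seq_len(oh), times = oh)
  owi <- rep(seq_len(oh), each = oh)
  kh <- rep(1:3, times = 3L * c_in)
  kw <- rep(rep(1:3, each = 3L), times = c_in)
  cc <- rep(seq_len(c_in), each = 9L)
  idx <- outer(2L * (ohi - 1L), kh, "+") +
    (outer(2L * (owi - 1L), kw, "+") - 1L) * hp +
    matrix((cc - 1L) * hp * hp, length(ohi), 9L * c_in, byrow = TRUE)
  list(h = h, hp = hp, oh = oh, c_in = c_in, idx = idx)
}

# pad + gather the im2col matrix: rows ordered (position, view), pos fastest
.im2col <- function(x, geom) {
  v <- dim(x)[4]
  xp <- array(0, c(geom$hp, geom$hp, geom$c_in, v))
  xp[2:(geom$h + 1L), 2:(geom$h + 1L), , ] <- x
  xm <- matrix(xp, geom$hp * geom$hp * geom$c_in, v)
  g <- xm[as.vector(geom$idx), , drop = FALSE]
  dim(g) <- c(nrow(geom$idx), ncol(geom$idx), v)
  g <- aperm(g, c(1L, 3L, 2L))
  dim(g) <- c(nrow(geom$idx) * v, ncol(geom$idx))
  g
}

# conv -> batch norm -> rectifier block. Batch statistics are used during
# training; exponential running statistics give deterministic inference.
.bn_eps <- 1e-5
.bn_momentum <- 0.1

.conv_forward <- function(x, par, geom, bn, training) {
  v <- dim(x)[4]
  xc <- .im2col(x, geom)
  y <- xc %*% par$w
  n <- nrow(y)
  if (training) {
    mu <- colMeans(y)
    yc <- y - matrix(mu, n, length(mu), byrow = TRUE)
    var <- colMeans(yc^2)
    bn$mean <- (1 - .bn_momentum) * bn$mean + .bn_momentum * mu
    bn$var <- (1 - .bn_momentum) * bn$var + .bn_momentum * var * n / max(n - 1, 1)
  } else {
    mu <- bn$mean
    var <- bn$var
    yc <- y - matrix(mu, n, length(mu), byrow = TRUE)
  }
  isd <- 1 / sqrt(var + .bn_eps)
  yhat <- yc * matrix(isd, n, length(isd), byrow = TRUE)
  act <- yhat * matrix(par$gamma, n, length(isd), byrow = TRUE) +
    matrix(par$beta, n, length(isd), byrow = TRUE)
  pos <- act > 0
  act[!pos] <- 0
  out <- act
  dim(out) <- c(geom$oh, geom$oh, v, ncol(par$w))
  list(out = aperm(out, c(1L, 2L, 4L, 3L)), bn = bn,
       cache = list(xc = xc, pos = pos, v = v, yhat = yhat, isd = isd))
}

.conv_backward <- function(dout, par, geom, cache) {
  v <- cache$v
  dy <- aperm(dout, c(1L, 2L, 4L, 3L))
  dim(dy) <- c(geom$oh * geom$oh * v, ncol(par$w))
  dy[!cache$pos] <- 0
  n <- nrow(dy)
  dgamma <- colSums(dy * cache$yhat)
  dbeta <- colSums(dy)
  # through batch normalization (batch statistics path)
  dyhat <- dy * matrix(par$gamma, n, length(par$gamma), byrow = TRUE)
  dpre <- (dyhat -
             matrix(colMeans(dyhat), n, ncol(dy), byrow = TRUE) -
             cache$yhat * matrix(colMeans(dyhat * cache$yhat), n, ncol(dy), byrow = TRUE)) *
    matrix(cache$isd, n, ncol(dy), byrow = TRUE)
  dw <- crossprod(cache$xc, dpre)
  dxc <- tcrossprod(dpre, par$w)
  p <- nrow(geom$idx)
  dxm <- matrix(0, geom$hp * geom$hp * geom$c_in, v)
  for (q in seq_len(ncol(geom$idx))) {
    rows <- geom$idx[, q]
    dxm[rows, ] <- dxm[rows, ] + matrix(dxc[, q], p, v)
  }
  dim(dxm) <- c(geom$hp, geom$hp, geom$c_in, v)
  list(dx = dxm[2:(geom$h + 1L), 2:(geom$h + 1L), , , drop = FALSE],
       dw = dw, dgamma = dgamma, dbeta = dbeta)
}

# unit-norm rows plus the pieces needed for the backward pass
.norm_forward <- function(x) {
  nrm <- sqrt(rowSums(x^2))
  nrm[nrm == 0] <- 1e-12
  list(y = x / nrm, nrm = nrm)
}

.norm_backward <- function(dy, fw) {
  (dy - fw$y * rowSums(dy * fw$y)) / fw$nrm
}

#' Build an untrained network
#'
#' Seeded deterministic initialization: He-style normal weights for the
#' rectified layers, smaller normal weights for the linear outputs, zero
#' biases.
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed.
#' @return An object of class \code{"am_model"} with untrained parameters.
#' @export
build_model <- function(spec = model_spec(), seed = 1L) {
  stopifnot(inherits(spec, "am_model_spec"))
  params <- with_seed(seed, {
    c_in <- 3L
    conv <- list()
    for (cout in spec$channels) {
      fan <- 9L * c_in
      conv[[length(conv) + 1L]] <- list(
        w = matrix(stats::rnorm(fan * cout, 0, sqrt(2 / fan)), fan, cout),
        gamma = rep(1, cout), beta = numeric(cout))
      c_in <- cout
    }
    list(
      conv = conv,
      proj = list(
        w1 = matrix(stats::rnorm(spec$d_e * spec$proj_hidden, 0,
                                 sqrt(2 / spec$d_e)), spec$d_e),
        b1 = numeric(spec$proj_hidden),
        w2 = matrix(stats::rnorm(spec$proj_hidden * spec$d_p, 0,
                                 sqrt(1 / spec$proj_hidden)), spec$proj_hidden),
        b2 = numeric(spec$d_p)),
      cls = list(
        w = matrix(stats::rnorm(spec$d_e * spec$n_classes, 0,
                                sqrt(1 / spec$d_e)), spec$d_e),
        b = numeric(spec$n_classes))
    )
  })
  geoms <- list()
  bn <- list()
  h <- spec$image_size
  c_in <- 3L
  for (cout in spec$channels) {
    geoms[[length(geoms) + 1L]] <- .conv_geom(h, c_in)
    bn[[length(bn) + 1L]] <- list(mean = numeric(cout), var = rep(1, cout))
    h <- h %/% 2L
    c_in <- cout
  }
  structure(list(params = params, spec = spec, geoms = geoms, bn = bn,
                 seed = as.integer(seed),
                 control = NULL, history = NULL, best_params = NULL),
            class = "am_model")
}

#' Forward pass of the network
#'
#' Maps a batch of image rasters to unit-norm representations \code{r},
#' unit-norm projections \code{z} and class probabilities. The inference
#' path (classifier) depends only on \code{r}, never on the projection
#' head.
#'
#' @param model An \code{"am_model"}.
#' @param images Array (h, w, 3, n_views).
#' @param params Parameter set to use (defaults to the model's current
#'   parameters).
#' @param keep_cache Retain intermediate activations for backpropagation.
#' @param training Use batch statistics in the normalization layers (and
#'   update the running statistics); inference mode (the default) uses the
#'   stored running statistics and is fully deterministic.
#' @return List with \code{r}, \code{z}, \code{probs} (and \code{cache},
#'   \code{bn} when \code{keep_cache}/\code{training}).
#' @export
model_forward <- function(model, images, params = model$params,
                          keep_cache = FALSE, training = keep_cache) {
  if (length(dim(images)) == 3L) dim(images) <- c(dim(images), 1L)
  if (dim(images)[1] != model$spec$image_size) {
    stop("images must be ", model$spec$image_size, "x", model$spec$image_size)
  }
  x <- images - 0.5            # centre [0,1] pixel values
  conv_caches <- list()
  bn <- model$bn
  for (k in seq_along(params$conv)) {
    cf <- .conv_forward(x, params$conv[[k]], model$geoms[[k]], bn[[k]], training)
    bn[[k]] <- cf$bn
    if (keep_cache) conv_caches[[k]] <- cf$cache
    x <- cf$out
  }
  oh <- dim(x)[1]; ce <- dim(x)[3]; v <- dim(x)[4]
  xm <- x
  dim(xm) <- c(oh * oh, ce * v)
  r_raw <- t(matrix(colMeans(xm), ce, v))           # views x d_e
  rn <- .norm_forward(r_raw)
  h1_pre <- rn$y %*% params$proj$w1 +
    matrix(params$proj$b1, v, length(params$proj$b1), byrow = TRUE)
  h1 <- pmax(h1_pre, 0)
  z_raw <- h1 %*% params$proj$w2 +
    matrix(params$proj$b2, v, length(params$proj$b2), byrow = TRUE)
  zn <- .norm_forward(z_raw)
  logits <- rn$y %*% params$cls$w +
    matrix(params$cls$b, v, length(params$cls$b), byrow = TRUE)
  lmax <- apply(logits, 1L, max)
  el <- exp(logits - lmax)
  probs <- el / rowSums(el)
  out <- list(r = rn$y, z = zn$y, probs = probs, bn = bn)
  if (keep_cache) {
    out$cache <- list(conv = conv_caches, rn = rn, h1 = h1, h1_pre = h1_pre,
                      zn = zn, probs = probs, oh = oh, ce = ce, v = v)
  }
  out
}

# gradient of the combined objective for one double-view batch;
# dz: dL/dz (from the contrastive loss, already weighted by lambda),
# labels: per-view class labels for the cross-entropy term
.model_backward <- function(model, params, fw, dz, labels) {
  cache <- fw$cache
  v <- cache$v
  # cross-entropy on class scores of all views, mean over views
  onehot <- matrix(0, v, ncol(cache$probs))
  onehot[cbind(seq_len(v), labels + 1L)] <- 1
  dlogits <- (cache$probs - onehot) / v
  g_cls_w <- crossprod(cache$rn$y, dlogits)
  g_cls_b <- colSums(dlogits)
  dr <- tcrossprod(dlogits, params$cls$w)
  # projection head
  dz_raw <- .norm_backward(dz, cache$zn)
  g_p_w2 <- crossprod(cache$h1, dz_raw)
  g_p_b2 <- colSums(dz_raw)
  dh1 <- tcrossprod(dz_raw, params$proj$w2)
  dh1[cache$h1_pre <= 0] <- 0
  g_p_w1 <- crossprod(cache$rn$y, dh1)
  g_p_b1 <- colSums(dh1)
  dr <- dr + tcrossprod(dh1, params$proj$w1)
  # representation normalization and global average pooling
  dr_raw <- .norm_backward(dr, cache$rn)
  oh <- cache$oh; ce <- cache$ce
  dxm <- matrix(rep(as.vector(t(dr_raw)) / (oh * oh), each = oh * oh), oh * oh)
  dx <- array(dxm, c(oh, oh, ce, v))
  grads_conv <- vector("list", length(params$conv))
  for (k in rev(seq_along(params$conv))) {
    cb <- .conv_backward(dx, params$conv[[k]], model$geoms[[k]], cache$conv[[k]])
    grads_conv[[k]] <- list(w = cb$dw, gamma = cb$dgamma, beta = cb$dbeta)
    dx <- cb$dx
  }
  list(conv = grads_conv,
       proj = list(w1 = g_p_w1, b1 = g_p_b1, w2 = g_p_w2, b2 = g_p_b2),
       cls = list(w = g_cls_w, b = g_cls_b))
}

# ---- Adam over a nested parameter list ----------------------------------

.adam_init <- function(params) {
  zero_like <- function(p) {
    if (is.list(p)) lapply(p, zero_like) else p * 0
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (k in seq_along(p)) {
        res <- walk(p[[k]], g[[k]], m[[k]], v[[k]])
        out_p[[k]] <- res$p; out_m[[k]] <- res$m; out_v[[k]] <- res$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
    }
  }
  res <- walk(params, grads, state$m, state$v)
  list(params = res$p, state = list(m = res$m, v = res$v, t = t))
}
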