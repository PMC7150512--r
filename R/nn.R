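# A small, self-contained neural-network engine: dense / convolutional /
# batch-norm / dropout layers with explicit forward-backward passes and an
# Adam optimizer.  It exists to make the two-branch classifier trainable at
# desk scale on a CPU; the architecture contract (a backbone exposing a
# pooled feature vector that the metadata branch is fused with) is what the
# pipeline depends on, not this particular engine.
#
# Batches of images are 4-d arrays c(h, w, channels, n); feature batches are
# matrices n x d.  Parameters are nested named lists of numeric arrays, so
# the optimizer and the freeze contract operate structurally.

# ---- parameter-tree helpers -------------------------------------------------

ptree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- Map(function(x, y) ptree_map2(f, x, y), a, b)
    return(out)
  }
  f(a, b)
}

ptree_zero <- function(a) {
  if (is.list(a)) return(lapply(a, ptree_zero))
  array(0, dim = if (is.null(dim(a))) length(a) else dim(a))
}

he_init <- function(nin, nout) {
  matrix(rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
}

# ---- dense / batchnorm / dropout -------------------------------------------

dense_init <- function(nin, nout) list(W = he_init(nin, nout), b = numeric(nout))

dense_fwd <- function(p, x) sweep(x %*% p$W, 2, p$b, `+`)

dense_bwd <- function(p, x, dy) {
  list(grads = list(W = crossprod(x, dy), b = colSums(dy)),
       dx = tcrossprod(dy, p$W))
}

bn_init <- function(d) {
  list(gamma = rep(1, d), beta = numeric(d))
}

bn_state_init <- function(d) list(mean = numeric(d), var = rep(1, d))

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

bn_fwd <- function(p, state, x, train) {
  if (train && nrow(x) > 1) {
    mu <- colMeans(x)
    v <- colMeans(sweep(x, 2, mu)^2)
    state$mean <- (1 - BN_MOMENTUM) * state$mean + BN_MOMENTUM * mu
    state$var <- (1 - BN_MOMENTUM) * state$var + BN_MOMENTUM * v
  } else {
    mu <- state$mean; v <- state$var
  }
  inv_sd <- 1 / sqrt(v + BN_EPS)
  xhat <- sweep(sweep(x, 2, mu), 2, inv_sd, `*`)
  y <- sweep(sweep(xhat, 2, p$gamma, `*`), 2, p$beta, `+`)
  list(y = y, cache = list(xhat = xhat, inv_sd = inv_sd, train = train),
       state = state)
}

bn_bwd <- function(p, cache, dy) {
  xhat <- cache$xhat
  n <- nrow(dy)
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2, p$gamma, `*`)
  if (cache$train && n > 1) {
    dx <- sweep(dxhat - matrix(colMeans(dxhat), n, ncol(dy), byrow = TRUE) -
                  xhat * matrix(colMeans(dxhat * xhat), n, ncol(dy), byrow = TRUE),
                2, cache$inv_sd, `*`)
  } else {
    dx <- sweep(dxhat, 2, cache$inv_sd, `*`)
  }
  list(grads = list(gamma = dgamma, beta = dbeta), dx = dx)
}

relu_fwd <- function(x) {
  y <- x; y[y < 0] <- 0
  y
}

dropout_fwd <- function(x, p_drop, train) {
  if (!train || p_drop <= 0) return(list(y = x, mask = NULL))
  mask <- matrix(runif(length(x)) >= p_drop, nrow(x), ncol(x)) / (1 - p_drop)
  list(y = x * mask, mask = mask)
}

# ---- convolution via im2col -------------------------------------------------

# Precompute patch gather indices for a (h, w, cin) image, valid 3x3-style
# convolution, stride 1.  Rows ordered column-major over output positions
# (oy fastest), columns over (dy, dx, c).
conv_indices <- function(h, w, cin, k) {
  oh <- h - k + 1L; ow <- w - k + 1L
  oy <- rep(seq_len(oh), times = ow) - 1L
  ox <- rep(seq_len(ow), each = oh) - 1L
  cols <- expand.grid(dy = 0:(k - 1L), dx = 0:(k - 1L), c = 0:(cin - 1L))
  idx <- matrix(0L, oh * ow, nrow(cols))
  for (j in seq_len(nrow(cols))) {
    idx[, j] <- (oy + cols$dy[j]) + h * (ox + cols$dx[j]) + h * w * cols$c[j] + 1L
  }
  list(idx = idx, oh = oh, ow = ow)
}

conv_init <- function(cin, cout, k = 3L) {
  list(W = he_init(k * k * cin, cout), b = numeric(cout))
}

# x: array (h, w, cin, n).  Returns y (oh, ow, cout, n) and cache.
conv_fwd <- function(p, x, ci) {
  d <- dim(x); n <- d[4]
  xm <- matrix(x, prod(d[1:3]), n)
  npos <- nrow(ci$idx)
  xcol <- matrix(0, n * npos, ncol(ci$idx))
  for (i in seq_len(n))
    xcol[(i - 1L) * npos + seq_len(npos), ] <- xm[ci$idx, i]
  ym <- sweep(xcol %*% p$W, 2, p$b, `+`)
  cout <- ncol(p$W)
  y <- array(0, c(ci$oh, ci$ow, cout, n))
  for (i in seq_len(n))
    y[, , , i] <- array(ym[(i - 1L) * npos + seq_len(npos), ], c(ci$oh, ci$ow, cout))
  list(y = y, cache = list(xcol = xcol, xdim = d, ci = ci))
}

conv_bwd <- function(p, cache, dy) {
  d <- cache$xdim; n <- d[4]; ci <- cache$ci
  npos <- nrow(ci$idx)
  cout <- ncol(p$W)
  dym <- matrix(0, n * npos, cout)
  for (i in seq_len(n))
    dym[(i - 1L) * npos + seq_len(npos), ] <- matrix(dy[, , , i], npos, cout)
  dW <- crossprod(cache$xcol, dym)
  db <- colSums(dym)
  dxcol <- tcrossprod(dym, p$W)
  dxm <- matrix(0, prod(d[1:3]), n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * npos + seq_len(npos)
    for (j in seq_len(ncol(ci$idx)))
      dxm[ci$idx[, j], i] <- dxm[ci$idx[, j], i] + dxcol[rows, j]
  }
  list(grads = list(W = dW, b = db), dx = array(dxm, d))
}

# 2x2 average pooling, stride 2; odd trailing row/column dropped.
pool_fwd <- function(x) {
  d <- dim(x)
  oh <- d[1] %/% 2L; ow <- d[2] %/% 2L
  x <- x[seq_len(2L * oh), seq_len(2L * ow), , , drop = FALSE]
  y <- (x[seq(1, 2 * oh, 2), seq(1, 2 * ow, 2), , , drop = FALSE] +
        x[seq(2, 2 * oh, 2), seq(1, 2 * ow, 2), , , drop = FALSE] +
        x[seq(1, 2 * oh, 2), seq(2, 2 * ow, 2), , , drop = FALSE] +
        x[seq(2, 2 * oh, 2), seq(2, 2 * ow, 2), , , drop = FALSE]) / 4
  list(y = y, xdim = d)
}

pool_bwd <- function(dy, xdim) {
  d <- dim(dy)
  dx <- array(0, xdim)
  g <- dy / 4
  dx[seq(1, 2 * d[1], 2), seq(1, 2 * d[2], 2), , ] <- g
  dx[seq(2, 2 * d[1], 2), seq(1, 2 * d[2], 2), , ] <- g
  dx[seq(1, 2 * d[1], 2), seq(2, 2 * d[2], 2), , ] <- g
  dx[seq(2, 2 * d[1], 2), seq(2, 2 * d[2], 2), , ] <- g
  dx
}

gap_fwd <- function(x) {
  d <- dim(x)
  feat <- t(apply(x, 4, function(a) colMeans(matrix(a, d[1] * d[2], d[3]))))
  if (d[4] == 1L) feat <- matrix(feat, 1, d[3])
  list(y = feat, xdim = d)
}

gap_bwd <- function(dfeat, xdim) {
  n <- xdim[4]
  dx <- array(0, xdim)
  per <- 1 / (xdim[1] * xdim[2])
  for (i in seq_len(n))
    dx[, , , i] <- aperm(array(rep(dfeat[i, ], each = xdim[1] * xdim[2]), xdim[1:3]),
                         c(1, 2, 3)) * per
  dx
}

# ---- tiny convolutional backbone -------------------------------------------

#' Tiny convolutional backbone
#'
#' A three-block CNN (3x3 valid convolutions, ReLU, 2x2 average pooling)
#' ending in global average pooling, satisfying the backbone contract used by
#' [build_two_branch_model()]: a declared input size and pooled feature
#' width, plus `init` / `forward` / `backward` closures.  It is small enough
#' to train in seconds on a CPU while separating the synthetic nine-class
#' task; GPU-scale backbones can be substituted by implementing the same
#' contract.
#'
#' @param input_size `c(h, w)` of the network input in pixels.
#' @param channels feature maps of the three blocks; the last entry is the
#'   pooled feature width.
#' @return backbone object of class `dermpipe_backbone`.
#' @export
tiny_backbone <- function(input_size = c(48L, 48L), channels = c(8L, 16L, 32L)) {
  abort_if(length(channels) != 3, "tiny_backbone uses exactly three blocks")
  h <- input_size[1]; w <- input_size[2]
  # Precompute gather indices per block for the fixed input geometry.
  ci1 <- conv_indices(h, w, 3L, 3L)
  h1 <- ci1$oh %/% 2L; w1 <- ci1$ow %/% 2L
  ci2 <- conv_indices(h1, w1, channels[1], 3L)
  h2 <- ci2$oh %/% 2L; w2 <- ci2$ow %/% 2L
  ci3 <- conv_indices(h2, w2, channels[2], 3L)
  abort_if(ci3$oh < 1 || ci3$ow < 1, "input_size too small for three blocks")

  structure(list(
    input_size = as.integer(input_size),
    feature_width = as.integer(channels[3]),
    init = function() list(conv1 = conv_init(3L, channels[1]),
                           conv2 = conv_init(channels[1], channels[2]),
                           conv3 = conv_init(channels[2], channels[3])),
    forward = function(params, x, train = TRUE) {
      c1 <- conv_fwd(params$conv1, x, ci1); a1 <- relu_fwd(c1$y)
      p1 <- pool_fwd(a1)
      c2 <- conv_fwd(params$conv2, p1$y, ci2); a2 <- relu_fwd(c2$y)
      p2 <- pool_fwd(a2)
      c3 <- conv_fwd(params$conv3, p2$y, ci3); a3 <- relu_fwd(c3$y)
      g <- gap_fwd(a3)
      list(features = g$y,
           cache = list(c1 = c1, a1 = a1, p1 = p1, c2 = c2, a2 = a2,
                        p2 = p2, c3 = c3, a3 = a3, g = g))
    },
    backward = function(params, cache, dfeat) {
      da3 <- gap_bwd(dfeat, cache$g$xdim)
      da3[cache$a3 <= 0] <- 0
      b3 <- conv_bwd(params$conv3, cache$c3$cache, da3)
      dp2 <- pool_bwd(b3$dx, cache$p2$xdim)
      dp2[cache$a2 <= 0] <- 0
      b2 <- conv_bwd(params$conv2, cache$c2$cache, dp2)
      dp1 <- pool_bwd(b2$dx, cache$p1$xdim)
      dp1[cache$a1 <= 0] <- 0
      b1 <- conv_bwd(params$conv1, cache$c1$cache, dp1)
      list(conv1 = b1$grads, conv2 = b2$grads, conv3 = b3$grads)
    }), class = "dermpipe_backbone")
}

# ---- two-branch model -------------------------------------------------------

#' Metadata-branch and fusion architecture settings
#'
#' @param hidden_units units of the two metadata dense layers (default 256).
#' @param meta_dropout dropout probability inside the metadata branch
#'   (default 0.4).
#' @param fusion_units width of the post-concatenation fusion layer
#'   (default 1024; scalable for larger backbones).
#' @param fusion_dropout dropout probability after the fusion layer.
#' @return settings list of class `meta_branch_spec`.
#' @export
meta_branch_spec <- function(hidden_units = 256L, meta_dropout = 0.4,
                             fusion_units = 1024L, fusion_dropout = 0.4) {
  abort_if(hidden_units < 1 || fusion_units < 1, "layer widths must be positive")
  abort_if(meta_dropout < 0 || meta_dropout >= 1 ||
             fusion_dropout < 0 || fusion_dropout >= 1,
           "dropout must be in [0, 1)")
  structure(list(hidden_units = as.integer(hidden_units),
                 meta_dropout = meta_dropout,
                 fusion_units = as.integer(fusion_units),
                 fusion_dropout = fusion_dropout),
            class = "meta_branch_spec")
}

META_DIM <- 11L

#' Build the two-branch (image + metadata) classifier
#'
#' In `"image_only"` mode the pooled backbone features feed a linear
#' classifier directly.  In `"meta"` mode the 11-dimensional metadata vector
#' passes through two dense layers (batch norm, ReLU, dropout), is
#' concatenated with the backbone features, and a fusion layer (batch norm,
#' ReLU, dropout) precedes the classifier.
#'
#' @param backbone a backbone object such as [tiny_backbone()].
#' @param meta_spec a [meta_branch_spec()]; ignored in image-only mode.
#' @param mode `"image_only"` or `"meta"`.
#' @param num_classes number of output classes (default 9).
#' @param seed integer seed for weight initialization.
#' @return model object of class `dermpipe_model`.
#' @export
build_two_branch_model <- function(backbone, meta_spec = meta_branch_spec(),
                                   mode = c("image_only", "meta"),
                                   num_classes = 9L, seed = 1L) {
  mode <- match.arg(mode)
  abort_if(!inherits(backbone, "dermpipe_backbone"),
           "backbone must satisfy the dermpipe_backbone contract")
  withr::with_seed(seed, {
    fw <- backbone$feature_width
    if (mode == "image_only") {
      head <- list(classifier = dense_init(fw, num_classes))
      bn_state <- list()
    } else {
      hu <- meta_spec$hidden_units; fu <- meta_spec$fusion_units
      head <- list(meta1 = dense_init(META_DIM, hu), bn1 = bn_init(hu),
                   meta2 = dense_init(hu, hu), bn2 = bn_init(hu),
                   fusion = dense_init(fw + hu, fu), bnf = bn_init(fu),
                   classifier = dense_init(fu, num_classes))
      bn_state <- list(bn1 = bn_state_init(hu), bn2 = bn_state_init(hu),
                       bnf = bn_state_init(fu))
    }
    params <- list(backbone = backbone$init(), head = head)
  })
  structure(list(backbone = backbone, params = params, bn_state = bn_state,
                 mode = mode, meta_spec = meta_spec,
                 num_classes = as.integer(num_classes)),
            class = "dermpipe_model")
}

#' @export
print.dermpipe_model <- function(x, ...) {
  np <- sum(unlist(lapply(rapply(x$params, length, how = "list"), unlist)))
  cat(sprintf("<dermpipe_model mode=%s  feature_width=%d  params=%d>\n",
              x$mode, x$backbone$feature_width, np))
  invisible(x)
}

# Forward pass.  x: (h, w, 3, n) batch; meta: n x 11 matrix or NULL.
# Returns logits (n x K), caches, and the (possibly updated) model whose
# batch-norm running statistics advanced when train = TRUE.
model_forward <- function(model, x, meta = NULL, train = TRUE) {
  if (model$mode == "meta") {
    abort_if(is.null(meta), "meta mode requires a metadata matrix")
    abort_if(ncol(meta) != META_DIM, "metadata matrix must have 11 columns")
  } else {
    abort_if(!is.null(meta), "metadata supplied to an image-only model")
  }
  bb <- model$backbone$forward(model$params$backbone, x, train)
  hp <- model$params$head
  if (model$mode == "image_only") {
    logits <- dense_fwd(hp$classifier, bb$features)
    return(list(logits = logits, model = model,
                cache = list(bb = bb, feat = bb$features)))
  }
  st <- model$bn_state
  z1 <- dense_fwd(hp$meta1, meta)
  b1 <- bn_fwd(hp$bn1, st$bn1, z1, train); st$bn1 <- b1$state
  a1 <- relu_fwd(b1$y)
  d1 <- dropout_fwd(a1, model$meta_spec$meta_dropout, train)
  z2 <- dense_fwd(hp$meta2, d1$y)
  b2 <- bn_fwd(hp$bn2, st$bn2, z2, train); st$bn2 <- b2$state
  a2 <- relu_fwd(b2$y)
  d2 <- dropout_fwd(a2, model$meta_spec$meta_dropout, train)
  concat <- cbind(bb$features, d2$y)
  zf <- dense_fwd(hp$fusion, concat)
  bf <- bn_fwd(hp$bnf, st$bnf, zf, train); st$bnf <- bf$state
  af <- relu_fwd(bf$y)
  df <- dropout_fwd(af, model$meta_spec$fusion_dropout, train)
  logits <- dense_fwd(hp$classifier, df$y)
  model$bn_state <- st
  list(logits = logits, model = model,
       cache = list(bb = bb, meta = meta, z1 = z1, b1 = b1, a1 = a1, d1 = d1,
                    z2 = z2, b2 = b2, a2 = a2, d2 = d2, concat = concat,
                    zf = zf, bf = bf, af = af, df = df))
}

# Backward pass; backbone gradients are omitted when freeze_backbone = TRUE
# (the meta training stage).
model_backward <- function(model, cache, dlogits, freeze_backbone = FALSE) {
  hp <- model$params$head
  if (model$mode == "image_only") {
    bc <- dense_bwd(hp$classifier, cache$feat, dlogits)
    head_grads <- list(classifier = bc$grads)
    bb_grads <- if (freeze_backbone) NULL else
      model$backbone$backward(model$params$backbone, cache$bb$cache, bc$dx)
    return(list(backbone = bb_grads, head = head_grads))
  }
  bc <- dense_bwd(hp$classifier, cache$df$y, dlogits)
  daf <- bc$dx
  if (!is.null(cache$df$mask)) daf <- daf * cache$df$mask
  daf[cache$af <= 0] <- 0
  bnf <- bn_bwd(hp$bnf, cache$bf$cache, daf)
  fus <- dense_bwd(hp$fusion, cache$concat, bnf$dx)
  fw <- model$backbone$feature_width
  dfeat <- fus$dx[, seq_len(fw), drop = FALSE]
  dmeta2 <- fus$dx[, -seq_len(fw), drop = FALSE]
  if (!is.null(cache$d2$mask)) dmeta2 <- dmeta2 * cache$d2$mask
  dmeta2[cache$a2 <= 0] <- 0
  bn2 <- bn_bwd(hp$bn2, cache$b2$cache, dmeta2)
  m2 <- dense_bwd(hp$meta2, cache$d1$y, bn2$dx)
  da1 <- m2$dx
  if (!is.null(cache$d1$mask)) da1 <- da1 * cache$d1$mask
  da1[cache$a1 <= 0] <- 0
  bn1 <- bn_bwd(hp$bn1, cache$b1$cache, da1)
  m1 <- dense_bwd(hp$meta1, cache$meta, bn1$dx)
  head_grads <- list(meta1 = m1$grads, bn1 = bn1$grads, meta2 = m2$grads,
                     bn2 = bn2$grads, fusion = fus$grads, bnf = bnf$grads,
                     classifier = bc$grads)
  bb_grads <- if (freeze_backbone) NULL else
    model$backbone$backward(model$params$backbone, cache$bb$cache, dfeat)
  list(backbone = bb_grads, head = head_grads)
}

# Softmax over logit rows, numerically stabilized.
softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# ---- Adam -------------------------------------------------------------------

adam_state <- function(params) list(m = ptree_zero(params), v = ptree_zero(params), t = 0L)

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- ptree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- ptree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  upd <- ptree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                    state$m, state$v)
  params <- ptree_map2(`-`, params, upd)
  list(params = params, state = state)
}
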