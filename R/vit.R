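# Encoder-only Vision Transformer: patch embedding + class token + position
# embeddings, N post-norm encoder layers (multi-head self-attention and a
# position-wise feed-forward network, each wrapped as LayerNorm(x +
# Sublayer(x))), and a linear classification head over the class token.
# Forward pass, analytic gradients and Adam updates are implemented directly
# on base-R matrices.

#' Vision Transformer configuration
#'
#' Defaults follow the reference transformer encoder (d_model 512, 6 layers,
#' 8 heads, feed-forward width 2048, 16 px patches on 224 px images). The
#' desk-scale profile used throughout the tests is 64 px images, patch 16,
#' d_model 64, 2 layers, 4 heads.
#'
#' @param image_size Square image side in pixels.
#' @param patch_size Patch side in pixels; must divide `image_size`.
#' @param d_model Embedding width; must be divisible by `n_heads`.
#' @param n_layers Number of encoder layers (>= 1).
#' @param n_heads Attention heads.
#' @param d_ff Feed-forward hidden width.
#' @param n_classes 2 (binary wheeze/crackle tasks) or 4.
#' @param dropout Dropout rate applied to each sub-layer output during
#'   training (default 0).
#' @param seed Seed for parameter initialization.
#' @return An object of class `vit_config`.
#' @export
vit_config <- function(image_size = 224, patch_size = 16, d_model = 512,
                       n_layers = 6, n_heads = 8, d_ff = 2048,
                       n_classes = 2, dropout = 0, seed = 1L) {
  if (image_size %% patch_size != 0)
    stop("image_size must be divisible by patch_size")
  if (d_model %% n_heads != 0)
    stop("d_model must be divisible by n_heads")
  if (n_layers < 1) stop("n_layers must be >= 1")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  structure(list(image_size = image_size, patch_size = patch_size,
                 d_model = d_model, n_layers = n_layers, n_heads = n_heads,
                 d_ff = d_ff, n_classes = as.integer(n_classes),
                 dropout = dropout, seed = as.integer(seed),
                 n_patches = as.integer((image_size / patch_size)^2),
                 patch_dim = as.integer(patch_size^2 * 3L)),
            class = "vit_config")
}

#' Split an image into flattened patches
#'
#' Non-overlapping `patch_size` x `patch_size` patches in row-major order
#' (left to right, top to bottom), each flattened to length
#' `patch_size^2 * 3`. Pixel values are rescaled from 0-255 to \[0, 1\].
#'
#' @param image A `feature_image` or an H x W x 3 numeric array.
#' @param patch_size Patch side in pixels; must divide the image side.
#' @return `P` x `patch_size^2*3` numeric matrix, `P = (side/patch_size)^2`.
#' @export
patchify <- function(image, patch_size) {
  px <- if (inherits(image, "feature_image")) image$pixels else image
  d <- dim(px)
  if (length(d) != 3L || d[1] != d[2])
    stop("image must be a square H x H x 3 array")
  side <- d[1]
  if (side %% patch_size != 0)
    stop("image side must be divisible by patch_size")
  if (max(px) > 1) px <- px / 255
  g <- side / patch_size
  P <- matrix(0, g * g, patch_size^2 * 3L)
  for (pr in seq_len(g)) {
    rows <- ((pr - 1) * patch_size + 1):(pr * patch_size)
    for (pc in seq_len(g)) {
      cols <- ((pc - 1) * patch_size + 1):(pc * patch_size)
      P[(pr - 1) * g + pc, ] <- as.vector(px[rows, cols, ])
    }
  }
  P
}

# truncated normal (resample beyond 2 sd), the reference ViT initialization
.trunc_normal <- function(n, sd = 0.02) {
  x <- stats::rnorm(n, 0, sd)
  repeat {
    bad <- abs(x) > 2 * sd
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), 0, sd)
  }
  x
}

#' Initialize Vision Transformer parameters
#'
#' Truncated-normal (sd 0.02) embeddings and projections, zero biases, unit
#' LayerNorm gains; deterministic given the seed.
#'
#' @param cfg A [vit_config].
#' @param seed Seed (defaults to `cfg$seed`).
#' @return Nested list of parameter matrices/vectors.
#' @export
vit_init <- function(cfg, seed = cfg$seed) {
  set.seed(seed)
  d <- cfg$d_model; dff <- cfg$d_ff
  tn <- function(r, c) matrix(.trunc_normal(r * c), r, c)
  layers <- lapply(seq_len(cfg$n_layers), function(l) list(
    Wq = tn(d, d), bq = numeric(d), Wk = tn(d, d), bk = numeric(d),
    Wv = tn(d, d), bv = numeric(d), Wo = tn(d, d), bo = numeric(d),
    g1 = rep(1, d), b1 = numeric(d),
    W1 = tn(d, dff), bw1 = numeric(dff), W2 = tn(dff, d), bw2 = numeric(d),
    g2 = rep(1, d), b2 = numeric(d)))
  list(Wp = tn(cfg$patch_dim, d), bp = numeric(d),
       cls = .trunc_normal(d),
       pos = tn(cfg$n_patches + 1L, d),
       layers = layers,
       Wh = tn(d, cfg$n_classes), bh = numeric(cfg$n_classes))
}

# ---- building blocks --------------------------------------------------------

.softmax_rows <- function(S) {
  rmax <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - rmax)
  E / rowSums(E)
}

# add a length-ncol vector to every row (column-major fill)
.add_row <- function(M, b) M + rep(b, each = nrow(M))

.ln_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  istd <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * istd
  n <- nrow(X)
  list(Y = xhat * rep(g, each = n) + rep(b, each = n),
       xhat = xhat, istd = istd)
}

.ln_bwd <- function(dY, cache, g) {
  xhat <- cache$xhat
  dxhat <- dY * rep(g, each = nrow(dY))
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- cache$istd * (dxhat - m1 - xhat * m2)
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

.mhsa_fwd <- function(X, lp, n_heads) {
  d <- ncol(X); dk <- d / n_heads
  Q <- .add_row(X %*% lp$Wq, lp$bq)
  K <- .add_row(X %*% lp$Wk, lp$bk)
  V <- .add_row(X %*% lp$Wv, lp$bv)
  O <- matrix(0, nrow(X), d)
  A_list <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1) * dk + 1):(h * dk)
    S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) /
      sqrt(dk)
    A <- .softmax_rows(S)
    A_list[[h]] <- A
    O[, cols] <- A %*% V[, cols, drop = FALSE]
  }
  out <- .add_row(O %*% lp$Wo, lp$bo)
  list(out = out, Q = Q, K = K, V = V, O = O, A = A_list)
}

.mhsa_bwd <- function(dout, cache, lp, X, n_heads) {
  d <- ncol(X); dk <- d / n_heads
  dWo <- crossprod(cache$O, dout)
  dbo <- colSums(dout)
  dO <- tcrossprod(dout, lp$Wo)
  dQ <- matrix(0, nrow(X), d); dK <- dQ; dV <- dQ
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1) * dk + 1):(h * dk)
    A <- cache$A[[h]]
    dOh <- dO[, cols, drop = FALSE]
    Vh <- cache$V[, cols, drop = FALSE]
    dA <- tcrossprod(dOh, Vh)
    dV[, cols] <- crossprod(A, dOh)
    dS <- A * (dA - rowSums(dA * A))
    dQ[, cols] <- dS %*% cache$K[, cols, drop = FALSE] / sqrt(dk)
    dK[, cols] <- crossprod(dS, cache$Q[, cols, drop = FALSE]) / sqrt(dk)
  }
  list(dX = tcrossprod(dQ, lp$Wq) + tcrossprod(dK, lp$Wk) +
         tcrossprod(dV, lp$Wv),
       dWq = crossprod(X, dQ), dbq = colSums(dQ),
       dWk = crossprod(X, dK), dbk = colSums(dK),
       dWv = crossprod(X, dV), dbv = colSums(dV),
       dWo = dWo, dbo = dbo)
}

#' Apply one transformer encoder layer
#'
#' Post-norm residual form: `h = LayerNorm(x + MHSA(x))`,
#' `out = LayerNorm(h + FFN(h))`, with ReLU in the position-wise FFN.
#'
#' @param X Token matrix (T x d_model).
#' @param layer_params One element of the `layers` list from [vit_init()].
#' @param n_heads Number of attention heads.
#' @param return_attention If `TRUE`, attach the per-head attention maps as
#'   attribute `"attention"`.
#' @return Transformed token matrix (T x d_model).
#' @export
vit_encoder_layer <- function(X, layer_params, n_heads,
                              return_attention = FALSE) {
  st <- .layer_fwd(X, layer_params, n_heads, dropout = 0, training = FALSE)
  out <- st$X2
  if (!all(is.finite(out))) stop("non-finite activations in encoder layer")
  if (return_attention) attr(out, "attention") <- st$att$A
  out
}

.layer_fwd <- function(X, lp, n_heads, dropout, training) {
  att <- .mhsa_fwd(X, lp, n_heads)
  a_out <- att$out
  mask_a <- NULL
  if (training && dropout > 0) {
    mask_a <- matrix(stats::rbinom(length(a_out), 1, 1 - dropout) /
                       (1 - dropout), nrow(a_out), ncol(a_out))
    a_out <- a_out * mask_a
  }
  ln1 <- .ln_fwd(X + a_out, lp$g1, lp$b1)
  X1 <- ln1$Y
  Hpre <- .add_row(X1 %*% lp$W1, lp$bw1)
  H <- pmax(Hpre, 0)
  f_out <- .add_row(H %*% lp$W2, lp$bw2)
  mask_f <- NULL
  if (training && dropout > 0) {
    mask_f <- matrix(stats::rbinom(length(f_out), 1, 1 - dropout) /
                       (1 - dropout), nrow(f_out), ncol(f_out))
    f_out <- f_out * mask_f
  }
  ln2 <- .ln_fwd(X1 + f_out, lp$g2, lp$b2)
  list(X_in = X, att = att, a_out = a_out, mask_a = mask_a, ln1 = ln1,
       X1 = X1, Hpre = Hpre, H = H, f_out = f_out, mask_f = mask_f,
       ln2 = ln2, X2 = ln2$Y)
}

.layer_bwd <- function(dX2, st, lp, n_heads) {
  l2 <- .ln_bwd(dX2, st$ln2, lp$g2)
  dres2 <- l2$dX                       # grad wrt (X1 + f_out)
  df_out <- if (is.null(st$mask_f)) dres2 else dres2 * st$mask_f
  dW2 <- crossprod(st$H, df_out)
  dbw2 <- colSums(df_out)
  dH <- tcrossprod(df_out, lp$W2)
  dHpre <- dH * (st$Hpre > 0)
  dW1 <- crossprod(st$X1, dHpre)
  dbw1 <- colSums(dHpre)
  dX1 <- dres2 + tcrossprod(dHpre, lp$W1)
  l1 <- .ln_bwd(dX1, st$ln1, lp$g1)
  dres1 <- l1$dX                       # grad wrt (X + a_out)
  da_out <- if (is.null(st$mask_a)) dres1 else dres1 * st$mask_a
  mh <- .mhsa_bwd(da_out, st$att, lp, st$X_in, n_heads)
  list(dX = dres1 + mh$dX,
       grads = list(Wq = mh$dWq, bq = mh$dbq, Wk = mh$dWk, bk = mh$dbk,
                    Wv = mh$dWv, bv = mh$dbv, Wo = mh$dWo, bo = mh$dbo,
                    g1 = l1$dg, b1 = l1$db,
                    W1 = dW1, bw1 = dbw1, W2 = dW2, bw2 = dbw2,
                    g2 = l2$dg, b2 = l2$db))
}

#' Embed patches as a token sequence
#'
#' Linear projection of each flattened patch to `d_model`, a learnable class
#' token prepended at position 0, and learnable position embeddings added
#' elementwise.
#'
#' @param patches P x patch_dim matrix from [patchify()].
#' @param params Parameter list from [vit_init()].
#' @param cfg A [vit_config].
#' @return (P + 1) x d_model token matrix.
#' @export
vit_embed <- function(patches, params, cfg) {
  if (nrow(patches) != cfg$n_patches)
    stop("patch count does not match the configuration geometry")
  if (ncol(patches) != cfg$patch_dim || ncol(params$Wp) != cfg$d_model)
    stop("parameter shapes inconsistent with the configuration")
  tok <- rbind(params$cls, .add_row(patches %*% params$Wp, params$bp))
  tok + params$pos
}

# forward for one sample from its patch matrix; returns probs (+cache)
.vit_fwd <- function(Pmat, params, cfg, training = FALSE,
                     keep_cache = FALSE, return_attention = FALSE) {
  X <- vit_embed(Pmat, params, cfg)
  states <- if (keep_cache) vector("list", cfg$n_layers) else NULL
  attn <- if (return_attention) vector("list", cfg$n_layers) else NULL
  for (l in seq_len(cfg$n_layers)) {
    st <- .layer_fwd(X, params$layers[[l]], cfg$n_heads,
                     cfg$dropout, training)
    if (!all(is.finite(st$X2)))
      stop("non-finite activations in encoder layer ", l)
    if (keep_cache) states[[l]] <- st
    if (return_attention) attn[[l]] <- st$att$A
    X <- st$X2
  }
  logits <- drop(X[1, ] %*% params$Wh) + params$bh
  z <- logits - max(logits)
  probs <- exp(z) / sum(exp(z))
  list(probs = probs, logits = logits, X_out = X, states = states,
       attention = attn)
}

.vit_bwd <- function(fw, y_idx, Pmat, params, cfg) {
  dlogits <- fw$probs
  dlogits[y_idx] <- dlogits[y_idx] - 1
  g <- list(Wh = outer(fw$X_out[1, ], dlogits), bh = dlogits)
  dX <- matrix(0, cfg$n_patches + 1L, cfg$d_model)
  dX[1, ] <- drop(params$Wh %*% dlogits)
  g$layers <- vector("list", cfg$n_layers)
  for (l in rev(seq_len(cfg$n_layers))) {
    lb <- .layer_bwd(dX, fw$states[[l]], params$layers[[l]], cfg$n_heads)
    g$layers[[l]] <- lb$grads
    dX <- lb$dX
  }
  g$pos <- dX
  g$cls <- dX[1, ]
  dPe <- dX[-1, , drop = FALSE]
  g$Wp <- crossprod(Pmat, dPe)
  g$bp <- colSums(dPe)
  g[c("Wp", "bp", "cls", "pos", "layers", "Wh", "bh")]
}

# params are kept in canonical field order so unlist() vectors are congruent
.canonical_params <- function(p) {
  p$layers <- lapply(p$layers, function(l)
    l[c("Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo",
        "g1", "b1", "W1", "bw1", "W2", "bw2", "g2", "b2")])
  p[c("Wp", "bp", "cls", "pos", "layers", "Wh", "bh")]
}

# elementwise sum of two congruent nested lists of numerics
.plist_add <- function(a, b, w = 1) {
  for (i in seq_along(a)) {
    a[[i]] <- if (is.list(a[[i]])) .plist_add(a[[i]], b[[i]], w)
              else a[[i]] + w * b[[i]]
  }
  a
}

.plist_scale <- function(a, s) {
  for (i in seq_along(a))
    a[[i]] <- if (is.list(a[[i]])) .plist_scale(a[[i]], s) else a[[i]] * s
  a
}

# mean cross-entropy loss (and gradient vector) over a batch of samples
.vit_loss_grads <- function(params, patch_list, y_idx, cfg,
                            training = FALSE, with_grads = TRUE,
                            sample_weights = NULL) {
  n <- length(patch_list)
  if (is.null(sample_weights)) sample_weights <- rep(1, n)
  loss <- 0; correct <- 0; gsum <- NULL
  for (i in seq_len(n)) {
    fw <- .vit_fwd(patch_list[[i]], params, cfg, training = training,
                   keep_cache = with_grads)
    loss <- loss + sample_weights[i] * (-log(max(fw$probs[y_idx[i]], 1e-12)))
    correct <- correct + (which.max(fw$probs) == y_idx[i])
    if (with_grads) {
      gi <- .vit_bwd(fw, y_idx[i], patch_list[[i]], params, cfg)
      gsum <- if (is.null(gsum)) .plist_scale(gi, sample_weights[i])
              else .plist_add(gsum, gi, sample_weights[i])
    }
  }
  wsum <- sum(sample_weights)
  list(loss = loss / wsum,
       acc = correct / n,
       grads = if (with_grads)
         unlist(gsum, use.names = FALSE) / wsum else NULL)
}

#' Forward pass: class probabilities for one image
#'
#' @param image A `feature_image`, an H x W x 3 array, or a pre-computed
#'   patch matrix.
#' @param params Parameter list from [vit_init()] (or a fitted `vit_model`'s
#'   `params`).
#' @param cfg A [vit_config].
#' @param return_attention If `TRUE`, attach per-layer, per-head attention
#'   maps as attribute `"attention"`.
#' @return Named numeric vector of `n_classes` probabilities (sums to 1).
#' @export
vit_forward <- function(image, params, cfg, return_attention = FALSE) {
  Pmat <- if (is.matrix(image)) image else patchify(image, cfg$patch_size)
  fw <- .vit_fwd(Pmat, params, cfg, return_attention = return_attention)
  p <- fw$probs
  if (return_attention) attr(p, "attention") <- fw$attention
  p
}

# ---- Adam -------------------------------------------------------------------

.adam_new <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

.adam_step <- function(theta, grad, st, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- beta1 * st$m + (1 - beta1) * grad
  st$v <- beta2 * st$v + (1 - beta2) * grad^2
  mhat <- st$m / (1 - beta1^st$t)
  vhat <- st$v / (1 - beta2^st$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = st)
}
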