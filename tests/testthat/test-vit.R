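test_that("patchify produces row-major non-overlapping patches of the right shape", {
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  P <- patchify(img, 16)
  expect_equal(dim(P), c(16, 768))
  # first patch is the top-left block, flattened column-major per channel
  expect_equal(P[1, 1:16], img[1:16, 1, 1])
  # second patch sits to the right of the first (row-major order)
  expect_equal(P[2, 1:16], img[1:16, 17, 1])

  big <- array(0, c(224, 224, 3))
  expect_equal(nrow(patchify(big, 16)), 196)
  expect_error(patchify(img, 13), "divisible")
})

test_that("embedding prepends the class token and adds position embeddings", {
  cfg <- tiny_vit_config()
  pr <- vit_init(cfg, seed = 2)
  P0 <- matrix(0, cfg$n_patches, cfg$patch_dim)
  tok <- vit_embed(P0, pr, cfg)
  expect_equal(dim(tok), c(cfg$n_patches + 1, cfg$d_model))
  # zero patches: tokens reduce to class token / biases plus positions
  expect_equal(tok[1, ], pr$cls + pr$pos[1, ])
  expect_equal(tok[2, ], pr$bp + pr$pos[2, ])

  # with zero position embeddings, permuting patches permutes token rows
  pr0 <- pr; pr0$pos[] <- 0
  set.seed(3)
  P <- matrix(rnorm(cfg$n_patches * cfg$patch_dim), cfg$n_patches)
  perm <- sample(cfg$n_patches)
  t1 <- vit_embed(P, pr0, cfg)
  t2 <- vit_embed(P[perm, ], pr0, cfg)
  expect_equal(t2[1, ], t1[1, ])
  expect_equal(t2[-1, ], t1[-1, ][perm, ])

  expect_error(vit_embed(P[1:3, ], pr, cfg), "patch count")
})

test_that("attention rows are simplexes and single-token attention is trivial", {
  cfg <- tiny_vit_config()
  pr <- vit_init(cfg, seed = 4)
  set.seed(4)
  X <- matrix(rnorm(17 * 64), 17, 64)
  out <- vit_encoder_layer(X, pr$layers[[1]], cfg$n_heads,
                           return_attention = TRUE)
  for (A in attr(out, "attention"))
    expect_equal(unname(rowSums(A)), rep(1, 17), tolerance = 1e-6)

  # a single-token sequence: softmax over one key is exactly 1, so the
  # attention output equals that token's value projection
  x1 <- matrix(rnorm(64), 1, 64)
  att <- respsound:::.mhsa_fwd(x1, pr$layers[[1]], cfg$n_heads)
  expect_equal(att$A[[1]][1, 1], 1)
  v1 <- x1 %*% pr$layers[[1]]$Wv + pr$layers[[1]]$bv
  o_exp <- (v1 %*% pr$layers[[1]]$Wo) + pr$layers[[1]]$bo
  expect_equal(att$out, o_exp, tolerance = 1e-12)
})

test_that("single-head attention matches the brute-force softmax(QK'/sqrt(dk))V oracle", {
  d <- 4
  lp <- list(Wq = diag(d), bq = numeric(d), Wk = diag(d), bk = numeric(d),
             Wv = diag(d), bv = numeric(d), Wo = diag(d), bo = numeric(d))
  X <- matrix(c(1, 0.5, -1, 2,
                0.2, -0.3, 1.5, 0.7), 2, d, byrow = TRUE)
  got <- respsound:::.mhsa_fwd(X, lp, n_heads = 1)$out
  # hand evaluation with identity projections
  S <- X %*% t(X) / sqrt(d)
  A <- t(apply(S, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  expect_equal(got, A %*% X, tolerance = 1e-12)
})

test_that("LayerNorm standardizes each token before the affine rescale", {
  set.seed(5)
  X <- matrix(rnorm(12 * 8, mean = 3, sd = 2), 12, 8)
  ln <- respsound:::.ln_fwd(X, g = rep(1, 8), b = numeric(8))
  expect_equal(rowMeans(ln$xhat), rep(0, 12), tolerance = 1e-10)
  expect_equal(apply(ln$xhat, 1, function(r) mean(r^2)), rep(1, 12),
               tolerance = 1e-3)   # population variance, up to eps
})

test_that("forward probabilities are a simplex and deterministic", {
  cfg <- tiny_vit_config(n_classes = 4)
  pr <- vit_init(cfg, seed = 6)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  p1 <- vit_forward(img, pr, cfg)
  p2 <- vit_forward(img, pr, cfg)
  expect_length(p1, 4)
  expect_true(all(p1 >= 0))
  expect_equal(sum(p1), 1, tolerance = 1e-6)
  expect_identical(p1, p2)
})

test_that("without position embeddings the class output ignores patch order", {
  cfg <- tiny_vit_config()
  pr <- vit_init(cfg, seed = 7)
  pr$pos[] <- 0
  set.seed(7)
  P <- matrix(runif(cfg$n_patches * cfg$patch_dim), cfg$n_patches)
  p_ref <- vit_forward(P, pr, cfg)
  for (i in 1:3) {
    perm <- sample(cfg$n_patches)
    expect_equal(vit_forward(P[perm, ], pr, cfg), p_ref, tolerance = 1e-5)
  }
})

test_that("analytic gradients match central finite differences on a toy model", {
  cfg <- vit_config(image_size = 2, patch_size = 2, d_model = 4,
                    n_layers = 1, n_heads = 2, d_ff = 8, n_classes = 2,
                    seed = 8)
  pr <- vit_init(cfg)
  set.seed(8)
  Pm <- matrix(runif(cfg$patch_dim), cfg$n_patches, cfg$patch_dim)
  lg <- respsound:::.vit_loss_grads(pr, list(Pm), 1L, cfg)
  sk <- respsound:::.canonical_params(pr)
  th <- unlist(sk, use.names = FALSE)
  loss_at <- function(t)
    respsound:::.vit_loss_grads(utils::relist(t, sk), list(Pm), 1L, cfg,
                                with_grads = FALSE)$loss
  eps <- 1e-5
  num <- vapply(seq_along(th), function(i) {
    tp <- th; tp[i] <- tp[i] + eps
    tm <- th; tm[i] <- tm[i] - eps
    (loss_at(tp) - loss_at(tm)) / (2 * eps)
  }, 0)
  denom <- pmax(abs(num) + abs(lg$grads), 1e-8)
  rel <- abs(num - lg$grads) / denom
  active <- abs(num) + abs(lg$grads) > 1e-7
  expect_lt(max(rel[active]), 1e-4)
})

test_that("training starts near the uniform-prediction loss and is seeded", {
  cfg <- tiny_vit_config()
  fix <- separable_images(32, seed = 10)
  tc <- train_config(epochs = 1, seed = 31)
  m1 <- vit_train(fix$images, fix$labels, cfg, tc, val_frac = 0)
  m2 <- vit_train(fix$images, fix$labels, cfg, tc, val_frac = 0)
  expect_lte(m1$history$train_loss[1], log(2) + 0.5)
  expect_equal(m1$history$train_loss[1], m2$history$train_loss[1],
               tolerance = 1e-6)
  expect_identical(m1$params$Wh, m2$params$Wh)

  expect_error(vit_train(list(), factor(character(0), levels = c("a", "b")),
                         cfg, tc), "length|empty")
})

test_that("a tiny model learns a linearly separable image set", {
  cfg <- tiny_vit_config()
  passes <- 0
  for (s in 1:3) {
    fix <- separable_images(60, seed = 100 + s)
    m <- vit_train(fix$images, fix$labels, cfg,
                   train_config(epochs = 30, seed = s), val_frac = 0)
    acc <- mean(predict(m, fix$images) == fix$labels)
    if (acc >= 0.95) passes <- passes + 1
  }
  expect_gte(passes, 2)
})

test_that("prediction breaks ties toward the lower class index and is stateless", {
  cfg <- tiny_vit_config()
  pr <- vit_init(cfg, seed = 12)
  # zero head: all logits equal -> uniform probabilities -> first class
  pr$Wh[] <- 0; pr$bh[] <- 0
  model <- structure(list(params = pr, config = cfg,
                          classes = c("first", "second"),
                          history = data.frame(train_acc = NA)),
                     class = "vit_model")
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  pp <- predict(model, img, type = "prob")
  expect_equal(unname(pp[1, ]), c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(as.character(predict(model, img)), "first")

  # batch prediction equals concatenated per-image prediction
  pr2 <- vit_init(cfg, seed = 13)
  model2 <- structure(list(params = pr2, config = cfg,
                           classes = c("a", "b"),
                           history = data.frame(train_acc = NA)),
                      class = "vit_model")
  imgs <- lapply(1:4, function(i) array(runif(64 * 64 * 3), c(64, 64, 3)))
  batch <- predict(model2, imgs)
  single <- vapply(imgs, function(im)
    as.character(predict(model2, im)), "")
  expect_identical(as.character(batch), single)
  expect_identical(batch, predict(model2, imgs))
})

test_that("configuration invariants are enforced", {
  expect_error(vit_config(image_size = 65, patch_size = 16), "divisible")
  expect_error(vit_config(d_model = 30, n_heads = 4), "divisible")
  expect_error(vit_config(n_layers = 0), "n_layers")
})
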