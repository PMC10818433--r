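#' Training configuration
#'
#' Defaults follow the study protocol: Adam, learning rate 0.001, batch
#' size 16, 30 epochs, early stopping with patience 10 on validation loss.
#'
#' @param epochs Maximum epochs (>= 1).
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam step size (> 0).
#' @param patience Early-stopping patience in epochs (validation loss);
#'   ignored when no validation set is available.
#' @param seed Integer seed covering initialization and shuffling.
#' @param class_weights Optional `"balanced"` for inverse-frequency class
#'   weights, or a numeric vector (one weight per class); default none.
#' @param clip_norm Global gradient-norm clip (default 1). Post-norm
#'   transformers are prone to late-training divergence under Adam;
#'   clipping keeps optimization stable. `Inf` disables.
#' @param verbose Print per-epoch progress.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 30, batch_size = 16, learning_rate = 0.001,
                         patience = 10, seed = 1L, class_weights = NULL,
                         clip_norm = 1, verbose = FALSE) {
  if (epochs < 1) stop("epochs must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 patience = as.integer(patience), seed = as.integer(seed),
                 class_weights = class_weights, clip_norm = clip_norm,
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

.as_patch_list <- function(x, cfg) {
  lapply(x, function(im)
    if (is.matrix(im)) im else patchify(im, cfg$patch_size))
}

#' Fit a Vision Transformer classifier
#'
#' Minimizes cross-entropy with Adam over mini-batches. When a validation
#' set is available (via `val_patients` or `val_frac`), training stops early
#' once the validation loss has failed to improve for `patience` consecutive
#' epochs, and the best-validation parameters are kept. Fully deterministic
#' given `tcfg$seed`.
#'
#' @param x List of `feature_image` objects (or pre-computed patch
#'   matrices).
#' @param y Class labels (factor or vector); levels define the class order.
#' @param cfg A [vit_config]; `n_classes` must match the labels.
#' @param tcfg A [train_config].
#' @param patients Optional patient id per sample, used to carve a
#'   patient-wise validation split.
#' @param val_patients Optional character vector of patient ids reserved
#'   for validation (must not be used any other way).
#' @param val_frac When `val_patients` is missing: fraction of patients (or
#'   of samples, if `patients` is `NULL`) carved out for validation
#'   (default 0.1; 0 disables validation and early stopping).
#' @return An object of class `vit_model` with elements `params`, `config`,
#'   `train_config`, `classes`, `history` (per-epoch loss/accuracy) and
#'   `best_epoch`.
#' @export
vit_train <- function(x, y, cfg, tcfg = train_config(), patients = NULL,
                      val_patients = NULL, val_frac = 0.1) {
  stopifnot(inherits(cfg, "vit_config"), inherits(tcfg, "train_config"))
  y <- as.factor(y)
  classes <- levels(y)
  if (length(classes) != cfg$n_classes)
    stop("number of label levels does not match cfg$n_classes")
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) == 0L) stop("empty training split")
  set.seed(tcfg$seed)
  patch_list <- .as_patch_list(x, cfg)
  y_idx <- as.integer(y)

  n <- length(x)
  val_id <- rep(FALSE, n)
  if (!is.null(val_patients)) {
    if (is.null(patients)) stop("val_patients requires patients")
    val_id <- patients %in% val_patients
  } else if (val_frac > 0) {
    if (!is.null(patients)) {
      up <- unique(patients)
      vp <- sample(up, max(1L, ceiling(val_frac * length(up))))
      val_id <- patients %in% vp
    } else {
      val_id[sample(n, max(1L, ceiling(val_frac * n)))] <- TRUE
    }
  }
  tr <- which(!val_id); va <- which(val_id)
  if (length(tr) == 0L) stop("empty training split")

  w_sample <- NULL
  if (!is.null(tcfg$class_weights)) {
    cw <- if (identical(tcfg$class_weights, "balanced")) {
      tab <- table(factor(y[tr], levels = classes))
      as.numeric(length(tr) / (length(classes) * pmax(tab, 1)))
    } else as.numeric(tcfg$class_weights)
    w_sample <- cw[y_idx]
  }

  params <- vit_init(cfg, seed = tcfg$seed)
  theta <- unlist(.canonical_params(params), use.names = FALSE)
  skeleton <- .canonical_params(params)
  adam <- .adam_new(length(theta))

  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        train_acc = numeric(0), val_loss = numeric(0),
                        val_acc = numeric(0))
  best <- list(loss = Inf, theta = theta, epoch = 0L)
  stale <- 0L
  for (ep in seq_len(tcfg$epochs)) {
    ord <- sample(tr)
    ep_loss <- 0; ep_acc <- 0; n_seen <- 0
    for (b0 in seq(1, length(ord), by = tcfg$batch_size)) {
      bi <- ord[b0:min(b0 + tcfg$batch_size - 1L, length(ord))]
      params <- utils::relist(theta, skeleton)
      lg <- .vit_loss_grads(params, patch_list[bi], y_idx[bi], cfg,
                            training = TRUE, with_grads = TRUE,
                            sample_weights = w_sample[bi])
      g <- lg$grads
      gn <- sqrt(sum(g^2))
      if (is.finite(tcfg$clip_norm) && gn > tcfg$clip_norm)
        g <- g * (tcfg$clip_norm / gn)
      upd <- .adam_step(theta, g, adam, tcfg$learning_rate)
      theta <- upd$theta; adam <- upd$state
      ep_loss <- ep_loss + lg$loss * length(bi)
      ep_acc <- ep_acc + lg$acc * length(bi)
      n_seen <- n_seen + length(bi)
    }
    params <- utils::relist(theta, skeleton)
    row <- data.frame(epoch = ep, train_loss = ep_loss / n_seen,
                      train_acc = ep_acc / n_seen,
                      val_loss = NA_real_, val_acc = NA_real_)
    if (length(va) > 0L) {
      ev <- .vit_loss_grads(params, patch_list[va], y_idx[va], cfg,
                            with_grads = FALSE)
      row$val_loss <- ev$loss; row$val_acc <- ev$acc
      if (ev$loss < best$loss - 1e-6) {
        best <- list(loss = ev$loss, theta = theta, epoch = ep)
        stale <- 0L
      } else stale <- stale + 1L
    }
    history <- rbind(history, row)
    if (tcfg$verbose)
      message(sprintf("epoch %3d  loss %.4f  acc %.3f%s", ep,
                      row$train_loss, row$train_acc,
                      if (is.na(row$val_loss)) "" else
                        sprintf("  val %.4f/%.3f", row$val_loss,
                                row$val_acc)))
    if (length(va) > 0L && stale >= tcfg$patience) break
  }
  if (length(va) > 0L && is.finite(best$loss)) {
    theta <- best$theta
    params <- utils::relist(theta, skeleton)
  } else best$epoch <- nrow(history)

  structure(list(params = params, config = cfg, train_config = tcfg,
                 classes = classes, history = history,
                 best_epoch = best$epoch),
            class = "vit_model")
}

#' Predict classes or probabilities from a fitted Vision Transformer
#'
#' The predicted class is the probability argmax; ties break toward the
#' lower class index. Predictions are stateless and deterministic.
#'
#' @param object A `vit_model` from [vit_train()].
#' @param newdata A single image / patch matrix or a list of them.
#' @param type `"class"` (default) or `"prob"`.
#' @param ... Unused.
#' @return Factor of predicted labels, or a matrix of class probabilities.
#' @export
predict.vit_model <- function(object, newdata, type = c("class", "prob"),
                              ...) {
  type <- match.arg(type)
  if (!is.list(newdata) || inherits(newdata, "feature_image"))
    newdata <- list(newdata)
  cfg <- object$config
  probs <- t(vapply(newdata, function(im)
    vit_forward(im, object$params, cfg), numeric(cfg$n_classes)))
  colnames(probs) <- object$classes
  if (type == "prob") return(probs)
  factor(object$classes[apply(probs, 1, which.max)],
         levels = object$classes)
}

#' @export
print.vit_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<vit_model> %d-class ViT: %dpx/%dpx patches, d_model %d, %d layers, %d heads\n",
    cfg$n_classes, cfg$image_size, cfg$patch_size, cfg$d_model,
    cfg$n_layers, cfg$n_heads))
  cat(sprintf("  trained %d epoch(s); final train acc %.3f\n",
              nrow(x$history), x$history$train_acc[nrow(x$history)]))
  invisible(x)
}

#' @export
summary.vit_model <- function(object, ...) {
  n_par <- length(unlist(object$params, use.names = FALSE))
  cat(sprintf("Vision Transformer classifier (%d parameters)\n", n_par))
  print(object)
  h <- object$history
  if (any(!is.na(h$val_loss)))
    cat(sprintf("  best validation loss %.4f at epoch %d\n",
                min(h$val_loss, na.rm = TRUE), object$best_epoch))
  invisible(object)
}

#' @export
plot.vit_model <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "cross-entropy loss", ...)
  if (any(!is.na(h$val_loss)))
    graphics::lines(h$epoch, h$val_loss, lty = 2)
  invisible(x)
}
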