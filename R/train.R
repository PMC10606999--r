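#' Train a Siamese model with the contrastive loss
#'
#' Pairs are built from the train and validation splits with [build_pairs()],
#' and the network (shared backbone, dense embedding, sigmoid distance head)
#' is optimized with Adam. By default the loss's `Dw` is the sigmoid output
#' `d` itself; set `loss_input = "raw_distance"` in the config for the
#' conventional contrastive formulation on the embedding distance.
#'
#' Per epoch the history records mean train loss, mean validation loss and
#' validation pair accuracy (at the config threshold). The returned model
#' carries the weights of the epoch with the best validation accuracy, ties
#' broken toward the earlier epoch. Everything is seeded: identical data,
#' config and seed reproduce the run exactly.
#'
#' @param split A `dataset_split` from [stratified_split()].
#' @param cfg A [train_config()].
#' @param backbone A [backbone_spec()].
#' @return A `siamese_fit` list: `model` (trained [siamese_model()]) and
#'   `history` (data frame: epoch, train_loss, val_loss, val_accuracy).
#' @export
train_siamese <- function(split, cfg = train_config(),
                          backbone = backbone_spec()) {
  stopifnot(inherits(split, "dataset_split"), inherits(cfg, "train_config"))
  model <- siamese_model(backbone, seed = cfg$seed)
  if (cfg$epochs == 0L) {
    return(structure(list(model = model,
                          history = data.frame(epoch = integer(0),
                                               train_loss = numeric(0),
                                               val_loss = numeric(0),
                                               val_accuracy = numeric(0))),
                     class = "siamese_fit"))
  }
  train_pairs <- build_pairs(split$train, seed = cfg$seed)
  val_pairs <- if (length(split$val) >= 2L &&
                   length(unique(dataset_labels(split$val))) >= 2L) {
    build_pairs(split$val, seed = cfg$seed + 1L)
  } else NULL

  xs_train <- .preprocess_all(model, split$train)
  xs_val <- if (!is.null(val_pairs)) .preprocess_all(model, split$val) else NULL

  opt <- .adam_init(model$params)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), val_accuracy = numeric(0))
  best <- list(acc = -Inf, params = model$params)
  n_pairs <- nrow(train_pairs)
  for (ep in seq_len(cfg$epochs)) {
    ord <- .with_seed(cfg$seed + 1000L * ep, sample.int(n_pairs))
    ep_loss <- 0
    b0 <- 1L
    while (b0 <= n_pairs) {
      b1 <- min(b0 + cfg$batch_size - 1L, n_pairs)
      rows <- ord[b0:b1]
      acc_g <- NULL
      for (r in rows) {
        st <- .pair_step(model, xs_train[[train_pairs$id_a[r]]],
                         xs_train[[train_pairs$id_b[r]]],
                         train_pairs$label[r], cfg)
        if (!is.finite(st$loss)) {
          stop("training diverged: non-finite loss at epoch ", ep,
               " (pair ", train_pairs$id_a[r], " / ", train_pairs$id_b[r], ")")
        }
        ep_loss <- ep_loss + st$loss
        acc_g <- if (is.null(acc_g)) st$grads else
          Map(`+`, acc_g, st$grads[names(acc_g)])
      }
      nb <- length(rows)
      acc_g <- lapply(acc_g, function(g) g / nb)
      upd <- .adam_step(model$params, acc_g, opt, cfg$lr,
                        head_mult = cfg$head_lr_mult)
      model$params <- upd$params
      opt <- upd$opt
      b0 <- b1 + 1L
    }
    val <- .eval_pair_set(model, xs_val, val_pairs, cfg)
    history <- rbind(history, data.frame(epoch = ep,
                                         train_loss = ep_loss / n_pairs,
                                         val_loss = val$loss,
                                         val_accuracy = val$accuracy))
    if (!is.na(val$accuracy) && val$accuracy > best$acc) {
      best <- list(acc = val$accuracy, params = model$params)
    }
  }
  if (is.finite(best$acc)) model$params <- best$params
  model$trained <- TRUE
  structure(list(model = model, history = history), class = "siamese_fit")
}

#' @export
print.siamese_fit <- function(x, ...) {
  cat("siamese_fit:", nrow(x$history), "epochs\n")
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  final train loss %.4f, val loss %.4f, val accuracy %.3f\n",
                last$train_loss, last$val_loss, last$val_accuracy))
  }
  invisible(x)
}

.preprocess_all <- function(model, ds) {
  out <- lapply(ds$images, function(im) .preprocess_for_model(model, im))
  names(out) <- dataset_ids(ds)
  out
}

# One pair: forward both branches, loss, full reverse pass; returns loss and
# gradients for every parameter (shared weights accumulate both branches).
.pair_step <- function(model, xa, xb, y, cfg) {
  fa <- .forward_backbone(model, xa, keep = TRUE)
  fb <- .forward_backbone(model, xb, keep = TRUE)
  hc <- .head_forward(model, fa$emb, fb$emb)
  Dw <- if (cfg$loss_input == "output") hc$d else hc$raw
  loss <- contrastive_loss(Dw, y, cfg$margin)
  gDw <- .contrastive_grad(Dw, y, cfg$margin)
  hb <- if (cfg$loss_input == "output") {
    .head_backward(model, hc, dd = gDw)
  } else {
    .head_backward(model, hc, draw = gDw)
  }
  ba <- .backward_backbone(model, fa$caches, hb$dea, collect = TRUE)
  bb <- .backward_backbone(model, fb$caches, hb$deb, collect = TRUE)
  grads <- Map(`+`, ba$grads, bb$grads[names(ba$grads)])
  grads$head_w <- hb$dw
  grads$head_b <- hb$db
  list(loss = loss, grads = grads)
}

.eval_pair_set <- function(model, xs, pairs, cfg) {
  if (is.null(pairs) || nrow(pairs) == 0L) {
    return(list(loss = NA_real_, accuracy = NA_real_))
  }
  d <- numeric(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    ea <- .forward_backbone(model, xs[[pairs$id_a[r]]])$emb
    eb <- .forward_backbone(model, xs[[pairs$id_b[r]]])$emb
    hc <- .head_forward(model, ea, eb)
    d[r] <- hc$d
  }
  Dw <- if (cfg$loss_input == "output") d else NULL
  loss <- if (!is.null(Dw)) {
    mean(contrastive_loss(Dw, pairs$label, cfg$margin))
  } else NA_real_
  pred <- as.integer(d >= cfg$threshold)   # 1 = different
  list(loss = loss, accuracy = mean(pred == pairs$label), d = d)
}

.adam_init <- function(params) {
  zeros <- lapply(params, function(p) p * 0)
  list(m = zeros, v = zeros, t = 0L)
}

.adam_step <- function(params, grads, opt, lr, head_mult = 1,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    lri <- if (nm %in% c("head_w", "head_b")) head_mult * lr else lr
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    mhat <- opt$m[[nm]] / (1 - beta1^opt$t)
    vhat <- opt$v[[nm]] / (1 - beta2^opt$t)
    params[[nm]] <- params[[nm]] - lri * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, opt = opt)
}

#' Save / load a model checkpoint
#'
#' The checkpoint bundles the weights, the backbone description and the
#' training configuration, so a saved model scores and explains pairs
#' identically after reload.
#'
#' @param fit A `siamese_fit` or `siamese_model`.
#' @param path Checkpoint path (`.rds`).
#' @return `path` (save) or the restored object (load).
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, c("siamese_fit", "siamese_model")))
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  stopifnot(inherits(obj, c("siamese_fit", "siamese_model")))
  obj
}

#' Write training history as JSON lines
#'
#' One JSON object per epoch with keys epoch, train_loss, val_loss,
#' val_accuracy.
#'
#' @param history History data frame from [train_siamese()].
#' @param path Output path.
#' @export
write_history <- function(history, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in seq_len(nrow(history))) {
    writeLines(jsonlite::toJSON(as.list(history[r, ]), auto_unbox = TRUE,
                                digits = NA), con)
  }
  invisible(path)
}
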