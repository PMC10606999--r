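#' Describe a Siamese backbone architecture
#'
#' A backbone is a stack of convolutional blocks (3x3 convolution, ReLU,
#' 2x2 max-pool), followed by global average pooling and a ReLU dense layer
#' that produces the embedding. Two block styles are available:
#' `"small-cnn"` uses plain blocks; `"resnet50-style"` adds an identity skip
#' connection inside each block (conv, ReLU, conv, add, ReLU), the structural
#' signature of residual networks at a size that trains on one CPU.
#'
#' @param name Block style, `"small-cnn"` (default) or `"resnet50-style"`.
#' @param input_size Integer `(H, W)` the network consumes; each dimension
#'   must be divisible by `2^length(channels)`.
#' @param channels Integer vector of output channels per block
#'   (default `c(8, 16, 32)`).
#' @param embedding_dim Length of the embedding vector (default 256,
#'   ReLU-activated so embeddings are nonnegative).
#' @param target_layer Name of the convolutional block whose post-ReLU
#'   activations are explained by Grad-CAM (`"conv1"`, `"conv2"`, ...);
#'   defaults to the last block, i.e. the last convolutional layer.
#' @param head Distance head: `"scalar"` (default) feeds the Euclidean
#'   distance between embeddings through a one-neuron sigmoid unit, which is
#'   symmetric by construction; `"absdiff"` feeds the elementwise absolute
#'   difference vector through a dense sigmoid unit.
#' @return A `backbone_spec` object.
#' @export
backbone_spec <- function(name = c("small-cnn", "resnet50-style"),
                          input_size = c(64L, 64L),
                          channels = c(8L, 16L, 32L),
                          embedding_dim = 256L,
                          target_layer = NULL,
                          head = c("scalar", "absdiff")) {
  name <- match.arg(name)
  head <- match.arg(head)
  input_size <- as.integer(input_size)
  channels <- as.integer(channels)
  nb <- length(channels)
  stopifnot(length(input_size) == 2L, nb >= 1L, all(channels >= 1L))
  if (any(input_size %% (2L^nb) != 0L)) {
    stop("input_size must be divisible by 2^", nb, " for ", nb, " pooling stages")
  }
  if (is.null(target_layer)) target_layer <- paste0("conv", nb)
  if (!target_layer %in% paste0("conv", seq_len(nb))) {
    stop("target_layer '", target_layer, "' does not name a convolutional block")
  }
  structure(list(name = name, input_size = input_size, channels = channels,
                 embedding_dim = as.integer(embedding_dim),
                 target_layer = target_layer, head = head),
            class = "backbone_spec")
}

#' Training configuration for the Siamese model
#'
#' @param margin Contrastive-loss margin `m` (default 2).
#' @param threshold Decision threshold on the model output `d`; a pair with
#'   `d < threshold` is called same-class (default 0.5).
#' @param lr Adam learning rate.
#' @param epochs Number of passes over the training pairs.
#' @param batch_size Pairs per gradient step.
#' @param seed Seed controlling weight initialization, pair sampling and
#'   shuffling.
#' @param loss_input What the contrastive loss sees as `Dw`: `"output"`
#'   (default) uses the sigmoid output `d`; `"raw_distance"` uses the
#'   Euclidean distance between embeddings, the conventional contrastive
#'   formulation (the sigmoid head then keeps its initial calibration).
#' @param head_lr_mult Learning-rate multiplier for the two-parameter
#'   sigmoid head (default 10): the head is a cheap calibration layer whose
#'   scale lags the backbone if stepped at the backbone rate.
#' @return A `train_config` object.
#' @export
train_config <- function(margin = 2, threshold = 0.5, lr = 5e-3,
                         epochs = 10L, batch_size = 4L, seed = 42L,
                         loss_input = c("output", "raw_distance"),
                         head_lr_mult = 10) {
  loss_input <- match.arg(loss_input)
  stopifnot(margin > 0, threshold > 0, threshold < 1, lr > 0,
            epochs >= 0, batch_size >= 1, head_lr_mult > 0)
  structure(list(margin = margin, threshold = threshold, lr = lr,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 seed = as.integer(seed), loss_input = loss_input,
                 head_lr_mult = head_lr_mult),
            class = "train_config")
}

#' Initialize a Siamese model
#'
#' Builds the weight tensors (He-normal initialization, seeded) and the
#' precomputed layer geometry for the given backbone. Both branches share
#' these weights; there is only one copy.
#'
#' @param backbone A [backbone_spec()].
#' @param seed Seed for weight initialization.
#' @return A `siamese_model` object.
#' @export
siamese_model <- function(backbone = backbone_spec(), seed = 42L) {
  stopifnot(inherits(backbone, "backbone_spec"))
  nb <- length(backbone$channels)
  res <- backbone$name == "resnet50-style"
  geom <- vector("list", nb)
  params <- list()
  H <- backbone$input_size[1]
  W <- backbone$input_size[2]
  Cin <- 3L
  .with_seed(seed, {
    for (i in seq_len(nb)) {
      Cout <- backbone$channels[i]
      geom[[i]] <- list(conv = .conv_geom(H, W, Cin),
                        pool = .pool_geom(H, W, Cout),
                        Cin = Cin, Cout = Cout, H = H, W = W)
      if (res) geom[[i]]$convb <- .conv_geom(H, W, Cout)
      params[[paste0("conv", i, "_W")]] <-
        matrix(stats::rnorm(9L * Cin * Cout, sd = sqrt(2 / (9 * Cin))), 9L * Cin, Cout)
      params[[paste0("conv", i, "_b")]] <- numeric(Cout)
      if (res) {
        params[[paste0("conv", i, "b_W")]] <-
          matrix(stats::rnorm(9L * Cout * Cout, sd = sqrt(2 / (9 * Cout))), 9L * Cout, Cout)
        params[[paste0("conv", i, "b_b")]] <- numeric(Cout)
      }
      H <- H %/% 2L
      W <- W %/% 2L
      Cin <- Cout
    }
    Clast <- backbone$channels[nb]
    ed <- backbone$embedding_dim
    params$dense_W <- matrix(stats::rnorm(Clast * ed, sd = sqrt(2 / Clast)), Clast, ed)
    params$dense_b <- rep(0.01, ed)   # small positive bias guards against dead ReLU units
    # the head starts calibrated so that a zero-distance pair reads as
    # similar (d = sigmoid(-1) ~ 0.27) rather than undecided (0.5)
    if (backbone$head == "scalar") {
      params$head_w <- 1
      params$head_b <- -1
    } else {
      params$head_w <- stats::rnorm(ed, sd = sqrt(1 / ed))
      params$head_b <- -1
    }
  })
  structure(list(backbone = backbone, params = params, geom = geom,
                 n_blocks = nb, residual = res, trained = FALSE),
            class = "siamese_model")
}

#' @export
print.siamese_model <- function(x, ...) {
  cat("Siamese model (", x$backbone$name, ")\n", sep = "")
  cat("  input:", paste(x$backbone$input_size, collapse = "x"),
      " blocks:", paste(x$backbone$channels, collapse = "-"),
      " embedding:", x$backbone$embedding_dim, "\n")
  cat("  head:", x$backbone$head, " target layer:", x$backbone$target_layer,
      " trained:", x$trained, "\n")
  invisible(x)
}

# ---- forward / backward ----------------------------------------------------

# x: (H*W) x 3 matrix in [0,1]. Returns embedding and (optionally) all
# intermediate caches needed for the reverse pass.
.forward_backbone <- function(model, x, keep = FALSE) {
  p <- model$params
  blocks <- if (keep) vector("list", model$n_blocks) else NULL
  cur <- x
  for (i in seq_len(model$n_blocks)) {
    g <- model$geom[[i]]
    cv <- .conv_forward(cur, p[[paste0("conv", i, "_W")]],
                        p[[paste0("conv", i, "_b")]], g$conv)
    if (model$residual) {
      z <- pmax(cv$out, 0)
      cv2 <- .conv_forward(z, p[[paste0("conv", i, "b_W")]],
                           p[[paste0("conv", i, "b_b")]], g$convb)
      pre <- cv2$out + z
      act <- pmax(pre, 0)
      pl <- .maxpool_forward(act, g$pool)
      if (keep) {
        blocks[[i]] <- list(cols_a = cv$cols, pre1 = cv$out, z = z,
                            cols_b = cv2$cols, pre = pre, act = act, arg = pl$arg)
      }
    } else {
      act <- pmax(cv$out, 0)
      pl <- .maxpool_forward(act, g$pool)
      if (keep) {
        blocks[[i]] <- list(cols = cv$cols, pre = cv$out, act = act, arg = pl$arg)
      }
    }
    cur <- pl$out
  }
  gvec <- colMeans(cur)
  pre_d <- drop(gvec %*% p$dense_W) + p$dense_b
  emb <- pmax(pre_d, 0)
  list(emb = emb,
       caches = if (keep) list(blocks = blocks, gap_rows = nrow(cur),
                               gvec = gvec, pre_d = pre_d) else NULL)
}

# Resume the forward pass from the post-ReLU activations of block `block_i`
# (an (h*w) x K matrix); used by the finite-difference oracle and tests.
.forward_tail <- function(model, act, block_i) {
  p <- model$params
  cur <- .maxpool_forward(act, model$geom[[block_i]]$pool)$out
  if (block_i < model$n_blocks) {
    for (i in (block_i + 1L):model$n_blocks) {
      g <- model$geom[[i]]
      cv <- .conv_forward(cur, p[[paste0("conv", i, "_W")]],
                          p[[paste0("conv", i, "_b")]], g$conv)
      if (model$residual) {
        z <- pmax(cv$out, 0)
        cv2 <- .conv_forward(z, p[[paste0("conv", i, "b_W")]],
                             p[[paste0("conv", i, "b_b")]], g$convb)
        act_i <- pmax(cv2$out + z, 0)
      } else {
        act_i <- pmax(cv$out, 0)
      }
      cur <- .maxpool_forward(act_i, g$pool)$out
    }
  }
  gvec <- colMeans(cur)
  pmax(drop(gvec %*% p$dense_W) + p$dense_b, 0)
}

.head_forward <- function(model, ea, eb) {
  p <- model$params
  diff <- ea - eb
  raw <- sqrt(sum(diff^2))
  if (model$backbone$head == "scalar") {
    z <- p$head_w * raw + p$head_b
  } else {
    v <- abs(diff)
    z <- sum(v * p$head_w) + p$head_b
  }
  d <- .sigmoid(z)
  list(d = d, raw = raw, diff = diff, z = z)
}

# Reverse pass through the head. Exactly one of `dd` (gradient w.r.t. the
# sigmoid output) or `draw` (gradient w.r.t. the raw distance) is nonzero.
.head_backward <- function(model, hc, dd = 0, draw = 0) {
  p <- model$params
  dw <- 0
  db <- 0
  if (dd != 0) {
    dz <- dd * hc$d * (1 - hc$d)
    if (model$backbone$head == "scalar") {
      dw <- dz * hc$raw
      db <- dz
      draw <- draw + dz * p$head_w
    } else {
      v <- abs(hc$diff)
      dw <- dz * v
      db <- dz
      dv <- dz * p$head_w
      dea <- dv * sign(hc$diff)
      return(list(dea = dea, deb = -dea, dw = dw, db = db))
    }
  }
  if (model$backbone$head == "absdiff" && draw != 0) {
    stop("raw-distance loss gradients are defined for the scalar head only")
  }
  dea <- if (hc$raw > 1e-12) draw * hc$diff / hc$raw else numeric(length(hc$diff))
  list(dea = dea, deb = -dea, dw = dw, db = db)
}

# Reverse pass through one branch's backbone. `demb` is the gradient w.r.t.
# the embedding. Weight gradients are returned when `collect`; the gradient
# w.r.t. the post-ReLU activations of block `record_block` is returned when
# that argument is nonzero (this is what Grad-CAM consumes).
.backward_backbone <- function(model, caches, demb, collect = TRUE,
                               record_block = 0L) {
  p <- model$params
  grads <- if (collect) list() else NULL
  dpre_d <- demb * (caches$pre_d > 0)
  if (collect) {
    grads$dense_W <- outer(caches$gvec, dpre_d)
    grads$dense_b <- dpre_d
  }
  dg <- drop(p$dense_W %*% dpre_d)
  n_sp <- caches$gap_rows
  dpool <- matrix(dg / n_sp, n_sp, length(dg), byrow = TRUE)
  dact_rec <- NULL
  for (i in rev(seq_len(model$n_blocks))) {
    g <- model$geom[[i]]
    bc <- caches$blocks[[i]]
    dact <- .maxpool_backward(dpool, bc$arg, g$pool)
    if (record_block == i) {
      dact_rec <- dact
      if (!collect) break
    }
    dpre <- dact * (bc$pre > 0)
    if (model$residual) {
      cb <- .conv_backward(dpre, bc$cols_b, p[[paste0("conv", i, "b_W")]],
                           g$convb)
      dz <- cb$dx + dpre                      # skip connection
      dpre1 <- dz * (bc$pre1 > 0)
      ca <- .conv_backward(dpre1, bc$cols_a, p[[paste0("conv", i, "_W")]],
                           g$conv)
      if (collect) {
        grads[[paste0("conv", i, "b_W")]] <- cb$dW
        grads[[paste0("conv", i, "b_b")]] <- cb$db
        grads[[paste0("conv", i, "_W")]] <- ca$dW
        grads[[paste0("conv", i, "_b")]] <- ca$db
      }
      dpool <- ca$dx
    } else {
      ca <- .conv_backward(dpre, bc$cols, p[[paste0("conv", i, "_W")]],
                           g$conv)
      if (collect) {
        grads[[paste0("conv", i, "_W")]] <- ca$dW
        grads[[paste0("conv", i, "_b")]] <- ca$db
      }
      dpool <- ca$dx
    }
  }
  list(grads = grads, dact = dact_rec)
}

# ---- public operations -----------------------------------------------------

#' Embed an image
#'
#' Runs one branch of the Siamese network: convolutional blocks, global
#' average pooling, and the ReLU dense layer. Both branches share weights,
#' so identical inputs always embed identically.
#'
#' @param model A [siamese_model()].
#' @param pixels An `H x W x C` array with intensities in 0-255 (or a
#'   `labeled_image`). Preprocessing (rescale to `[0,1]`, bilinear resize to
#'   the backbone's input size, channel replication for grayscale) is applied.
#' @return Numeric embedding vector (all entries `>= 0`).
#' @export
embed <- function(model, pixels) {
  stopifnot(inherits(model, "siamese_model"))
  x <- .preprocess_for_model(model, pixels)
  .forward_backbone(model, x, keep = FALSE)$emb
}

.preprocess_for_model <- function(model, pixels) {
  if (inherits(pixels, "labeled_image")) pixels <- pixels$pixels
  arr <- preprocess_image(pixels, model$backbone$input_size)
  matrix(as.vector(arr), prod(model$backbone$input_size), 3L)
}

#' Score an image pair
#'
#' Embeds both images with the shared backbone, computes the Euclidean
#' distance between the embeddings, and maps it through the sigmoid output
#' unit. The output `d` is the model's dissimilarity score in (0,1);
#' similarity is `s = 1 - d`.
#'
#' @inheritParams embed
#' @param pixels_a,pixels_b The two images.
#' @return A `siamese_output` list with elements `d`, `s` and `raw_distance`.
#' @export
forward_pair <- function(model, pixels_a, pixels_b) {
  stopifnot(inherits(model, "siamese_model"))
  ea <- embed(model, pixels_a)
  eb <- embed(model, pixels_b)
  hc <- .head_forward(model, ea, eb)
  structure(list(d = hc$d, s = 1 - hc$d, raw_distance = hc$raw),
            class = "siamese_output")
}

#' Similarity score from the model output
#'
#' The similarity between two images is defined as `1 - d`, where `d` is the
#' Siamese model's output. A `d` of 0.24 therefore reads as 76% similarity.
#'
#' @param d Model output(s) in `[0, 1]`.
#' @return `1 - d`.
#' @export
similarity_score <- function(d) {
  if (!is.numeric(d) || any(!is.finite(d)) || any(d < 0 | d > 1)) {
    stop("d must be numeric in [0, 1]")
  }
  1 - d
}

#' Classify a pair as same- or different-class
#'
#' A pair is called `"same"` when the model output `d` is strictly less than
#' the threshold, otherwise `"different"`.
#'
#' @param d Model output(s).
#' @param threshold Decision threshold in (0,1).
#' @return Character vector of `"same"` / `"different"`.
#' @export
classify_pair <- function(d, threshold = 0.5) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold > 0, threshold < 1)
  ifelse(d < threshold, "same", "different")
}

#' Contrastive loss
#'
#' `L = 1/2 (1 - y) Dw^2 + y max(0, m - Dw)^2`, with the 1/2 factor on the
#' same-class term only. Same-class pairs (`y = 0`) are penalized for any
#' positive distance; different-class pairs (`y = 1`) are penalized only
#' while their distance falls short of the margin `m`.
#'
#' @param Dw Nonnegative distance (by default the model's sigmoid output;
#'   see [train_config()]'s `loss_input`).
#' @param y Pair label: 0 = same class, 1 = different class.
#' @param m Margin (default 2).
#' @return Loss value(s), always `>= 0`.
#' @export
contrastive_loss <- function(Dw, y, m = 2) {
  if (any(Dw < 0)) stop("Dw must be nonnegative")
  if (m <= 0) stop("margin m must be positive")
  if (!all(y %in% c(0, 1))) stop("y must be 0 or 1")
  0.5 * (1 - y) * Dw^2 + y * pmax(0, m - Dw)^2
}

# dL/dDw for the printed loss
.contrastive_grad <- function(Dw, y, m) {
  (1 - y) * Dw - 2 * y * pmax(0, m - Dw)
}
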