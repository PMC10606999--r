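# Shared fixtures. Everything is generated in code; nothing is read from
# disk except what a test itself writes to a tempdir.

# A deliberately small but "alive" network (nonzero embeddings and
# gradients for generic inputs): 8x8 input, three 2-channel blocks, so the
# explained layer has K = 2 maps of 2 x 2.
tiny_model <- function(seed = 2, ...) {
  siamese_model(backbone_spec(input_size = c(8, 8), channels = c(2, 2, 2),
                              embedding_dim = 8, ...),
                seed = seed)
}

rand_img <- function(seed, H = 8, W = H) {
  set.seed(seed)
  array(runif(H * W * 3) * 255, c(H, W, 3))
}

# quick-to-train synthetic fixture
small_shapes <- function(n_classes = 2, n_per_class = 10, seed = 11) {
  generate_shape_dataset(synthetic_spec(
    n_classes = n_classes, n_per_class = n_per_class,
    image_size = c(32, 32), shape_size_range = c(5, 7), seed = seed))
}

small_backbone <- function() {
  backbone_spec(input_size = c(32, 32), channels = c(8, 16, 16),
                embedding_dim = 64)
}

# Independent 8-connected component labeling: depth-first flood fill with an
# explicit stack, scanning pixels in row-major order (the package uses a
# vectorized breadth-first search in column-major order).
flood_fill_components <- function(mask) {
  H <- nrow(mask)
  W <- ncol(mask)
  lab <- matrix(0L, H, W)
  comp <- 0L
  for (y in seq_len(H)) {
    for (x in seq_len(W)) {
      if (!mask[y, x] || lab[y, x] != 0L) next
      comp <- comp + 1L
      stack <- list(c(y, x))
      lab[y, x] <- comp
      while (length(stack)) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (dy in -1:1) for (dx in -1:1) {
          ny <- p[1] + dy
          nx <- p[2] + dx
          if (ny < 1 || ny > H || nx < 1 || nx > W) next
          if (mask[ny, nx] && lab[ny, nx] == 0L) {
            lab[ny, nx] <- comp
            stack[[length(stack) + 1L]] <- c(ny, nx)
          }
        }
      }
    }
  }
  lab
}

# Brute-force pairwise-rank AUC (Mann-Whitney, ties count 1/2); positive
# class is "similar" (label 0), scored by s = 1 - d.
bruteforce_auc <- function(d, labels) {
  s <- 1 - d
  pos <- s[labels == 0]
  neg <- s[labels == 1]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# write a labeled_dataset of flat-colored images to a folder layout
write_color_folder <- function(root, spec) {
  # spec: named list class -> number of images
  for (cls in names(spec)) {
    dir.create(file.path(root, cls), recursive = TRUE, showWarnings = FALSE)
    for (k in seq_len(spec[[cls]])) {
      px <- array(runif(3), c(16, 16, 3))
      png::writePNG(px, file.path(root, cls, sprintf("img_%02d.png", k)))
    }
  }
  root
}
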