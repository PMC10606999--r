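#' Specification of a synthetic shapes-on-noise dataset
#'
#' Each class is a distinct colored shape (red disc, green square, blue
#' cross, yellow triangle, magenta ring, cyan diamond, orange bar) placed at
#' a random position on a noisy gray background. The shape is the only
#' class-correlated content, giving every image a known discriminative
#' region for localization and refinement tests.
#'
#' @param n_classes Number of classes (2-7).
#' @param n_per_class Images per class (>= 2).
#' @param image_size `(H, W)` in pixels.
#' @param shape_size_range Inclusive range of the shape's half-size radius
#'   in pixels; shapes always fit fully inside the image.
#' @param noise_level Background noise amplitude as a fraction of the 0-255
#'   range (uniform in `+/- noise_level * 255`); 0 gives a constant
#'   background.
#' @param seed Seed; generation is fully reproducible.
#' @return A `synthetic_spec`.
#' @export
synthetic_spec <- function(n_classes = 5L, n_per_class = 40L,
                           image_size = c(64L, 64L),
                           shape_size_range = c(7L, 11L),
                           noise_level = 0.1, seed = 42L) {
  n_classes <- as.integer(n_classes)
  n_per_class <- as.integer(n_per_class)
  image_size <- as.integer(image_size)
  shape_size_range <- as.integer(shape_size_range)
  stopifnot(n_classes >= 2L, n_per_class >= 2L,
            length(image_size) == 2L, all(image_size >= 16L),
            length(shape_size_range) == 2L,
            shape_size_range[1] >= 3L,
            shape_size_range[1] <= shape_size_range[2],
            noise_level >= 0, noise_level <= 1)
  if (2L * shape_size_range[2] + 2L >= min(image_size)) {
    stop("shapes do not fit inside the image")
  }
  structure(list(n_classes = n_classes, n_per_class = n_per_class,
                 image_size = image_size, shape_size_range = shape_size_range,
                 noise_level = noise_level, seed = as.integer(seed)),
            class = "synthetic_spec")
}

.shape_catalog <- function() {
  list(
    red_disc       = list(color = c(220, 40, 40),  shape = "disc"),
    green_square   = list(color = c(40, 200, 40),  shape = "square"),
    blue_cross     = list(color = c(50, 80, 230),  shape = "cross"),
    yellow_triangle = list(color = c(230, 210, 40), shape = "triangle"),
    magenta_ring   = list(color = c(220, 40, 220), shape = "ring"),
    cyan_diamond   = list(color = c(40, 210, 210), shape = "diamond"),
    orange_bar     = list(color = c(240, 140, 30), shape = "bar")
  )
}

# Boolean H x W mask of a shape of half-size r centred at (cy, cx)
.shape_mask <- function(shape, H, W, cy, cx, r) {
  y <- matrix(seq_len(H), H, W) - cy
  x <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  switch(shape,
    disc     = (y^2 + x^2) <= r^2,
    square   = abs(y) <= r & abs(x) <= r,
    cross    = (abs(y) <= ceiling(r / 3) & abs(x) <= r) |
               (abs(x) <= ceiling(r / 3) & abs(y) <= r),
    triangle = y >= -r & y <= r & abs(x) <= (y + r) / 2,
    ring     = {
      d2 <- y^2 + x^2
      d2 <= r^2 & d2 >= (0.55 * r)^2
    },
    diamond  = (abs(y) + abs(x)) <= r,
    bar      = abs(y) <= ceiling(r / 3) & abs(x) <= r,
    stop("unknown shape: ", shape)
  )
}

#' Generate a synthetic shape dataset with ground-truth masks
#'
#' Every image holds one class-defining shape on a noisy background; the
#' per-image boolean mask marks exactly the shape's pixels (one connected
#' component). Shape colors are saturated while the background is mid-gray,
#' so shape pixels differ from the background by far more than the noise
#' amplitude.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `dataset` (a [labeled_dataset()]) and `masks` (named
#'   list of `H x W` logical matrices keyed by image id).
#' @export
generate_shape_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  catalog <- .shape_catalog()
  if (spec$n_classes > length(catalog)) {
    stop("at most ", length(catalog), " shape/color classes are available")
  }
  H <- spec$image_size[1]
  W <- spec$image_size[2]
  bg <- 110
  images <- list()
  masks <- list()
  .with_seed(spec$seed, {
    for (ci in seq_len(spec$n_classes)) {
      cls <- names(catalog)[ci]
      def <- catalog[[ci]]
      for (k in seq_len(spec$n_per_class)) {
        r <- sample(spec$shape_size_range[1]:spec$shape_size_range[2], 1L)
        cy <- sample((r + 2L):(H - r - 1L), 1L)
        cx <- sample((r + 2L):(W - r - 1L), 1L)
        mask <- .shape_mask(def$shape, H, W, cy, cx, r)
        px <- array(bg, c(H, W, 3L))
        if (spec$noise_level > 0) {
          noise <- array(stats::runif(H * W * 3L, -1, 1) * spec$noise_level * 255,
                         c(H, W, 3L))
          px <- px + noise
        }
        for (ch in 1:3) {
          plane <- px[, , ch]
          plane[mask] <- def$color[ch]
          px[, , ch] <- plane
        }
        px <- round(px)          # integer intensities, exact PNG round-trip
        px[px < 0] <- 0
        px[px > 255] <- 255
        id <- sprintf("%s/%s_%03d.png", cls, cls, k)
        images[[id]] <- labeled_image(px, cls, id)
        masks[[id]] <- mask
      }
    }
  })
  list(dataset = labeled_dataset(unname(images),
                                 classes = names(catalog)[seq_len(spec$n_classes)]),
       masks = masks)
}

#' Write a synthetic dataset and its masks to disk
#'
#' Images go to `root` in the directory-per-class layout consumed by
#' [load_image_folder()]; masks are PNGs under `root/_masks/` with a
#' `mask_manifest.csv` mapping image ids to mask files.
#'
#' @param gen Output of [generate_shape_dataset()].
#' @param root Output directory.
#' @return `root`, invisibly.
#' @export
write_shape_dataset <- function(gen, root) {
  write_image_folder(gen$dataset, root)
  mdir <- file.path(root, "_masks")
  dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
  rows <- data.frame(image_id = character(0), mask_file = character(0))
  for (id in names(gen$masks)) {
    mf <- paste0(gsub("/", "_", id), ".mask.png")
    png::writePNG(gen$masks[[id]] * 1, file.path(mdir, mf))
    rows <- rbind(rows, data.frame(image_id = id, mask_file = mf))
  }
  utils::write.csv(rows, file.path(mdir, "mask_manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(root)
}
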