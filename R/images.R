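#' Construct a labeled image
#'
#' @param pixels `H x W x C` numeric array of intensities in 0-255
#'   (a plain `H x W` matrix is treated as single-channel). `H, W >= 8`,
#'   `C` 1 or 3.
#' @param class_label Class identifier (coerced to character).
#' @param image_id Unique identifier, typically the source path.
#' @return A `labeled_image`.
#' @export
labeled_image <- function(pixels, class_label, image_id) {
  if (is.matrix(pixels)) pixels <- array(pixels, c(dim(pixels), 1L))
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L)
  d <- dim(pixels)
  if (d[1] < 8L || d[2] < 8L) stop("image must be at least 8x8")
  if (!d[3] %in% c(1L, 3L)) stop("image must have 1 or 3 channels")
  if (any(pixels < 0) || any(pixels > 255)) stop("intensities must lie in 0-255")
  structure(list(pixels = pixels, class_label = as.character(class_label),
                 image_id = as.character(image_id)),
            class = "labeled_image")
}

#' Construct a labeled dataset
#'
#' @param images List of [labeled_image()] objects.
#' @param classes Optional ordered label set; defaults to the sorted unique
#'   labels present.
#' @return A `labeled_dataset`.
#' @export
labeled_dataset <- function(images, classes = NULL) {
  stopifnot(is.list(images), all(vapply(images, inherits, TRUE, "labeled_image")))
  labs <- vapply(images, function(im) im$class_label, character(1))
  ids <- vapply(images, function(im) im$image_id, character(1))
  if (anyDuplicated(ids)) stop("image_ids must be unique")
  if (is.null(classes)) classes <- sort(unique(labs))
  if (!all(labs %in% classes)) stop("every image label must be in `classes`")
  names(images) <- ids
  structure(list(images = images, classes = as.character(classes)),
            class = "labeled_dataset")
}

#' @export
length.labeled_dataset <- function(x) length(x$images)

#' @export
print.labeled_dataset <- function(x, ...) {
  labs <- dataset_labels(x)
  cat("labeled_dataset:", length(x), "images,", length(x$classes), "classes\n")
  print(table(factor(labs, levels = x$classes)))
  invisible(x)
}

#' Class label of every image in a dataset
#' @param ds A `labeled_dataset`.
#' @return Character vector, one label per image, in dataset order.
#' @export
dataset_labels <- function(ds) {
  vapply(ds$images, function(im) im$class_label, character(1), USE.NAMES = FALSE)
}

#' Image ids of a dataset
#' @param ds A `labeled_dataset`.
#' @return Character vector of ids in dataset order.
#' @export
dataset_ids <- function(ds) {
  vapply(ds$images, function(im) im$image_id, character(1), USE.NAMES = FALSE)
}

# ---- file I/O --------------------------------------------------------------

.read_image_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png  = png::readPNG(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format: ", ext)
  )
  if (is.matrix(arr)) arr <- array(arr, c(dim(arr), 1L))
  if (dim(arr)[3] == 4L) arr <- arr[, , 1:3, drop = FALSE]  # drop alpha
  if (dim(arr)[3] == 2L) arr <- arr[, , 1L, drop = FALSE]   # gray+alpha
  round(arr * 255)
}

.write_image_file <- function(pixels, path) {
  arr <- pixels / 255
  if (dim(arr)[3] == 1L) arr <- arr[, , 1L]
  png::writePNG(arr, path)
}

#' Load a directory-per-class image dataset
#'
#' Expects `root` to contain one subdirectory per class, each holding PNG or
#' JPEG files. Images become [labeled_image()]s labeled by their directory
#' name; ordering is lexicographic by path so repeated loads are identical.
#' Files that cannot be decoded are skipped with a warning.
#'
#' @param root Dataset root directory.
#' @return A [labeled_dataset()].
#' @export
load_image_folder <- function(root) {
  if (!dir.exists(root)) stop("dataset root not found: ", root)
  class_dirs <- sort(list.dirs(root, recursive = FALSE))
  # underscore/dot-prefixed directories (e.g. _masks) are auxiliary, not classes
  class_dirs <- class_dirs[!grepl("^[._]", basename(class_dirs))]
  class_dirs <- class_dirs[vapply(class_dirs, function(d)
    length(list.files(d)) > 0, logical(1))]
  if (length(class_dirs) < 2L) {
    stop("need at least 2 class directories under ", root)
  }
  images <- list()
  for (cd in class_dirs) {
    cls <- basename(cd)
    files <- sort(list.files(cd, pattern = "\\.(png|jpe?g)$",
                             ignore.case = TRUE, full.names = TRUE))
    for (f in files) {
      arr <- tryCatch(.read_image_file(f), error = function(e) {
        warning("skipping undecodable image ", f, ": ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
      if (is.null(arr)) next
      id <- file.path(cls, basename(f))
      images[[id]] <- labeled_image(arr, cls, id)
    }
  }
  if (length(images) == 0L) stop("no decodable images under ", root)
  labeled_dataset(unname(images), classes = basename(class_dirs))
}

#' Write a dataset in the directory-per-class layout
#'
#' Images are written as PNG under `root/<class>/<basename>.png`; the layout
#' round-trips through [load_image_folder()].
#'
#' @param ds A `labeled_dataset`.
#' @param root Output directory (created if missing).
#' @return `root`, invisibly.
#' @export
write_image_folder <- function(ds, root) {
  stopifnot(inherits(ds, "labeled_dataset"))
  for (im in ds$images) {
    dir <- file.path(root, im$class_label)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    base <- sub("\\.(png|jpe?g)$", "", basename(im$image_id), ignore.case = TRUE)
    .write_image_file(im$pixels, file.path(dir, paste0(base, ".png")))
  }
  invisible(root)
}

# ---- preprocessing ---------------------------------------------------------

#' Preprocess an image for the model
#'
#' Rescales intensities from 0-255 to `[0, 1]`, replicates a grayscale
#' channel to 3, and bilinearly resizes to `size` when needed.
#'
#' @param pixels `H x W x C` array of intensities in 0-255.
#' @param size Target `(H, W)`.
#' @return `H x W x 3` array in `[0, 1]`.
#' @export
preprocess_image <- function(pixels, size) {
  if (is.matrix(pixels)) pixels <- array(pixels, c(dim(pixels), 1L))
  arr <- pixels / 255
  if (dim(arr)[3] == 1L) arr <- array(rep(arr, 3L), c(dim(arr)[1:2], 3L))
  if (!identical(dim(arr)[1:2], as.integer(size))) {
    arr <- resize_bilinear(arr, size)
  }
  arr
}

#' Bilinear resize
#'
#' @param x An `H x W` matrix or `H x W x C` array.
#' @param size Target `(H, W)`.
#' @return Resized matrix or array of the same number of channels.
#' @export
resize_bilinear <- function(x, size) {
  size <- as.integer(size)
  was_matrix <- is.matrix(x)
  if (was_matrix) x <- array(x, c(dim(x), 1L))
  if (identical(dim(x)[1:2], size)) {
    return(if (was_matrix) x[, , 1L] else x)
  }
  # EBImage stores (x, y, c): transpose spatial dims on the way in and out
  img <- EBImage::Image(aperm(x, c(2L, 1L, 3L)), colormode = "Color")
  out <- EBImage::resize(img, w = size[2], h = size[1], filter = "bilinear")
  out <- aperm(EBImage::imageData(out), c(2L, 1L, 3L))
  if (was_matrix) out[, , 1L] else out
}
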