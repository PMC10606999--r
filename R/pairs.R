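#' Stratified train/validation/test split
#'
#' Test images are drawn per class so class proportions are preserved: each
#' class contributes round-half-up(`test_frac` * class size) test images,
#' at least 1 when the class has 2 or more images (classes with a single
#' image go entirely to train, with a warning). The validation set is sized
#' as round-half-up(`val_frac` * remaining train pool) overall and allocated
#' across classes by largest remainder, so every class stays represented
#' when the counts allow it.
#'
#' @param ds A [labeled_dataset()].
#' @param test_frac Fraction of each class held out for testing (0-1).
#' @param val_frac Fraction of the train pool moved to validation (0-1).
#' @param seed Seed; identical inputs and seed give an identical split.
#' @return A `dataset_split` list with `train`, `val`, `test` datasets.
#' @export
stratified_split <- function(ds, test_frac = 0.2, val_frac = 0.1, seed = 42L) {
  stopifnot(inherits(ds, "labeled_dataset"),
            test_frac > 0, test_frac < 1, val_frac >= 0, val_frac < 1)
  labs <- dataset_labels(ds)
  ids <- dataset_ids(ds)
  half_up <- function(x) floor(x + 0.5)
  test_ids <- character(0)
  train_pool <- list()   # per-class train ids after removing test
  .with_seed(seed, {
    for (cls in ds$classes) {
      cid <- ids[labs == cls]
      n <- length(cid)
      if (n == 0L) next
      if (n == 1L) {
        warning("class '", cls, "' has a single image; assigned to train",
                call. = FALSE)
        train_pool[[cls]] <- cid
        next
      }
      n_test <- min(n - 1L, max(1L, half_up(n * test_frac)))
      sel <- sample(cid, n_test)
      test_ids <- c(test_ids, sel)
      train_pool[[cls]] <- setdiff(cid, sel)
    }
    val_ids <- character(0)
    if (val_frac > 0) {
      sizes <- lengths(train_pool)
      n_val <- half_up(sum(sizes) * val_frac)
      if (n_val > 0) {
        # largest-remainder allocation across classes
        exact <- sizes * val_frac
        base <- pmin(floor(exact), pmax(sizes - 1L, 0L))
        left <- n_val - sum(base)
        if (left > 0) {
          ord <- order(exact - base, decreasing = TRUE)
          for (k in ord) {
            if (left == 0) break
            if (base[k] < sizes[k] - 1L) {
              base[k] <- base[k] + 1L
              left <- left - 1L
            }
          }
        }
        for (k in seq_along(train_pool)) {
          if (base[k] > 0) {
            sel <- sample(train_pool[[k]], base[k])
            val_ids <- c(val_ids, sel)
            train_pool[[k]] <- setdiff(train_pool[[k]], sel)
          }
        }
      }
    }
  })
  train_ids <- unlist(train_pool, use.names = FALSE)
  subset_ds <- function(keep) {
    labeled_dataset(unname(ds$images[ids %in% keep]),
                    classes = ds$classes)
  }
  empty_ds <- function() structure(list(images = list(), classes = ds$classes),
                                   class = "labeled_dataset")
  structure(list(train = subset_ds(train_ids),
                 val = if (length(val_ids)) subset_ds(val_ids) else empty_ds(),
                 test = subset_ds(test_ids)),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat("dataset_split: train", length(x$train),
      "/ val", length(x$val), "/ test", length(x$test), "\n")
  invisible(x)
}

#' Build labeled image pairs
#'
#' For each image (the anchor), two mates are drawn at random: one from the
#' same class (pair label 0) and one from a different class (pair label 1).
#' The same-class mate is drawn from the class excluding the anchor itself,
#' so no pair contains an image twice. Anchors whose class has a single
#' image skip their label-0 pair with a warning.
#'
#' @param ds A [labeled_dataset()] with at least 2 classes.
#' @param seed Seed; identical dataset and seed give an identical manifest.
#' @return A data frame with columns `id_a`, `id_b`, `label` (0 = same
#'   class, 1 = different class), two rows per anchor in dataset order.
#' @export
build_pairs <- function(ds, seed = 42L) {
  stopifnot(inherits(ds, "labeled_dataset"))
  labs <- dataset_labels(ds)
  ids <- dataset_ids(ds)
  if (length(unique(labs)) < 2L) stop("pair construction needs >= 2 classes")
  by_class <- split(ids, labs)
  id_a <- character(0); id_b <- character(0); label <- integer(0)
  .with_seed(seed, {
    for (i in seq_along(ids)) {
      anchor <- ids[i]
      same <- setdiff(by_class[[labs[i]]], anchor)
      if (length(same) == 0L) {
        warning("class '", labs[i], "' has a single image; ",
                "label-0 pair for ", anchor, " skipped", call. = FALSE)
      } else {
        mate <- if (length(same) == 1L) same else sample(same, 1L)
        id_a <- c(id_a, anchor); id_b <- c(id_b, mate); label <- c(label, 0L)
      }
      other <- ids[labs != labs[i]]
      mate <- if (length(other) == 1L) other else sample(other, 1L)
      id_a <- c(id_a, anchor); id_b <- c(id_b, mate); label <- c(label, 1L)
    }
  })
  data.frame(id_a = id_a, id_b = id_b, label = label,
             stringsAsFactors = FALSE)
}

#' Write / read a pair manifest
#'
#' CSV with header `id_a,id_b,label` — a stable, diff-able record of the
#' pairs used for training or evaluation.
#'
#' @param pairs Data frame from [build_pairs()].
#' @param path CSV path.
#' @return `path` (write) or the manifest data frame (read).
#' @export
write_pair_manifest <- function(pairs, path) {
  stopifnot(all(c("id_a", "id_b", "label") %in% names(pairs)))
  utils::write.csv(pairs[, c("id_a", "id_b", "label")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pair_manifest
#' @export
read_pair_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("id_a", "id_b", "label") %in% names(df)))
  df
}

#' Write a split manifest
#'
#' CSV with header `image_id,split` recording which split each image
#' landed in.
#'
#' @param split A `dataset_split`.
#' @param path CSV path.
#' @export
write_split_manifest <- function(split, path) {
  rows <- do.call(rbind, lapply(c("train", "val", "test"), function(s) {
    n <- length(split[[s]])
    if (n == 0L) return(NULL)
    data.frame(image_id = dataset_ids(split[[s]]), split = s,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
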