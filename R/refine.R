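#' Crop-refinement configuration
#'
#' @param similarity_gate An anchor is refined only when a same-class mate
#'   scores a similarity strictly above this value (default 0.80).
#' @param binarize_frac Heatmap binarization level as a fraction of the
#'   heatmap maximum (default 0.5).
#' @param max_mate_retries Distinct same-class mates tried before giving up
#'   on an anchor (default 5).
#' @param min_box_frac Boxes smaller than this fraction of the image area
#'   trigger the full-image fallback (default 0.01).
#' @return A `refinement_config`.
#' @export
refinement_config <- function(similarity_gate = 0.80, binarize_frac = 0.5,
                              max_mate_retries = 5L, min_box_frac = 0.01) {
  stopifnot(similarity_gate > 0, similarity_gate <= 1,
            binarize_frac > 0, binarize_frac <= 1,
            max_mate_retries >= 1, min_box_frac > 0, min_box_frac <= 1)
  structure(list(similarity_gate = similarity_gate,
                 binarize_frac = binarize_frac,
                 max_mate_retries = as.integer(max_mate_retries),
                 min_box_frac = min_box_frac),
            class = "refinement_config")
}

#' Find a confidently similar same-class mate
#'
#' Draws up to `cfg$max_mate_retries` distinct same-class mates (uniformly,
#' seeded) and returns the first whose predicted similarity `s = 1 - d`
#' strictly exceeds `cfg$similarity_gate`; `NULL` when none qualifies or
#' the anchor's class has no other image.
#'
#' @param model A trained [siamese_model()].
#' @param ds The dataset the anchor belongs to.
#' @param anchor A `labeled_image` (or its id in `ds`).
#' @param cfg A [refinement_config()].
#' @param seed Seed for mate drawing.
#' @return List with `mate` (a `labeled_image`) and `similarity`, or `NULL`.
#' @export
select_confident_mate <- function(model, ds, anchor, cfg = refinement_config(),
                                  seed = 42L) {
  stopifnot(inherits(ds, "labeled_dataset"))
  if (is.character(anchor)) anchor <- ds$images[[anchor]]
  stopifnot(inherits(anchor, "labeled_image"))
  ids <- dataset_ids(ds)
  labs <- dataset_labels(ds)
  cand <- ids[labs == anchor$class_label & ids != anchor$image_id]
  if (length(cand) == 0L) {
    message("anchor ", anchor$image_id, ": singleton class, no mate")
    return(NULL)
  }
  order_cand <- .with_seed(seed, sample(cand, min(length(cand),
                                                  cfg$max_mate_retries)))
  for (mid in order_cand) {
    out <- forward_pair(model, anchor, ds$images[[mid]])
    if (out$s > cfg$similarity_gate) {
      return(list(mate = ds$images[[mid]], similarity = out$s))
    }
  }
  NULL
}

# 8-connected component labeling of a logical matrix by breadth-first
# search; returns an integer matrix of component ids (0 = background).
.label_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  comp <- 0L
  offs <- cbind(dy = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
                dx = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    comp <- comp + 1L
    queue <- start
    lab[start] <- comp
    while (length(queue)) {
      cur <- queue
      queue <- integer(0)
      cy <- ((cur - 1L) %% H) + 1L
      cx <- ((cur - 1L) %/% H) + 1L
      for (o in 1:8) {
        ny <- cy + offs[o, 1L]
        nx <- cx + offs[o, 2L]
        ok <- ny >= 1L & ny <= H & nx >= 1L & nx <= W
        if (!any(ok)) next
        nidx <- ny[ok] + (nx[ok] - 1L) * H
        nidx <- unique(nidx[mask[nidx] & lab[nidx] == 0L])
        if (length(nidx)) {
          lab[nidx] <- comp
          queue <- c(queue, nidx)
        }
      }
    }
  }
  lab
}

#' Bounding box from a normalized heatmap
#'
#' Binarizes the heatmap at `binarize_frac` of its maximum, keeps the
#' largest 8-connected component, and returns its tight bounding box in
#' half-open pixel coordinates (origin top-left, `x` = column, `y` = row).
#' An all-zero heatmap, or a box smaller than `min_box_frac` of the image
#' area, falls back to the full image.
#'
#' @param h Normalized `H x W` heatmap (values in `[0, 1]`) or a
#'   `gradcam_heatmap`.
#' @param cfg A [refinement_config()].
#' @return A `bounding_box` list: `x_min`, `y_min`, `x_max`, `y_max`
#'   (half-open) and `fallback` flag.
#' @export
heatmap_to_bbox <- function(h, cfg = refinement_config()) {
  if (inherits(h, "gradcam_heatmap")) h <- h$values
  stopifnot(is.matrix(h))
  H <- nrow(h); W <- ncol(h)
  full <- structure(list(x_min = 0L, y_min = 0L, x_max = W, y_max = H,
                         fallback = TRUE), class = "bounding_box")
  mx <- max(h)
  if (mx <= 0) return(full)
  mask <- h >= cfg$binarize_frac * mx
  lab <- .label_components(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- lab == which.max(sizes)
  rows <- range(which(rowSums(keep) > 0))
  cols <- range(which(colSums(keep) > 0))
  box <- structure(list(x_min = cols[1] - 1L, y_min = rows[1] - 1L,
                        x_max = cols[2], y_max = rows[2], fallback = FALSE),
                   class = "bounding_box")
  area <- (box$x_max - box$x_min) * (box$y_max - box$y_min)
  if (area < cfg$min_box_frac * H * W) return(full)
  box
}

#' @export
print.bounding_box <- function(x, ...) {
  cat(sprintf("bounding_box [x %d:%d) [y %d:%d)%s\n", x$x_min, x$x_max,
              x$y_min, x$y_max, if (x$fallback) " (fallback)" else ""))
  invisible(x)
}

#' Crop an image to a bounding box
#'
#' @param pixels `H x W x C` array (or `labeled_image`).
#' @param box A `bounding_box`.
#' @return The cropped array.
#' @export
crop_to_bbox <- function(pixels, box) {
  if (inherits(pixels, "labeled_image")) pixels <- pixels$pixels
  stopifnot(inherits(box, "bounding_box"),
            box$x_max <= dim(pixels)[2], box$y_max <= dim(pixels)[1])
  pixels[(box$y_min + 1L):box$y_max, (box$x_min + 1L):box$x_max, ,
         drop = FALSE]
}

#' Heatmap-driven crop refinement of a training set
#'
#' For every anchor image with a confidently similar same-class mate
#' (similarity strictly above the gate), the anchor's factual Grad-CAM
#' heatmap — computed with the anchor as branch A of the anchor-mate pair —
#' is turned into a bounding box and the anchor is replaced by its crop.
#' Anchors without a confident mate are kept unchanged. Labels, ids and
#' dataset cardinality are preserved; only pixel content changes.
#'
#' @param model A trained [siamese_model()].
#' @param train_ds The training [labeled_dataset()].
#' @param cfg A [refinement_config()].
#' @param seed Seed for mate drawing.
#' @return A `refinement_result` list: `dataset` (the refined
#'   `labeled_dataset`) and `log` (one row per anchor: mate id, similarity,
#'   box coordinates, fallback and refined flags).
#' @export
refine_dataset <- function(model, train_ds, cfg = refinement_config(),
                           seed = 42L) {
  stopifnot(inherits(model, "siamese_model"),
            inherits(train_ds, "labeled_dataset"))
  ids <- dataset_ids(train_ds)
  out_images <- vector("list", length(ids))
  log <- data.frame(anchor = ids, mate = NA_character_,
                    similarity = NA_real_, x_min = NA_integer_,
                    y_min = NA_integer_, x_max = NA_integer_,
                    y_max = NA_integer_, fallback = NA,
                    refined = FALSE, stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    anchor <- train_ds$images[[i]]
    sel <- select_confident_mate(model, train_ds, anchor, cfg,
                                 seed = seed + i)
    if (is.null(sel)) {
      out_images[[i]] <- anchor
      next
    }
    hm <- explain_pair(model, anchor, sel$mate, mode = "factual")$a
    box <- heatmap_to_bbox(hm, cfg)
    cropped <- crop_to_bbox(anchor, box)
    out_images[[i]] <- labeled_image(.pad_min_size(cropped),
                                     anchor$class_label, anchor$image_id)
    log$mate[i] <- sel$mate$image_id
    log$similarity[i] <- sel$similarity
    log$x_min[i] <- box$x_min; log$y_min[i] <- box$y_min
    log$x_max[i] <- box$x_max; log$y_max[i] <- box$y_max
    log$fallback[i] <- box$fallback
    log$refined[i] <- TRUE
  }
  structure(list(dataset = labeled_dataset(out_images,
                                           classes = train_ds$classes),
                 log = log),
            class = "refinement_result")
}

# crops narrower than the 8-pixel image minimum are edge-padded
.pad_min_size <- function(px) {
  d <- dim(px)
  if (d[1] >= 8L && d[2] >= 8L) return(px)
  out <- array(0, c(max(d[1], 8L), max(d[2], 8L), d[3]))
  out[seq_len(d[1]), seq_len(d[2]), ] <- px
  if (d[1] < 8L) out[(d[1] + 1L):8L, , ] <- out[rep(d[1], 8L - d[1]), , ]
  if (d[2] < 8L) out[, (d[2] + 1L):8L, ] <- out[, rep(d[2], 8L - d[2]), ]
  out
}

#' Write a refinement log as JSON
#'
#' One record per anchor: mate id, similarity, bounding box, fallback and
#' refined flags.
#'
#' @param res A `refinement_result`.
#' @param path Output path.
#' @export
write_refinement_log <- function(res, path) {
  stopifnot(inherits(res, "refinement_result"))
  jsonlite::write_json(res$log, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
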