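#' Capture activations and gradients for a pair
#'
#' Runs one forward pass of the Siamese model on the pair and one reverse
#' pass of the chosen target scalar, reading off, for each branch, the
#' post-ReLU activation maps of the target convolutional layer and the
#' gradient of the target with respect to them. The factual target is the
#' model output `d`; the counterfactual target is `1 - d`, whose gradients
#' are exactly the negated factual gradients.
#'
#' @param model A [siamese_model()].
#' @param pixels_a,pixels_b The two images (0-255 arrays or `labeled_image`s).
#' @param mode `"factual"` or `"counterfactual"`.
#' @param target `"d"` (default) or `"s"`: which
#'   scalar the factual explanation differentiates. The two choices are each
#'   other's counterfactuals.
#' @param target_layer Convolutional block to explain; defaults to the
#'   backbone's configured layer (the last convolutional layer).
#' @return A `gradcam_capture` list: per branch (`a`, `b`) the `activations`
#'   and `gradients` as `h x w x K` arrays, plus `d`, `s`, `mode`, `layer`.
#' @export
gradcam_capture <- function(model, pixels_a, pixels_b,
                            mode = c("factual", "counterfactual"),
                            target = c("d", "s"), target_layer = NULL) {
  stopifnot(inherits(model, "siamese_model"))
  mode <- match.arg(mode)
  target <- match.arg(target)
  if (is.null(target_layer)) target_layer <- model$backbone$target_layer
  bi <- match(target_layer, paste0("conv", seq_len(model$n_blocks)))
  if (is.na(bi)) stop("target_layer '", target_layer, "' not found")

  xa <- .preprocess_for_model(model, pixels_a)
  xb <- .preprocess_for_model(model, pixels_b)
  fa <- .forward_backbone(model, xa, keep = TRUE)
  fb <- .forward_backbone(model, xb, keep = TRUE)
  hc <- .head_forward(model, fa$emb, fb$emb)
  # d(target)/dd: +1 for d, -1 for s = 1 - d; counterfactual flips the sign
  sgn <- if (target == "d") 1 else -1
  if (mode == "counterfactual") sgn <- -sgn
  hb <- .head_backward(model, hc, dd = sgn)
  g <- model$geom[[bi]]
  to_arr <- function(m) array(m, c(g$H, g$W, g$Cout))
  da <- .backward_backbone(model, fa$caches, hb$dea, collect = FALSE,
                           record_block = bi)$dact
  db <- .backward_backbone(model, fb$caches, hb$deb, collect = FALSE,
                           record_block = bi)$dact
  structure(list(
    a = list(activations = to_arr(fa$caches$blocks[[bi]]$act),
             gradients = to_arr(da), branch = "a"),
    b = list(activations = to_arr(fb$caches$blocks[[bi]]$act),
             gradients = to_arr(db), branch = "b"),
    d = hc$d, s = 1 - hc$d, mode = mode, layer = target_layer),
    class = "gradcam_capture")
}

#' Neuron importance weights
#'
#' Global-average-pools the gradient of the target scalar over the spatial
#' dimensions of each activation map: `alpha_k = (1/Z) sum_ij dy/dA_ijk`,
#' where `Z = h * w` is the number of spatial locations.
#'
#' @param grads `h x w x K` gradient array (or a branch entry from
#'   [gradcam_capture()]).
#' @return Numeric vector of `K` weights.
#' @export
neuron_importance <- function(grads) {
  if (is.list(grads)) grads <- grads$gradients
  stopifnot(is.array(grads), length(dim(grads)) == 3L)
  d <- dim(grads)
  colMeans(matrix(grads, d[1] * d[2], d[3]))
}

#' Raw Grad-CAM heatmap
#'
#' The ReLU of the alpha-weighted combination of forward activation maps:
#' `ReLU(sum_k alpha_k A_k)`. Entries are nonnegative by construction.
#'
#' @param alpha Importance weights from [neuron_importance()].
#' @param acts `h x w x K` activation array (or a branch entry from
#'   [gradcam_capture()]).
#' @return `h x w` matrix of nonnegative saliency values.
#' @export
gradcam_map <- function(alpha, acts) {
  if (is.list(acts)) acts <- acts$activations
  stopifnot(is.array(acts), length(dim(acts)) == 3L)
  d <- dim(acts)
  if (length(alpha) != d[3]) {
    stop("alpha has length ", length(alpha), " but activations have ",
         d[3], " maps")
  }
  comb <- matrix(acts, d[1] * d[2], d[3]) %*% alpha
  matrix(pmax(comb, 0), d[1], d[2])
}

#' Normalize and upsample a heatmap
#'
#' Min-max normalizes a nonnegative raw map to `[0, 1]` and bilinearly
#' upsamples it to image resolution. Degenerate maps are handled
#' explicitly: an all-zero map stays all-zero; a constant positive map
#' becomes all-ones (every location is maximally salient).
#'
#' @param raw `h x w` nonnegative matrix.
#' @param size Target `(H, W)`; `NULL` keeps the raw resolution.
#' @return Matrix in `[0, 1]` of the requested size.
#' @export
normalize_and_resize <- function(raw, size = NULL) {
  stopifnot(is.matrix(raw))
  if (any(raw < 0)) stop("raw heatmap must be nonnegative")
  mx <- max(raw)
  mn <- min(raw)
  if (mx <= 0) {
    out <- raw                       # all-zero passes through
  } else if (mx == mn) {
    out <- (raw > 0) * 1             # constant positive -> all ones
  } else {
    out <- (raw - mn) / (mx - mn)
  }
  if (!is.null(size) && !identical(dim(out), as.integer(size))) {
    out <- resize_bilinear(out, size)
    out[out < 0] <- 0
    out[out > 1] <- 1
  }
  out
}

#' Factual / counterfactual heatmaps for an image pair
#'
#' Composes [gradcam_capture()], [neuron_importance()], [gradcam_map()] and
#' [normalize_and_resize()] for both branches of the pair. Factual heatmaps
#' show where the model looked for its actual output; counterfactual
#' heatmaps (target `1 - y`) show the regions that would push the decision
#' the other way.
#'
#' @inheritParams gradcam_capture
#' @param size Output resolution `(H, W)`; defaults to each input image's
#'   own resolution.
#' @return List with elements `a` and `b`, each a `gradcam_heatmap`:
#'   `values` (normalized `H x W`), `raw` (`h x w`), `alpha`, `mode`,
#'   `branch`, `d`, `s`, `layer`.
#' @export
explain_pair <- function(model, pixels_a, pixels_b,
                         mode = c("factual", "counterfactual"),
                         target = c("d", "s"), target_layer = NULL,
                         size = NULL) {
  mode <- match.arg(mode)
  target <- match.arg(target)
  cap <- gradcam_capture(model, pixels_a, pixels_b, mode = mode,
                         target = target, target_layer = target_layer)
  px_dim <- function(p) {
    if (inherits(p, "labeled_image")) p <- p$pixels
    dim(p)[1:2]
  }
  one <- function(br, px) {
    alpha <- neuron_importance(cap[[br]]$gradients)
    raw <- gradcam_map(alpha, cap[[br]]$activations)
    sz <- if (is.null(size)) px_dim(px) else size
    structure(list(values = normalize_and_resize(raw, sz), raw = raw,
                   alpha = alpha, mode = mode, branch = br,
                   d = cap$d, s = cap$s, layer = cap$layer),
              class = "gradcam_heatmap")
  }
  list(a = one("a", pixels_a), b = one("b", pixels_b))
}

#' @export
print.gradcam_heatmap <- function(x, ...) {
  cat(sprintf("gradcam_heatmap (%s, branch %s): %dx%d, d = %.3f, s = %.3f, layer %s\n",
              x$mode, x$branch, nrow(x$values), ncol(x$values), x$d, x$s,
              x$layer))
  invisible(x)
}

.jet_colors <- function(v) {
  ramp <- grDevices::colorRamp(c("#000080", "#0000FF", "#00FFFF",
                                 "#FFFF00", "#FF0000"))
  ramp(pmin(pmax(v, 0), 1)) / 255
}

#' Overlay a heatmap on an image
#'
#' Colormaps the normalized heatmap (blue = cold to red = hot) and
#' alpha-blends it over the image:
#' `out = (1 - alpha) * image + alpha * colormap(heatmap)`.
#'
#' @param h A `gradcam_heatmap` or a normalized `H x W` matrix matching the
#'   image size.
#' @param pixels The image (`H x W x C`, 0-255).
#' @param alpha Blend weight in `[0, 1]`; 0 returns the image, 1 the
#'   colormapped heatmap.
#' @return `H x W x 3` array in `[0, 1]`, ready for [png::writePNG()].
#' @export
overlay_heatmap <- function(h, pixels, alpha = 0.5) {
  if (inherits(h, "gradcam_heatmap")) h <- h$values
  if (inherits(pixels, "labeled_image")) pixels <- pixels$pixels
  if (is.matrix(pixels)) pixels <- array(pixels, c(dim(pixels), 1L))
  stopifnot(alpha >= 0, alpha <= 1)
  if (!identical(dim(h), dim(pixels)[1:2])) {
    stop("heatmap size ", paste(dim(h), collapse = "x"),
         " does not match image size ", paste(dim(pixels)[1:2], collapse = "x"))
  }
  img <- pixels / 255
  if (dim(img)[3] == 1L) img <- array(rep(img, 3L), c(dim(img)[1:2], 3L))
  cm <- .jet_colors(as.vector(h))
  cmap <- array(cm, c(dim(h), 3L))
  (1 - alpha) * img + alpha * cmap
}

#' Write an explanation to disk
#'
#' Saves the overlay PNG, the grayscale heatmap PNG, and a sidecar JSON
#' recording pair ids, mode, branch, model scores and the explained layer.
#'
#' @param h A `gradcam_heatmap`.
#' @param pixels The explained image.
#' @param prefix Output path prefix; files `<prefix>_overlay.png`,
#'   `<prefix>_heatmap.png` and `<prefix>.json` are written.
#' @param id_a,id_b Pair image ids recorded in the sidecar.
#' @param alpha Overlay blend weight.
#' @return Invisibly, the sidecar path.
#' @export
write_explanation <- function(h, pixels, prefix, id_a = NA, id_b = NA,
                              alpha = 0.5) {
  stopifnot(inherits(h, "gradcam_heatmap"))
  ov <- overlay_heatmap(h, pixels, alpha)
  png::writePNG(ov, paste0(prefix, "_overlay.png"))
  png::writePNG(h$values, paste0(prefix, "_heatmap.png"))
  side <- list(id_a = id_a, id_b = id_b, mode = h$mode, branch = h$branch,
               d = h$d, s = h$s, layer = h$layer)
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(prefix, ".json"))
}
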