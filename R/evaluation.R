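#' Pair-verification metrics from scores and labels
#'
#' The positive class is "similar" (pair label 0). A pair is predicted
#' similar when `d < threshold`. Precision and recall are macro-averages
#' over the similar and dissimilar classes; the per-class values and the
#' confusion matrix are returned so any other convention can be
#' reconstructed. AUC uses the similarity `s = 1 - d` as the score for the
#' similar class and follows the Mann-Whitney convention: tied scores
#' contribute 1/2.
#'
#' @param d Model outputs, one per pair.
#' @param labels Pair labels (0 = same class / similar, 1 = different).
#' @param threshold Decision threshold on `d`.
#' @return A `pair_metrics` list: `accuracy`, `auc`, `precision`, `recall`
#'   (macro), `per_class` data frame, `confusion` matrix, `n_similar`,
#'   `n_dissimilar`, `threshold`.
#' @export
pair_metrics <- function(d, labels, threshold = 0.5) {
  stopifnot(length(d) == length(labels), length(d) > 0,
            all(labels %in% c(0, 1)))
  pred_sim <- d < threshold
  true_sim <- labels == 0
  tp <- sum(pred_sim & true_sim)
  fp <- sum(pred_sim & !true_sim)
  fn <- sum(!pred_sim & true_sim)
  tn <- sum(!pred_sim & !true_sim)
  confusion <- matrix(c(tp, fn, fp, tn), 2, 2,
                      dimnames = list(truth = c("similar", "dissimilar"),
                                      predicted = c("similar", "dissimilar")))
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  prec_sim <- safe_div(tp, tp + fp)
  rec_sim <- safe_div(tp, tp + fn)
  prec_dis <- safe_div(tn, tn + fn)
  rec_dis <- safe_div(tn, tn + fp)
  per_class <- data.frame(class = c("similar", "dissimilar"),
                          precision = c(prec_sim, prec_dis),
                          recall = c(rec_sim, rec_dis))
  n_pos <- sum(true_sim)
  n_neg <- sum(!true_sim)
  auc <- if (n_pos == 0 || n_neg == 0) {
    warning("AUC undefined: both pair labels must be present", call. = FALSE)
    NA_real_
  } else {
    s <- 1 - d
    r <- rank(s, ties.method = "average")
    (sum(r[true_sim]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  }
  structure(list(accuracy = (tp + tn) / length(d), auc = auc,
                 precision = mean(c(prec_sim, prec_dis)),
                 recall = mean(c(rec_sim, rec_dis)),
                 per_class = per_class, confusion = confusion,
                 n_similar = n_pos, n_dissimilar = n_neg,
                 threshold = threshold),
            class = "pair_metrics")
}

#' @export
print.pair_metrics <- function(x, ...) {
  cat(sprintf("pair_metrics on %d pairs (%d similar / %d dissimilar), threshold %.2f\n",
              x$n_similar + x$n_dissimilar, x$n_similar, x$n_dissimilar,
              x$threshold))
  cat(sprintf("  accuracy %.4f  AUC %.4f  macro precision %.4f  macro recall %.4f\n",
              x$accuracy, x$auc, x$precision, x$recall))
  invisible(x)
}

#' Score pairs with a model
#'
#' @param model A [siamese_model()].
#' @param ds The `labeled_dataset` the pair ids refer to.
#' @param pairs Pair manifest (`id_a`, `id_b`, `label`).
#' @param threshold Decision threshold.
#' @return Data frame: `id_a`, `id_b`, `label`, `d`, `s`, `prediction`.
#' @export
predict_pairs <- function(model, ds, pairs, threshold = 0.5) {
  stopifnot(inherits(model, "siamese_model"), inherits(ds, "labeled_dataset"),
            nrow(pairs) > 0)
  xs <- .preprocess_all(model, ds)
  missing <- setdiff(unique(c(pairs$id_a, pairs$id_b)), names(xs))
  if (length(missing)) {
    stop("pair manifest references ids absent from the dataset: ",
         paste(utils::head(missing, 3), collapse = ", "))
  }
  emb_cache <- new.env(parent = emptyenv())
  get_emb <- function(id) {
    if (is.null(emb_cache[[id]])) {
      emb_cache[[id]] <- .forward_backbone(model, xs[[id]])$emb
    }
    emb_cache[[id]]
  }
  d <- vapply(seq_len(nrow(pairs)), function(r) {
    .head_forward(model, get_emb(pairs$id_a[r]), get_emb(pairs$id_b[r]))$d
  }, numeric(1))
  data.frame(pairs[, c("id_a", "id_b", "label")], d = d, s = 1 - d,
             prediction = classify_pair(d, threshold),
             stringsAsFactors = FALSE)
}

#' Evaluate a model on a labeled pair set
#'
#' Scores every pair and computes verification metrics; see [pair_metrics()]
#' for the conventions used.
#'
#' @inheritParams predict_pairs
#' @return A `pair_metrics` object with the per-pair score table attached
#'   as attribute `"scores"`.
#' @export
evaluate_pairs <- function(model, ds, pairs, threshold = 0.5) {
  scored <- predict_pairs(model, ds, pairs, threshold)
  m <- pair_metrics(scored$d, scored$label, threshold)
  attr(m, "scores") <- scored
  m
}

#' Write metrics as JSON
#'
#' @param m A `pair_metrics`.
#' @param path Output path.
#' @export
write_metrics <- function(m, path) {
  stopifnot(inherits(m, "pair_metrics"))
  out <- list(accuracy = m$accuracy, auc = m$auc, precision = m$precision,
              recall = m$recall, threshold = m$threshold,
              n_similar = m$n_similar, n_dissimilar = m$n_dissimilar,
              per_class = m$per_class,
              confusion = as.data.frame(as.table(m$confusion)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
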