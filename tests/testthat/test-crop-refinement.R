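# a model whose output d is a constant regardless of the input pair:
# head_w = 0 collapses the sigmoid unit to its bias
constant_d_model <- function(d) {
  m <- tiny_model()
  m$params$head_w <- 0
  m$params$head_b <- stats::qlogis(d)
  m
}

test_that("heatmap_to_bbox boxes a single hot rectangle tightly", {
  h <- matrix(0, 64, 64)
  h[21:30, 31:40] <- 1   # rows 20-29, cols 30-39 zero-based
  box <- heatmap_to_bbox(h)
  expect_equal(box$x_min, 30)
  expect_equal(box$y_min, 20)
  expect_equal(box$x_max, 40)
  expect_equal(box$y_max, 30)
  expect_false(box$fallback)
})

test_that("an all-zero heatmap falls back to the full image", {
  box <- heatmap_to_bbox(matrix(0, 48, 40))
  expect_true(box$fallback)
  expect_equal(box$x_max, 40)
  expect_equal(box$y_max, 48)
  expect_equal(box$x_min, 0)
  expect_equal(box$y_min, 0)
})

test_that("the largest 8-connected component wins, per a flood-fill oracle", {
  h <- matrix(0, 32, 32)
  h[3:12, 3:7] <- 0.9    # 50 px blob
  h[20:23, 20:24] <- 1   # 20 px blob (hotter but smaller)
  box <- heatmap_to_bbox(h)
  lab <- flood_fill_components(h >= 0.5 * max(h))
  sizes <- table(lab[lab > 0])
  big <- as.integer(names(sizes)[which.max(sizes)])
  rows <- range(which(rowSums(lab == big) > 0))
  cols <- range(which(colSums(lab == big) > 0))
  expect_equal(c(box$y_min, box$y_max), c(rows[1] - 1, rows[2]))
  expect_equal(c(box$x_min, box$x_max), c(cols[1] - 1, cols[2]))
  expect_equal(box$y_max - box$y_min, 10)
  expect_equal(box$x_max - box$x_min, 5)
})

test_that("boxes stay in bounds and contain the selected component's peak", {
  set.seed(31)
  for (rep in 1:20) {
    h <- matrix(runif(40 * 30)^4, 40, 30)
    h <- h / max(h)
    box <- heatmap_to_bbox(h)
    expect_true(box$x_min >= 0 && box$x_max <= 30)
    expect_true(box$y_min >= 0 && box$y_max <= 40)
    expect_true(box$x_min < box$x_max && box$y_min < box$y_max)
    if (!box$fallback) {
      # the box is the tight bbox of some maximal-size suprathreshold
      # component and covers that component's hottest pixel
      lab <- flood_fill_components(h >= 0.5 * max(h))
      sizes <- table(lab[lab > 0])
      biggest <- as.integer(names(sizes)[sizes == max(sizes)])
      matched <- FALSE
      for (big in biggest) {
        rows <- range(which(rowSums(lab == big) > 0))
        cols <- range(which(colSums(lab == big) > 0))
        if (box$y_min == rows[1] - 1 && box$y_max == rows[2] &&
            box$x_min == cols[1] - 1 && box$x_max == cols[2]) {
          matched <- TRUE
          hsel <- ifelse(lab == big, h, -Inf)
          am <- which(hsel == max(hsel), arr.ind = TRUE)[1, ]
          expect_true(am["row"] > box$y_min && am["row"] <= box$y_max)
          expect_true(am["col"] > box$x_min && am["col"] <= box$x_max)
          break
        }
      }
      expect_true(matched)
    }
  }
})

test_that("tiny boxes trigger the min-area fallback", {
  h <- matrix(0, 64, 64)
  h[10, 10] <- 1   # single hot pixel: 1 px << 1% of 4096
  box <- heatmap_to_bbox(h, refinement_config(min_box_frac = 0.01))
  expect_true(box$fallback)
})

test_that("crop_to_bbox extracts the half-open rectangle", {
  px <- array(seq_len(16 * 16 * 3), c(16, 16, 3))
  box <- structure(list(x_min = 2L, y_min = 4L, x_max = 10L, y_max = 9L,
                        fallback = FALSE), class = "bounding_box")
  cr <- crop_to_bbox(px, box)
  expect_equal(dim(cr), c(5L, 8L, 3L))
  expect_equal(cr[1, 1, 1], px[5, 3, 1])
})

test_that("mate selection honours the strict similarity gate", {
  gen <- small_shapes(n_classes = 2, n_per_class = 4, seed = 41)
  ds <- gen$dataset
  anchor <- ds$images[[1]]
  always <- constant_d_model(0.1)    # s = 0.9 > 0.8 for every pair
  sel <- select_confident_mate(always, ds, anchor, seed = 1)
  expect_false(is.null(sel))
  expect_equal(sel$similarity, 0.9)
  expect_equal(ds$images[[sel$mate$image_id]]$class_label, anchor$class_label)
  expect_false(sel$mate$image_id == anchor$image_id)

  never <- constant_d_model(0.9)     # s = 0.1
  expect_null(select_confident_mate(never, ds, anchor, seed = 1))

  boundary <- constant_d_model(0.2)  # s = 0.8 exactly: strict > rejects
  expect_null(select_confident_mate(boundary, ds, anchor, seed = 1))
})

test_that("refinement without confident mates is the identity", {
  gen <- small_shapes(n_classes = 2, n_per_class = 3, seed = 43)
  never <- constant_d_model(0.9)
  res <- refine_dataset(never, gen$dataset, seed = 5)
  expect_length(res$dataset, length(gen$dataset))
  expect_false(any(res$log$refined))
  id <- dataset_ids(gen$dataset)[2]
  expect_identical(res$dataset$images[[id]]$pixels,
                   gen$dataset$images[[id]]$pixels)
})

test_that("an oracle heatmap crops every image to its shape's bounding box", {
  gen <- small_shapes(n_classes = 2, n_per_class = 3, seed = 47)
  masks <- gen$masks
  always <- constant_d_model(0.1)
  local_mocked_bindings(
    explain_pair = function(model, pixels_a, pixels_b, mode = "factual",
                            target = "d", target_layer = NULL, size = NULL) {
      id <- pixels_a$image_id
      list(a = structure(list(values = masks[[id]] * 1,
                              raw = masks[[id]] * 1, mode = "factual",
                              branch = "a", d = 0.1, s = 0.9,
                              layer = "conv3"),
                         class = "gradcam_heatmap"))
    },
    .package = "simexplain"
  )
  res <- refine_dataset(always, gen$dataset, seed = 9)
  expect_true(all(res$log$refined))
  for (i in seq_along(res$dataset$images)) {
    id <- dataset_ids(gen$dataset)[i]
    mask <- masks[[id]]
    rows <- range(which(rowSums(mask) > 0))
    cols <- range(which(colSums(mask) > 0))
    expect_equal(dim(res$dataset$images[[id]]$pixels)[1:2],
                 c(max(diff(rows) + 1, 8), max(diff(cols) + 1, 8)))
    expect_equal(res$log$y_min[i], rows[1] - 1)
    expect_equal(res$log$x_max[i], cols[2])
  }
})

test_that("refinement preserves cardinality, ids and labels", {
  gen <- small_shapes(n_classes = 2, n_per_class = 3, seed = 53)
  always <- constant_d_model(0.1)
  res <- refine_dataset(always, gen$dataset, seed = 3)
  expect_length(res$dataset, length(gen$dataset))
  expect_identical(dataset_ids(res$dataset), dataset_ids(gen$dataset))
  expect_identical(dataset_labels(res$dataset), dataset_labels(gen$dataset))
  expect_equal(nrow(res$log), length(gen$dataset))
  path <- withr::local_tempfile(fileext = ".json")
  write_refinement_log(res, path)
  js <- jsonlite::read_json(path)
  expect_length(js, length(gen$dataset))
})
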