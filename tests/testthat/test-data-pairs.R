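test_that("load_image_folder labels images by directory and orders deterministically", {
  root <- withr::local_tempdir()
  set.seed(1)
  write_color_folder(root, list(rose = 2, tulip = 3))
  ds <- load_image_folder(root)
  expect_s3_class(ds, "labeled_dataset")
  expect_length(ds, 5)
  expect_equal(ds$classes, c("rose", "tulip"))
  expect_equal(table(dataset_labels(ds))[["rose"]], 2)
  ds2 <- load_image_folder(root)
  expect_identical(dataset_ids(ds), dataset_ids(ds2))
  expect_identical(dataset_labels(ds), dataset_labels(ds2))
})

test_that("load_image_folder rejects single-class roots and skips undecodable files", {
  root <- withr::local_tempdir()
  set.seed(2)
  write_color_folder(root, list(only = 3))
  expect_error(load_image_folder(root), "2 class")

  root2 <- withr::local_tempdir()
  write_color_folder(root2, list(a = 2, b = 2))
  writeLines("not a png", file.path(root2, "a", "broken.png"))
  expect_warning(ds <- load_image_folder(root2), "undecodable")
  expect_length(ds, 4)
})

test_that("stratified_split keeps per-class test proportions and is seeded", {
  gen <- small_shapes(n_classes = 2, n_per_class = 5, seed = 3)
  ds <- gen$dataset
  sp <- stratified_split(ds, test_frac = 0.2, val_frac = 0, seed = 1)
  expect_length(sp$train, 8)
  expect_length(sp$val, 0)
  expect_length(sp$test, 2)
  expect_setequal(unique(dataset_labels(sp$test)), ds$classes)
  sp2 <- stratified_split(ds, test_frac = 0.2, val_frac = 0, seed = 1)
  expect_identical(dataset_ids(sp$test), dataset_ids(sp2$test))
  expect_identical(dataset_ids(sp$train), dataset_ids(sp2$train))
})

test_that("split sizes follow round-half-up test counts and a global val total", {
  # 5 classes x 20 images, test 0.2, val 0.1:
  # per class round-half-up(20 * 0.2) = 4 test -> 20 test, 80 remain;
  # val total = round-half-up(80 * 0.1) = 8 by largest remainder -> 72 train
  gen <- small_shapes(n_classes = 5, n_per_class = 20, seed = 4)
  sp <- stratified_split(gen$dataset, test_frac = 0.2, val_frac = 0.1, seed = 9)
  expect_length(sp$train, 72)
  expect_length(sp$val, 8)
  expect_length(sp$test, 20)
  # every class still represented in train and test
  expect_setequal(unique(dataset_labels(sp$test)), gen$dataset$classes)
  expect_setequal(unique(dataset_labels(sp$train)), gen$dataset$classes)
})

test_that("splits are disjoint and union to the input dataset", {
  for (seed in 1:3) {
    gen <- small_shapes(n_classes = 3, n_per_class = 7, seed = seed)
    sp <- stratified_split(gen$dataset, test_frac = 0.25, val_frac = 0.15,
                           seed = seed)
    ids <- list(dataset_ids(sp$train), dataset_ids(sp$val),
                dataset_ids(sp$test))
    expect_length(intersect(ids[[1]], ids[[2]]), 0)
    expect_length(intersect(ids[[1]], ids[[3]]), 0)
    expect_length(intersect(ids[[2]], ids[[3]]), 0)
    expect_setequal(unlist(ids), dataset_ids(gen$dataset))
  }
})

test_that("a singleton class goes to train with a warning", {
  gen <- small_shapes(n_classes = 2, n_per_class = 3, seed = 5)
  ds <- gen$dataset
  keep <- dataset_ids(ds)[-c(2, 3)]   # reduce class 1 to a single image
  ds1 <- labeled_dataset(unname(ds$images[keep]), classes = ds$classes)
  expect_warning(sp <- stratified_split(ds1, 0.3, 0, seed = 1), "single image")
  singleton <- dataset_ids(ds)[1]
  expect_true(singleton %in% dataset_ids(sp$train))
})

test_that("build_pairs emits two pairs per anchor with consistent labels", {
  gen <- small_shapes(n_classes = 2, n_per_class = 2, seed = 6)
  pairs <- build_pairs(gen$dataset, seed = 1)
  expect_equal(nrow(pairs), 8)
  expect_equal(sum(pairs$label == 0), 4)
  expect_equal(sum(pairs$label == 1), 4)
  pairs2 <- build_pairs(gen$dataset, seed = 1)
  expect_identical(pairs, pairs2)
})

test_that("build_pairs respects class structure on unbalanced datasets", {
  gen <- small_shapes(n_classes = 2, n_per_class = 3, seed = 7)
  ds <- gen$dataset
  ds5 <- labeled_dataset(unname(ds$images[-2]), classes = ds$classes)  # sizes 2, 3
  pairs <- build_pairs(ds5, seed = 3)
  expect_equal(nrow(pairs), 10)
  labs <- setNames(dataset_labels(ds5), dataset_ids(ds5))
  for (r in seq_len(nrow(pairs))) {
    same <- labs[[pairs$id_a[r]]] == labs[[pairs$id_b[r]]]
    expect_identical(pairs$label[r] == 0L, same)
    expect_false(pairs$id_a[r] == pairs$id_b[r])
  }
})

test_that("pair labels are balanced and self-pair-free across random datasets", {
  for (seed in 1:3) {
    gen <- small_shapes(n_classes = 3, n_per_class = 4, seed = seed)
    pairs <- build_pairs(gen$dataset, seed = seed + 50)
    expect_equal(nrow(pairs), 2 * length(gen$dataset))
    expect_equal(sum(pairs$label == 0), sum(pairs$label == 1))
    expect_true(all(pairs$id_a != pairs$id_b))
  }
})

test_that("single-class datasets are rejected and singleton classes skip label-0 pairs", {
  gen <- small_shapes(n_classes = 2, n_per_class = 3, seed = 8)
  ds <- gen$dataset
  one_class <- labeled_dataset(unname(ds$images[dataset_labels(ds) == ds$classes[1]]),
                               classes = ds$classes[1])
  expect_error(build_pairs(one_class, seed = 1), ">= 2 classes")

  keep <- c(dataset_ids(ds)[1], dataset_ids(ds)[dataset_labels(ds) == ds$classes[2]])
  ds_singleton <- labeled_dataset(unname(ds$images[keep]), classes = ds$classes)
  expect_warning(pairs <- build_pairs(ds_singleton, seed = 1), "skipped")
  anchor1 <- dataset_ids(ds_singleton)[1]
  expect_equal(sum(pairs$id_a == anchor1 & pairs$label == 0), 0)
  expect_equal(sum(pairs$id_a == anchor1 & pairs$label == 1), 1)
})

test_that("pair and split manifests serialize deterministically and round-trip", {
  gen <- small_shapes(n_classes = 2, n_per_class = 5, seed = 9)
  sp <- stratified_split(gen$dataset, 0.2, 0.2, seed = 2)
  pairs <- build_pairs(sp$train, seed = 2)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_pair_manifest(pairs, f1)
  write_pair_manifest(build_pairs(sp$train, seed = 2), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  back <- read_pair_manifest(f1)
  expect_equal(back$id_a, pairs$id_a)
  expect_equal(back$label, pairs$label)
  fs <- withr::local_tempfile(fileext = ".csv")
  write_split_manifest(sp, fs)
  man <- utils::read.csv(fs)
  expect_setequal(man$image_id, dataset_ids(gen$dataset))
})
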