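test_that("class-per-folder loading returns sorted, labelled records", {
  root <- withr::local_tempdir()
  spec <- synthetic_dataset_spec(scale = 0.003, seed = 7, image_size = 32)
  written <- generate_dataset(spec, root)
  recs <- load_image_folder(root)
  expect_length(recs, length(written))
  ids <- vapply(recs, `[[`, "", "sample_id")
  expect_identical(ids, sort(ids))
  expect_setequal(unique(vapply(recs, `[[`, "", "label")),
                  vapply(spec$class_specs, `[[`, "", "name"))
  # loaded pixel data round-trips the written PNGs exactly
  expect_identical(recs[[1]]$image, written[[which(vapply(written, `[[`, "", "sample_id") == ids[1])]]$image)
  expect_true(all(vapply(recs, function(r) all(r$image >= 0 & r$image <= 255), TRUE)))
})

test_that("corrupt files are skipped with a warning and fatal cases stop", {
  root <- withr::local_tempdir()
  generate_dataset(synthetic_dataset_spec(scale = 0.003, seed = 1, image_size = 24), root)
  writeLines("not a png", file.path(root, "Bacteria", "broken.png"))
  expect_warning(recs <- load_image_folder(root), "broken.png")
  expect_false(any(grepl("broken", vapply(recs, `[[`, "", "sample_id"))))
  expect_error(load_image_folder(file.path(root, "no_such_dir")), "does not exist")
  empty <- withr::local_tempdir()
  expect_error(load_image_folder(empty), "no class subdirectories")
})

test_that("RGB images are reduced by the luminance weights", {
  root <- withr::local_tempdir()
  dir.create(file.path(root, "c1"))
  arr <- array(0, c(10, 10, 3))
  arr[, , 1] <- 1; arr[, , 2] <- 0.5; arr[, , 3] <- 0.25
  png::writePNG(arr, file.path(root, "c1", "rgb.png"))
  rec <- load_image_folder(root)[[1]]
  # channels quantize to 255/128/64 on write; luminance of those exact levels
  expect_equal(unique(as.vector(rec$image)),
               as.integer(round(0.299 * 255 + 0.587 * 128 + 0.114 * 64)))
  rec2 <- load_image_folder(root, color_policy = "first_channel")[[1]]
  expect_equal(unique(as.vector(rec2$image)), 255L)
})

fake_records <- function(counts, classes = names(counts)) {
  recs <- list()
  for (i in seq_along(counts)) {
    for (j in seq_len(counts[i])) {
      recs[[length(recs) + 1L]] <- list(label = classes[i],
                                        sample_id = sprintf("%s/%04d", classes[i], j))
    }
  }
  recs
}

test_that("stratified split is exact on divisible inputs and deterministic", {
  recs <- fake_records(c(a = 50, b = 50))
  sp <- stratified_split(recs, 0.8, seed = 42)
  expect_length(sp$train_ids, 80)
  expect_length(sp$test_ids, 20)
  lab <- function(ids) sub("/.*", "", ids)
  expect_equal(unname(table(lab(sp$train_ids))), array(c(40L, 40L)))
  expect_identical(sp, stratified_split(recs, 0.8, seed = 42))
  expect_false(identical(sp$train_ids, stratified_split(recs, 0.8, seed = 43)$train_ids))
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  expect_setequal(c(sp$train_ids, sp$test_ids), vapply(recs, `[[`, "", "sample_id"))
})

test_that("per-class train counts follow round-half-up within one sample", {
  set.seed(9)
  for (trial in 1:5) {
    counts <- sample(3:40, 4)
    names(counts) <- paste0("k", 1:4)
    frac <- runif(1, 0.5, 0.9)
    sp <- stratified_split(fake_records(counts), frac, seed = trial)
    tr <- table(sub("/.*", "", sp$train_ids))
    for (cl in names(counts)) {
      expect_lte(abs(tr[cl] - round(frac * counts[cl])), 1)
      expect_equal(as.integer(tr[cl]), as.integer(floor(frac * counts[cl] + 0.5)))
    }
  }
  expect_error(stratified_split(fake_records(c(a = 1, b = 5)), 0.8, 1), "a")
})

test_that("the imbalanced 8-class composition splits to near one-fifth test", {
  counts <- c(Bacteria = 1224, Crystal = 1842, Cylinder = 240, Epithelial = 432,
              Erythrocyte = 2279, Leukocyte = 1734, Yeast = 688, Others = 70)
  sp <- stratified_split(fake_records(counts), 0.8, seed = 0)
  expect_equal(length(sp$train_ids) + length(sp$test_ids), 8509)
  # per-class round-half-up leaves 1702 test images, within rounding of 20%
  expect_equal(length(sp$test_ids), 1702)
  expect_lt(abs(length(sp$test_ids) / 8509 - 0.2), 0.005)
})

test_that("split manifests round-trip through JSON", {
  sp <- stratified_split(fake_records(c(a = 10, b = 14)), 0.75, seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_split(sp, path)
  sp2 <- read_split(path)
  expect_identical(sp2$train_ids, sp$train_ids)
  expect_identical(sp2$test_ids, sp$test_ids)
  expect_identical(sp2$seed, sp$seed)
})
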