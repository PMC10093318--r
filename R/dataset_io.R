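#' Load a class-per-folder image dataset
#'
#' Each immediate subdirectory of `root` is a class; every PNG/JPEG/TIFF file
#' inside becomes one record. Colour images are reduced to a single channel
#' either by the ITU-R BT.601 luminance weights (0.299 R + 0.587 G + 0.114 B,
#' rounded to the nearest integer) or by taking the first channel. Records are
#' sorted by their relative path so downstream seeded operations do not depend
#' on filesystem enumeration order.
#'
#' @param root dataset directory (`root/<class>/<file>`).
#' @param color_policy `"luminance"` (default) or `"first_channel"`.
#' @return List of records, each `list(image, label, sample_id)` where `image`
#'   is an integer matrix of 0-255 intensities. Unreadable files are skipped
#'   with a warning.
#' @export
load_image_folder <- function(root, color_policy = c("luminance", "first_channel")) {
  color_policy <- match.arg(color_policy)
  if (!dir.exists(root)) stop("dataset root does not exist: ", root)
  classes <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  if (length(classes) == 0) stop("no class subdirectories under ", root)
  records <- list()
  for (cls in classes) {
    files <- sort(list.files(file.path(root, cls),
                             pattern = "\\.(png|jpe?g|tiff?)$",
                             ignore.case = TRUE))
    for (f in files) {
      rel <- file.path(cls, f)
      img <- tryCatch(read_gray_image(file.path(root, rel), color_policy),
                      error = function(e) {
                        warning("skipping unreadable image ", rel, ": ",
                                conditionMessage(e), call. = FALSE)
                        NULL
                      })
      if (!is.null(img)) {
        records[[length(records) + 1L]] <- list(image = img, label = cls, sample_id = rel)
      }
    }
  }
  if (length(records) == 0) stop("no readable images under ", root)
  records[order(vapply(records, `[[`, "", "sample_id"))]
}

# Read one image file as an integer 0-255 grayscale matrix (rows = y).
read_gray_image <- function(path, color_policy = "luminance") {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 3) {
    if (color_policy == "luminance" && dim(a)[3] >= 3) {
      a <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
    } else {
      a <- a[, , 1]
    }
  }
  # EBImage stores x,y; transpose to the row = y raster convention
  m <- t(a)
  m <- round(m * 255)
  storage.mode(m) <- "integer"
  pmin(pmax(m, 0L), 255L)
}

#' Deterministic stratified train/test split
#'
#' Per class, the train count is `floor(fraction * class_count + 0.5)` and the
#' members are drawn by a seeded shuffle of the class's ids (sorted first, so
#' the result is reproducible across platforms); the remainder goes to test.
#'
#' @param records list of records as returned by [load_image_folder()], or any
#'   list whose elements carry `label` and `sample_id` fields.
#' @param train_fraction real in (0, 1).
#' @param seed integer seed.
#' @return `urised_split`: list with `train_ids`, `test_ids`, `seed`,
#'   `train_fraction`.
#' @export
stratified_split <- function(records, train_fraction, seed) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  ids <- vapply(records, `[[`, "", "sample_id")
  labels <- vapply(records, `[[`, "", "label")
  if (anyDuplicated(ids)) stop("duplicate sample_ids")
  singles <- names(which(table(labels) < 2))
  if (length(singles)) {
    stop("classes with fewer than 2 samples cannot be split: ",
         paste(singles, collapse = ", "))
  }
  train_ids <- character(0)
  test_ids <- character(0)
  for (cls in sort(unique(labels))) {
    cls_ids <- sort(ids[labels == cls])
    n_train <- floor(train_fraction * length(cls_ids) + 0.5)
    perm <- with_seed(seed + strtoi(substr(digest_hex(cls), 1, 6), 16L),
                      sample.int(length(cls_ids)))
    train_ids <- c(train_ids, cls_ids[perm[seq_len(n_train)]])
    test_ids <- c(test_ids, cls_ids[perm[-seq_len(n_train)]])
  }
  structure(list(train_ids = sort(train_ids), test_ids = sort(test_ids),
                 seed = as.integer(seed), train_fraction = train_fraction),
            class = "urised_split")
}

# Small stable hex hash of a string (class-name -> per-class seed offset),
# so adding a class never perturbs the other classes' draws.
digest_hex <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 16777213
  sprintf("%06x", h)
}

#' Write / read a split manifest
#'
#' JSON form: `{"seed": ..., "train_fraction": ..., "train": [...], "test": [...]}`.
#' @param split a `urised_split`.
#' @param path JSON file path.
#' @export
write_split <- function(split, path) {
  jsonlite::write_json(
    list(seed = split$seed, train_fraction = split$train_fraction,
         train = split$train_ids, test = split$test_ids),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(train_ids = as.character(j$train), test_ids = as.character(j$test),
                 seed = as.integer(j$seed), train_fraction = j$train_fraction),
            class = "urised_split")
}
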