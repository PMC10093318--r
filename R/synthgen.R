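#' Synthetic textured-particle dataset specification
#'
#' Default class list mirrors the composition of a real urine-sediment image
#' collection: eight classes with counts 1224 (Bacteria), 1842 (Crystal),
#' 240 (Cylinder), 432 (Epithelial), 2279 (Erythrocyte), 1734 (Leukocyte),
#' 688 (Yeast) and 70 (Others), scaled by `scale` (floored, minimum 2 per
#' class). Each class pairs a shape archetype (rods, polygons, rings, ovals,
#' elongated casts, irregular blobs — a caricature for testability, not a
#' biological claim) with its own grating texture (base frequency, orientation
#' jitter, contrast) over a speckle-noise background. The "Others" class gets
#' the smallest count and the most heterogeneous generator on purpose, so the
#' benchmark reproduces the qualitative failure mode of rare, ill-defined
#' classes.
#'
#' @param scale multiplier applied to the default per-class counts.
#' @param seed integer master seed; every image derives its own stream from it.
#' @param image_size square image side in pixels.
#' @param uniform_texture if TRUE every class uses the same archetype and
#'   texture (a chance-level control: classes differ only in label).
#' @param class_specs optional custom list overriding the defaults; each
#'   element `list(name, count, archetype, freq, orient_jitter, contrast,
#'   noise_sd)`.
#' @return A `synthetic_dataset_spec` list.
#' @export
synthetic_dataset_spec <- function(scale = 1, seed = 0L, image_size = 224L,
                                   uniform_texture = FALSE, class_specs = NULL) {
  if (is.null(class_specs)) {
    base <- list(
      list(name = "Bacteria",    count = 1224L, archetype = "rod",
           freq = 18, orient_jitter = 0.3, contrast = 0.9, noise_sd = 0.04),
      list(name = "Crystal",     count = 1842L, archetype = "polygon",
           freq = 4,  orient_jitter = 0.1, contrast = 0.8, noise_sd = 0.04),
      list(name = "Cylinder",    count = 240L,  archetype = "cast",
           freq = 8,  orient_jitter = 0.2, contrast = 0.6, noise_sd = 0.04),
      list(name = "Epithelial",  count = 432L,  archetype = "polygon",
           freq = 2,  orient_jitter = 0.5, contrast = 0.35, noise_sd = 0.04),
      list(name = "Erythrocyte", count = 2279L, archetype = "ring",
           freq = 12, orient_jitter = 0.8, contrast = 0.7, noise_sd = 0.04),
      list(name = "Leukocyte",   count = 1734L, archetype = "oval",
           freq = 25, orient_jitter = 1.5, contrast = 0.85, noise_sd = 0.04),
      list(name = "Yeast",       count = 688L,  archetype = "oval",
           freq = 6,  orient_jitter = 0.05, contrast = 0.95, noise_sd = 0.04),
      list(name = "Others",      count = 70L,   archetype = "irregular",
           freq = 10, orient_jitter = 2, contrast = 0.5, noise_sd = 0.08))
    class_specs <- base
  }
  if (uniform_texture) {
    class_specs <- lapply(class_specs, function(cs) {
      cs$archetype <- "oval"; cs$freq <- 10
      cs$orient_jitter <- 0.5; cs$contrast <- 0.7; cs$noise_sd <- 0.04
      cs
    })
  }
  class_specs <- lapply(class_specs, function(cs) {
    cs$count <- max(2L, as.integer(floor(cs$count * scale)))
    cs
  })
  nms <- vapply(class_specs, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("class names must be unique")
  structure(list(class_specs = class_specs, image_size = as.integer(image_size),
                 seed = as.integer(seed)),
            class = "synthetic_dataset_spec")
}

#' Generate a synthetic particle-image dataset
#'
#' One grayscale image per record: shapes of the class archetype at seeded
#' random position/scale/rotation, filled with the class grating texture,
#' over a speckle-noise background. Fully deterministic given the spec
#' (each image's RNG stream is derived from the master seed, the class name
#' and the image index, so neither generation order nor class set perturbs
#' other images). When `output_dir` is given the images are also written as
#' 8-bit grayscale PNG in class-per-folder layout.
#'
#' @param spec a [synthetic_dataset_spec()].
#' @param output_dir optional directory for the PNG tree.
#' @return List of records `list(image, label, sample_id)`, sorted by
#'   `sample_id`.
#' @export
generate_dataset <- function(spec, output_dir = NULL) {
  records <- list()
  for (cs in spec$class_specs) {
    for (i in seq_len(cs$count)) {
      img_seed <- (spec$seed + strtoi(substr(digest_hex(paste0(cs$name, "#", i)), 1, 7), 16L)) %% .Machine$integer.max
      img <- with_seed(img_seed, render_particle_image(cs, spec$image_size))
      sid <- file.path(cs$name, sprintf("%s_%05d.png", tolower(cs$name), i))
      records[[length(records) + 1L]] <- list(image = img, label = cs$name, sample_id = sid)
    }
  }
  records <- records[order(vapply(records, `[[`, "", "sample_id"))]
  if (!is.null(output_dir)) {
    ok <- dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(output_dir)) stop("cannot create output directory ", output_dir)
    for (r in records) {
      d <- file.path(output_dir, dirname(r$sample_id))
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      png::writePNG(r$image / 255, file.path(output_dir, r$sample_id))
    }
  }
  records
}

# One image: background speckle + textured archetype shapes. Returns an
# integer 0-255 matrix.
render_particle_image <- function(cs, size) {
  xg <- matrix(rep(seq_len(size), each = size), size, size)   # column index
  yg <- matrix(rep(seq_len(size), times = size), size, size)  # row index
  img <- 0.45 + rnorm(1, 0, 0.03) + matrix(rnorm(size * size, 0, cs$noise_sd), size, size)

  n_shapes <- if (cs$archetype %in% c("rod", "oval")) sample(2:4, 1) else 1L
  for (s in seq_len(n_shapes)) {
    cx <- runif(1, 0.25, 0.75) * size
    cy <- runif(1, 0.25, 0.75) * size
    ang <- runif(1, 0, pi)
    scale_px <- runif(1, 0.18, 0.3) * size
    mask <- shape_mask(cs$archetype, xg, yg, cx, cy, ang, scale_px)
    tex_ang <- ang + rnorm(1, 0, cs$orient_jitter)
    phase <- runif(1, 0, 2 * pi)
    wave <- sin(2 * pi * cs$freq * ((xg * cos(tex_ang) + yg * sin(tex_ang)) / size) + phase)
    tex <- 0.5 + 0.5 * cs$contrast * wave
    img[mask] <- tex[mask]
  }
  img <- pmin(pmax(img, 0), 1)
  m <- round(img * 255)
  storage.mode(m) <- "integer"
  m
}

# Boolean mask of one shape archetype centred at (cx, cy).
shape_mask <- function(archetype, xg, yg, cx, cy, ang, scale_px) {
  u <- (xg - cx) * cos(ang) + (yg - cy) * sin(ang)
  v <- -(xg - cx) * sin(ang) + (yg - cy) * cos(ang)
  switch(archetype,
    rod = abs(u) < scale_px & abs(v) < scale_px / 6,
    cast = abs(u) < scale_px * 1.4 & abs(v) < scale_px / 3,
    oval = (u / scale_px)^2 + (v / (0.7 * scale_px))^2 < 1,
    ring = {
      r2 <- (u / scale_px)^2 + (v / scale_px)^2
      r2 < 1 & r2 > 0.35
    },
    polygon = {
      k <- sample(3:6, 1)
      th <- atan2(v, u)
      r <- sqrt(u^2 + v^2)
      r < scale_px * cos(pi / k) / cos(((th * k) %% (2 * pi)) / k - pi / k)
    },
    irregular = {
      r <- sqrt(u^2 + v^2)
      th <- atan2(v, u)
      wob <- 1 + 0.4 * sin(3 * th + runif(1, 0, 2 * pi)) +
        0.3 * sin(5 * th + runif(1, 0, 2 * pi))
      r < scale_px * 0.8 * wob
    },
    stop("unknown archetype ", archetype))
}

#' End-to-end separability probe
#'
#' Runs the full default pipeline on a set of records — LBP (2891 features)
#' and filter-bank (1000 features) blocks, mRMR with `k` per block, fusion,
#' linear SVM under stratified 5-fold CV — and returns the pooled accuracy in
#' percent.
#'
#' @param records list of image records.
#' @param k features kept per block (capped at each block's width).
#' @param seed seed for fold assignment.
#' @return Pooled CV accuracy, percent.
#' @export
separability_probe <- function(records, k = 500L, seed = 0L) {
  lbp_fm <- extract_lbp_features(records)
  deep_fm <- extract_deep_features(records, feature_extractor_spec(seed = seed))
  sel_a <- mrmr_select(lbp_fm, min(k, ncol(lbp_fm$values)), "MID")
  sel_b <- mrmr_select(deep_fm, min(k, ncol(deep_fm$values)), "MID")
  fused <- fuse(subselect(lbp_fm, sel_a), subselect(deep_fm, sel_b))
  res <- train_eval(fused, classifier_spec("svm", seed = seed),
                    eval_scheme("kfold_cv", folds = 5L, seed = seed))
  res$accuracy
}
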