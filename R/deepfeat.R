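#' Deep-style feature extractor specification
#'
#' Contract: an extractor maps an image to a fixed-length dense vector
#' (`output_dim`, default 1000 — the width of a classification network's final
#' fully-connected layer). The built-in `"filterbank"` backend is a
#' deterministic handcrafted extractor: multi-scale oriented band-pass filter
#' responses pooled over a 4x4 grid and projected to `output_dim` by a
#' seed-fixed Gaussian random projection. Additional backends (e.g. an adapter
#' around a pretrained network's penultimate layer) can be registered by name.
#'
#' @param name backend name; `"filterbank"` is always available.
#' @param output_dim output vector length.
#' @param input_size target geometry (height = width) images are resized to.
#' @param preprocessing `"resize_bilinear"` (default) or `"center_crop"`.
#' @param seed integer seed fixing the projection matrix.
#' @return A `feature_extractor_spec` list.
#' @export
feature_extractor_spec <- function(name = "filterbank", output_dim = 1000L,
                                   input_size = 224L,
                                   preprocessing = c("resize_bilinear", "center_crop"),
                                   seed = 0L) {
  preprocessing <- match.arg(preprocessing)
  if (output_dim < 1) stop("output_dim must be >= 1")
  structure(list(name = name, output_dim = as.integer(output_dim),
                 input_size = as.integer(input_size),
                 preprocessing = preprocessing, seed = as.integer(seed)),
            class = "feature_extractor_spec")
}

deep_backends <- new.env(parent = emptyenv())

#' Register a deep-feature backend
#'
#' @param name backend name.
#' @param fun function `(image, spec) -> numeric vector` of length
#'   `spec$output_dim`.
#' @export
register_deep_backend <- function(name, fun) {
  assign(name, fun, envir = deep_backends)
  invisible(name)
}

resolve_deep_backend <- function(name) {
  if (!exists(name, envir = deep_backends)) {
    stop("unknown deep-feature backend '", name, "'; registered: ",
         paste(ls(deep_backends), collapse = ", "))
  }
  get(name, envir = deep_backends)
}

#' Extract dense image features for a list of records
#'
#' @param records list of image records.
#' @param spec a [feature_extractor_spec()].
#' @return A [feature_matrix()] with columns tagged `deep:<name>:NNNN`; row
#'   order matches the input record order.
#' @export
extract_deep_features <- function(records, spec = feature_extractor_spec()) {
  backend <- resolve_deep_backend(spec$name)
  vecs <- lapply(records, function(r) backend(r$image, spec))
  vals <- do.call(rbind, vecs)
  feature_matrix(vals,
                 sample_ids = vapply(records, `[[`, "", "sample_id"),
                 labels = vapply(records, `[[`, "", "label"),
                 feature_names = sprintf("deep:%s:%04d", spec$name,
                                         seq_len(ncol(vals)) - 1L))
}

#' Built-in filter-bank extractor
#'
#' The image is resized to `input_size`; band-pass responses (oriented
#' difference-of-boxes at 4 orientations and centre-surround
#' difference-of-box-blurs, each at 3 scales) are rectified and mean-pooled
#' over a 4x4 grid, a DC channel keeps per-cell mean intensity, and the pooled
#' vector is projected to `output_dim` by a Gaussian matrix drawn once from
#' `spec$seed`. Band-pass channels vanish exactly on constant images.
#'
#' @param image intensity matrix (0-255 or 0-1).
#' @param spec a [feature_extractor_spec()].
#' @return Numeric vector of length `spec$output_dim`.
#' @export
builtin_filterbank_extractor <- function(image, spec = feature_extractor_spec()) {
  img <- as.matrix(image)
  storage.mode(img) <- "double"
  if (max(img) > 1) img <- img / 255
  sz <- spec$input_size
  if (spec$preprocessing == "center_crop" &&
      nrow(img) >= sz && ncol(img) >= sz) {
    r0 <- (nrow(img) - sz) %/% 2
    c0 <- (ncol(img) - sz) %/% 2
    img <- img[r0 + seq_len(sz), c0 + seq_len(sz), drop = FALSE]
  } else if (nrow(img) != sz || ncol(img) != sz) {
    img <- resize_bilinear(img, sz, sz)
  }
  pooled <- filterbank_pooled(img)
  proj <- projection_matrix(spec$output_dim, length(pooled), spec$seed)
  as.numeric(proj %*% pooled)
}

# Pooled responses: 4 orientations x 3 scales + 3 centre-surround, |.|
# mean-pooled on a 4x4 grid, plus 16 DC cells -> (12 + 3) * 16 + 16 = 256.
filterbank_pooled <- function(img) {
  scales <- c(2L, 4L, 8L)
  out <- numeric(0)
  for (s in scales) {
    b <- box_mean(img, s)
    # oriented difference of displaced blurs: E-W, N-S and the two diagonals
    shifts <- list(c(0, s), c(s, 0), c(s, s), c(s, -s))
    for (sh in shifts) {
      resp <- shift_pad(b, sh[1], sh[2]) - shift_pad(b, -sh[1], -sh[2])
      out <- c(out, pool_grid(abs(resp), 4L))
    }
    cs <- b - box_mean(img, 2L * s)
    out <- c(out, pool_grid(abs(cs), 4L))
  }
  c(out, pool_grid(img, 4L))
}

# Mean filter of half-width r with clamped (replicated) borders, via integral
# image; constant inputs map to the same constant exactly.
box_mean <- function(m, r) {
  H <- nrow(m); W <- ncol(m)
  ri <- pmin(pmax(seq_len(H) + r, 1), H)
  li <- pmin(pmax(seq_len(H) - r - 1, 0), H)
  bi <- pmin(pmax(seq_len(W) + r, 1), W)
  ti <- pmin(pmax(seq_len(W) - r - 1, 0), W)
  cs <- apply(m, 2, cumsum)
  cs <- rbind(0, cs)
  colpart <- cs[ri + 1, , drop = FALSE] - cs[li + 1, , drop = FALSE]
  cs2 <- t(apply(colpart, 1, cumsum))
  cs2 <- cbind(0, cs2)
  tot <- cs2[, bi + 1, drop = FALSE] - cs2[, ti + 1, drop = FALSE]
  area <- outer(ri - li, bi - ti)
  tot / area
}

# Shift with edge replication.
shift_pad <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  m[pmin(pmax(seq_len(H) + dr, 1), H), pmin(pmax(seq_len(W) + dc, 1), W), drop = FALSE]
}

pool_grid <- function(m, g) {
  rb <- round(seq(0, nrow(m), length.out = g + 1))
  cb <- round(seq(0, ncol(m), length.out = g + 1))
  out <- numeric(g * g)
  k <- 1L
  for (r in seq_len(g)) {
    for (cc in seq_len(g)) {
      out[k] <- mean(m[(rb[r] + 1):rb[r + 1], (cb[cc] + 1):cb[cc + 1]])
      k <- k + 1L
    }
  }
  out
}

# Seed-fixed Gaussian projection, cached per (rows, cols, seed).
projection_env <- new.env(parent = emptyenv())
projection_matrix <- function(rows, cols, seed) {
  key <- sprintf("%d_%d_%d", rows, cols, seed)
  if (!exists(key, envir = projection_env)) {
    m <- with_seed(seed, matrix(rnorm(rows * cols), rows, cols) / sqrt(cols))
    assign(key, m, envir = projection_env)
  }
  get(key, envir = projection_env)
}

#' Bilinear image resize
#'
#' @param img numeric matrix.
#' @param h,w target dimensions.
#' @return Resized matrix.
#' @export
resize_bilinear <- function(img, h, w) {
  out <- EBImage::resize(EBImage::Image(t(img)), w = w, h = h,
                         filter = "bilinear")
  t(EBImage::imageData(out))
}
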