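#' Local Binary Pattern configuration
#'
#' The default configuration — 8 neighbours at radius 1, uniform mapping
#' (59 bins), 7x7 cell grid, raw counts — produces a 59 x 49 = 2891-dimension
#' descriptor, the unique standard uniform-LBP geometry of that length.
#'
#' @param neighbors number of sampling points P (8 for `nearest_8_connected`).
#' @param radius sampling radius R in pixels.
#' @param sampling `"nearest_8_connected"` (the 8 axis/diagonal neighbours at
#'   offset R) or `"circular_interpolated"` (P points on a circle of radius R,
#'   bilinear interpolation).
#' @param tie_rule bit value when neighbour equals centre: `"geq_is_one"`
#'   (default; makes constant images well defined) or `"gt_is_one"`.
#' @param uniform collapse non-uniform codes (more than two circular 0-1
#'   transitions) into one catch-all bin.
#' @param grid_rows,grid_cols cell grid applied to the code map.
#' @param normalize `"counts"` (raw cell histograms) or `"per_cell_fraction"`
#'   (each cell's histogram sums to 1).
#' @return An `lbp_config` list.
#' @export
lbp_config <- function(neighbors = 8L, radius = 1L,
                       sampling = c("nearest_8_connected", "circular_interpolated"),
                       tie_rule = c("geq_is_one", "gt_is_one"),
                       uniform = TRUE, grid_rows = 7L, grid_cols = 7L,
                       normalize = c("counts", "per_cell_fraction")) {
  sampling <- match.arg(sampling)
  tie_rule <- match.arg(tie_rule)
  normalize <- match.arg(normalize)
  neighbors <- as.integer(neighbors)
  if (sampling == "nearest_8_connected" && neighbors != 8L) {
    stop("nearest_8_connected sampling requires neighbors = 8")
  }
  if (neighbors < 1L || neighbors > 16L) stop("neighbors must be in 1..16")
  if (grid_rows < 1L || grid_cols < 1L) stop("grid must be at least 1x1")
  structure(list(neighbors = neighbors, radius = as.integer(radius),
                 sampling = sampling, tie_rule = tie_rule, uniform = uniform,
                 grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
                 normalize = normalize),
            class = "lbp_config")
}

#' Uniform-pattern bin mapping
#'
#' A code is *uniform* when its circular bit string has at most two 0-1 / 1-0
#' transitions; uniform codes get distinct bins (in increasing code order) and
#' all remaining codes share one catch-all bin. For P neighbours there are
#' P(P-1) + 2 uniform codes, hence P(P-1) + 3 bins — 59 at P = 8.
#'
#' @param P number of neighbours (1..16).
#' @return Integer vector of length 2^P mapping code (0-based, via index
#'   code + 1) to 1-based bin; attribute `n_bins` gives the bin count.
#' @export
uniform_mapping <- function(P) {
  P <- as.integer(P)
  if (P < 1L || P > 16L) stop("P must be in 1..16")
  codes <- 0:(2^P - 1)
  bits <- vapply(codes, function(cd) as.integer(intToBits(cd))[seq_len(P)],
                 integer(P))
  bits <- matrix(bits, nrow = P)
  trans <- if (P == 1L) rep(0, 2L^P) else colSums(bits != bits[c(2:P, 1), , drop = FALSE])
  is_uniform <- trans <= 2
  mapping <- integer(2^P)
  mapping[is_uniform] <- seq_len(sum(is_uniform))
  mapping[!is_uniform] <- sum(is_uniform) + 1L
  attr(mapping, "n_bins") <- sum(is_uniform) + 1L
  mapping
}

#' Compute the LBP code map of an image
#'
#' For every interior pixel, bit i is 1 iff neighbour i is >= (or >, per the
#' tie rule) the centre value; the code is sum(bit_i * 2^i). Bit 0 is the east
#' neighbour and bits proceed counter-clockwise. Border policy is "valid": the
#' code map is (H - 2R) x (W - 2R).
#'
#' @param image integer/numeric matrix of intensities (rows = y).
#' @param config an [lbp_config()].
#' @return Integer matrix of codes in `[0, 2^P - 1]`.
#' @export
compute_lbp_codes <- function(image, config = lbp_config()) {
  img <- as.matrix(image)
  storage.mode(img) <- "double"
  R <- config$radius
  P <- config$neighbors
  H <- nrow(img); W <- ncol(img)
  if (H < 2 * R + 1 || W < 2 * R + 1) {
    stop(sprintf("image %dx%d too small for radius %d (needs >= %dx%d)",
                 H, W, R, 2 * R + 1, 2 * R + 1))
  }
  center <- img[(R + 1):(H - R), (R + 1):(W - R), drop = FALSE]
  geq <- config$tie_rule == "geq_is_one"
  codes <- matrix(0L, nrow(center), ncol(center))
  for (i in seq_len(P) - 1L) {
    nb <- sample_neighbor(img, R, P, i, config$sampling)
    bit <- if (geq) nb >= center else nb > center
    codes <- codes + as.integer(bit) * bitwShiftL(1L, i)
  }
  codes
}

# Neighbour plane i for the valid interior, as a matrix aligned with centres.
# Angles start east (i = 0) and move counter-clockwise (image rows grow
# downward, so dy = -R sin(theta)).
sample_neighbor <- function(img, R, P, i, sampling) {
  H <- nrow(img); W <- ncol(img)
  rows <- (R + 1):(H - R)
  cols <- (R + 1):(W - R)
  if (sampling == "nearest_8_connected") {
    off <- list(c(0, R), c(-R, R), c(-R, 0), c(-R, -R),
                c(0, -R), c(R, -R), c(R, 0), c(R, R))[[i + 1L]]
    return(img[rows + off[1], cols + off[2], drop = FALSE])
  }
  theta <- 2 * pi * i / P
  dy <- -R * sin(theta)
  dx <- R * cos(theta)
  # snap near-integer offsets to avoid interpolation noise at the compass points
  if (abs(dy - round(dy)) < 1e-9) dy <- round(dy)
  if (abs(dx - round(dx)) < 1e-9) dx <- round(dx)
  y0 <- floor(dy); x0 <- floor(dx)
  fy <- dy - y0;  fx <- dx - x0
  # zero-weight corners reuse the base index so offsets stay within the pad
  y1 <- if (fy > 0) y0 + 1 else y0
  x1 <- if (fx > 0) x0 + 1 else x0
  w00 <- (1 - fy) * (1 - fx); w01 <- (1 - fy) * fx
  w10 <- fy * (1 - fx);       w11 <- fy * fx
  w00 * img[rows + y0, cols + x0, drop = FALSE] +
    w01 * img[rows + y0, cols + x1, drop = FALSE] +
    w10 * img[rows + y1, cols + x0, drop = FALSE] +
    w11 * img[rows + y1, cols + x1, drop = FALSE]
}

#' LBP cell-grid histogram descriptor
#'
#' Partitions the code map into `grid_rows` x `grid_cols` near-equal
#' rectangular cells (boundaries at `round(k * H' / grid_rows)`), histograms
#' each cell over the uniform mapping, and concatenates the histograms in
#' row-major cell order. With the defaults the descriptor has
#' 59 x 49 = 2891 entries.
#'
#' @inheritParams compute_lbp_codes
#' @return Numeric vector of length `n_bins * grid_rows * grid_cols`.
#' @export
lbp_feature_vector <- function(image, config = lbp_config()) {
  codes <- compute_lbp_codes(image, config)
  lbp_histogram_from_codes(codes, config)
}

lbp_histogram_from_codes <- function(codes, config) {
  Hc <- nrow(codes); Wc <- ncol(codes)
  gr <- config$grid_rows; gc <- config$grid_cols
  if (Hc < gr || Wc < gc) {
    stop(sprintf("code map %dx%d smaller than the %dx%d cell grid; image must be at least %dx%d",
                 Hc, Wc, gr, gc, gr + 2 * config$radius, gc + 2 * config$radius))
  }
  if (config$uniform) {
    mapping <- uniform_mapping(config$neighbors)
    n_bins <- attr(mapping, "n_bins")
    binned <- matrix(mapping[codes + 1L], Hc, Wc)
  } else {
    n_bins <- 2L^config$neighbors
    binned <- codes + 1L
  }
  rb <- round(seq(0, Hc, length.out = gr + 1))
  cb <- round(seq(0, Wc, length.out = gc + 1))
  out <- numeric(0)
  for (r in seq_len(gr)) {
    for (cc in seq_len(gc)) {
      cell <- binned[(rb[r] + 1):rb[r + 1], (cb[cc] + 1):cb[cc + 1], drop = FALSE]
      h <- tabulate(cell, nbins = n_bins)
      if (config$normalize == "per_cell_fraction") {
        h <- h / max(sum(h), 1)
      }
      out <- c(out, h)
    }
  }
  out
}

#' Extract LBP descriptors for a list of image records
#'
#' @param records list of records from [load_image_folder()] or
#'   [generate_dataset()].
#' @param config an [lbp_config()].
#' @return A [feature_matrix()] with feature names tagged `lbp:fNNNN`.
#' @export
extract_lbp_features <- function(records, config = lbp_config()) {
  vecs <- lapply(records, function(r) lbp_feature_vector(r$image, config))
  vals <- do.call(rbind, vecs)
  feature_matrix(vals,
                 sample_ids = vapply(records, `[[`, "", "sample_id"),
                 labels = vapply(records, `[[`, "", "label"),
                 feature_names = sprintf("lbp:f%04d", seq_len(ncol(vals)) - 1L))
}
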