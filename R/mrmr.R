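#' Equal-width discretization
#'
#' Maps each value to `floor(bins * (x - min) / (max - min))`, clipped to
#' `[0, bins - 1]`; a constant vector maps to all zeros. This is the
#' prerequisite for the entropy-based mRMR criteria.
#'
#' @param values numeric vector, all finite.
#' @param bins number of bins, >= 2.
#' @return Integer vector of 0-based bin codes.
#' @export
discretize_equal_width <- function(values, bins) {
  if (bins < 2) stop("bins must be >= 2")
  if (any(!is.finite(values))) stop("non-finite values cannot be discretized")
  rng <- range(values)
  if (rng[1] == rng[2]) return(integer(length(values)))
  codes <- floor(bins * (values - rng[1]) / (rng[2] - rng[1]))
  as.integer(pmin(pmax(codes, 0), bins - 1))
}

#' Plug-in mutual information estimate (bits)
#'
#' `sum p(a,b) log2(p(a,b) / (p(a) p(b)))` over the observed joint table of
#' two discrete vectors.
#'
#' @param x,y discrete vectors (integer codes or factors) of equal length.
#' @return Non-negative real, in bits.
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  xi <- as.integer(factor(x)) - 1L
  yi <- as.integer(factor(y)) - 1L
  mi_columns(matrix(xi, ncol = 1), yi, max(xi) + 1L, max(yi) + 1L)[1]
}

#' One-way ANOVA F statistic of a feature against class labels
#'
#' F = between-class mean square / within-class mean square. Zero within-class
#' variance with a non-zero between-class component returns `Inf` (perfectly
#' separating feature).
#'
#' @param x numeric feature vector.
#' @param y class labels (any vector coercible to factor, >= 2 classes).
#' @return The F statistic.
#' @export
f_statistic <- function(x, y) {
  y <- factor(y)
  if (nlevels(y) < 2) stop("f_statistic needs at least 2 classes")
  n <- length(x)
  gm <- tapply(x, y, mean)
  nk <- tabulate(y)
  ssb <- sum(nk * (gm - mean(x))^2)
  ssw <- sum((x - gm[as.integer(y)])^2)
  df1 <- nlevels(y) - 1L
  df2 <- n - nlevels(y)
  if (df2 < 1) stop("f_statistic needs more samples than classes")
  msb <- ssb / df1
  msw <- ssw / df2
  if (msw == 0) {
    if (msb == 0) return(0)
    return(Inf)
  }
  msb / msw
}

# Vectorized per-column F statistics (same definition as f_statistic).
f_statistic_columns <- function(X, y) {
  y <- factor(y)
  n <- nrow(X); K <- nlevels(y)
  G <- stats::model.matrix(~ y - 1)
  nk <- colSums(G)
  gm <- crossprod(G, X) / nk            # K x p class means
  grand <- colMeans(X)
  ssb <- colSums(nk * (sweep(gm, 2, grand))^2)
  sst <- colSums(sweep(X, 2, grand)^2)
  ssw <- pmax(sst - ssb, 0)
  msb <- ssb / (K - 1)
  msw <- ssw / (n - K)
  f <- ifelse(msw <= 1e-12 * pmax(msb, 1), ifelse(msb <= 1e-30, 0, Inf), msb / msw)
  as.numeric(f)
}

#' Greedy minimum-redundancy maximum-relevance feature selection
#'
#' The first feature maximizes relevance to the class label; every later pick
#' maximizes `relevance - meanRedundancy` (MID/FCD) or
#' `relevance / meanRedundancy` (MIQ/FCQ) against the already-selected set.
#' For the entropy criteria (MID, MIQ) relevance is the mutual information of
#' the equal-width-discretized feature with the label and redundancy the MI
#' between discretized features; for the F-test criteria (FCD, FCQ) relevance
#' is the one-way ANOVA F and redundancy the absolute Pearson correlation.
#' Ties break toward the lowest feature index; the MIQ/FCQ denominator is
#' floored at 1e-12.
#'
#' @param fm a [feature_matrix()].
#' @param k number of features to select.
#' @param criterion `"MID"`, `"MIQ"`, `"FCD"` or `"FCQ"`.
#' @param bins equal-width discretization bins (entropy criteria only).
#' @return `urised_selection`: list with `selected` (ordered 1-based column
#'   indices), `criterion`, `relevance` (per-feature score), `redundancy_trace`
#'   (mean redundancy of each pick at selection time), `bins`.
#' @export
mrmr_select <- function(fm, k, criterion = c("MID", "MIQ", "FCD", "FCQ"), bins = 10L) {
  criterion <- match.arg(criterion)
  X <- fm$values
  p <- ncol(X)
  if (k < 1 || k > p) stop("k must be in 1..n_features (", p, ")")
  classes <- sort(unique(fm$labels))
  if (length(classes) < 2) stop("mrmr_select needs at least 2 classes")
  y <- as.integer(factor(fm$labels, levels = classes)) - 1L
  entropy <- criterion %in% c("MID", "MIQ")
  quotient <- criterion %in% c("MIQ", "FCQ")

  if (entropy) {
    D <- apply(X, 2, discretize_equal_width, bins = bins)
    storage.mode(D) <- "integer"
    relevance <- as.numeric(mi_columns(D, y, bins, length(classes)))
  } else {
    relevance <- f_statistic_columns(X, y)
  }

  selected <- integer(0)
  red_sum <- numeric(p)
  red_trace <- numeric(0)
  remaining <- rep(TRUE, p)
  for (step in seq_len(k)) {
    if (step == 1L) {
      score <- relevance
    } else {
      mean_red <- red_sum / (step - 1L)
      score <- if (quotient) relevance / pmax(mean_red, 1e-12) else relevance - mean_red
    }
    score[!remaining] <- -Inf
    pick <- which.max(score)
    selected <- c(selected, pick)
    red_trace <- c(red_trace, if (step == 1L) 0 else red_sum[pick] / (step - 1L))
    remaining[pick] <- FALSE
    if (step < k) {
      if (entropy) {
        red_sum <- red_sum + as.numeric(mi_columns(D, D[, pick], bins, bins))
      } else {
        r <- suppressWarnings(as.numeric(cor(X[, pick], X)))
        r[is.na(r)] <- 0   # constant feature: no linear redundancy
        red_sum <- red_sum + abs(r)
      }
    }
  }
  structure(list(selected = selected, criterion = criterion,
                 relevance = relevance, redundancy_trace = red_trace,
                 bins = if (entropy) as.integer(bins) else NA_integer_,
                 feature_names = fm$feature_names[selected]),
            class = "urised_selection")
}

#' Write / read a selection result as JSON
#' @param sel a `urised_selection`.
#' @param path JSON file path.
#' @export
write_selection <- function(sel, path) {
  jsonlite::write_json(
    c(list(selected = sel$selected, criterion = sel$criterion,
           relevance = sel$relevance, redundancy_trace = sel$redundancy_trace,
           feature_names = sel$feature_names),
      if (!is.na(sel$bins)) list(bins = sel$bins)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_selection
#' @export
read_selection <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(selected = as.integer(j$selected), criterion = j$criterion,
                 relevance = as.numeric(j$relevance),
                 redundancy_trace = as.numeric(j$redundancy_trace),
                 bins = if (length(j$bins) != 1 || is.na(j$bins)) NA_integer_ else as.integer(j$bins),
                 feature_names = as.character(j$feature_names)),
            class = "urised_selection")
}
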