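# Independent oracles and fixture builders shared across tests.

# Naive per-pixel double-loop LBP (8-connected, radius 1), independent of the
# vectorized implementation.
lbp_oracle_codes <- function(img, tie_geq = TRUE) {
  H <- nrow(img); W <- ncol(img)
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1),
               c(0, -1), c(1, -1), c(1, 0), c(1, 1))
  out <- matrix(0L, H - 2, W - 2)
  for (r in 2:(H - 1)) {
    for (cc in 2:(W - 1)) {
      code <- 0L
      for (i in 0:7) {
        nb <- img[r + offs[[i + 1]][1], cc + offs[[i + 1]][2]]
        bit <- if (tie_geq) nb >= img[r, cc] else nb > img[r, cc]
        if (bit) code <- code + bitwShiftL(1L, i)
      }
      out[r - 1, cc - 1] <- code
    }
  }
  out
}

# Brute-force plug-in MI (bits) from the joint table.
mi_oracle <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  mi <- 0
  for (a in seq_len(nrow(tab))) {
    for (b in seq_len(ncol(tab))) {
      pab <- tab[a, b] / n
      if (pab > 0) {
        mi <- mi + pab * log2(pab / ((sum(tab[a, ]) / n) * (sum(tab[, b]) / n)))
      }
    }
  }
  mi
}

# Brute-force one-way ANOVA F.
f_oracle <- function(x, y) {
  y <- factor(y)
  fit <- stats::anova(stats::lm(x ~ y))
  fit[["F value"]][1]
}

# Exhaustive re-implementation of the greedy mRMR rule: recomputes every
# relevance and pairwise redundancy from scratch at each step.
mrmr_oracle <- function(X, labels, k, criterion, bins = 10L) {
  p <- ncol(X)
  disc <- function(v) {
    r <- range(v)
    if (r[1] == r[2]) return(integer(length(v)))
    as.integer(pmin(pmax(floor(bins * (v - r[1]) / (r[2] - r[1])), 0), bins - 1))
  }
  entropy <- criterion %in% c("MID", "MIQ")
  quotient <- criterion %in% c("MIQ", "FCQ")
  rel <- sapply(seq_len(p), function(j) {
    if (entropy) mi_oracle(disc(X[, j]), labels) else f_oracle(X[, j], labels)
  })
  red_pair <- function(a, b) {
    if (entropy) mi_oracle(disc(X[, a]), disc(X[, b]))
    else {
      r <- suppressWarnings(cor(X[, a], X[, b]))
      if (is.na(r)) 0 else abs(r)
    }
  }
  sel <- integer(0)
  for (step in seq_len(k)) {
    best <- NA_integer_; best_score <- -Inf
    for (j in seq_len(p)) {
      if (j %in% sel) next
      score <- if (step == 1) rel[j] else {
        mr <- mean(sapply(sel, red_pair, a = j))
        if (quotient) rel[j] / max(mr, 1e-12) else rel[j] - mr
      }
      if (score > best_score) { best_score <- score; best <- j }
    }
    sel <- c(sel, best)
  }
  sel
}

# Feature matrix of two (or more) Gaussian classes with a mean offset on the
# first `n_inf` columns.
make_gaussian_fm <- function(n_per_class, n_classes = 2, p = 20, n_inf = 5,
                             d = 6, seed = 0) {
  set.seed(seed)
  n <- n_per_class * n_classes
  y <- rep(paste0("class", seq_len(n_classes)), each = n_per_class)
  X <- matrix(rnorm(n * p), n, p)
  n_inf <- min(n_inf, p)
  for (k in seq_len(n_classes)[-1]) {
    rows <- y == paste0("class", k)
    X[rows, seq_len(n_inf)] <- X[rows, seq_len(n_inf)] + d * (k - 1)
  }
  feature_matrix(X, sprintf("s%04d", seq_len(n)), y)
}

# Balanced synthetic image spec: `count` images for each of the 8 default
# classes.
balanced_synth_spec <- function(count, seed = 0, uniform_texture = FALSE,
                                image_size = 224L) {
  spec <- synthetic_dataset_spec(seed = seed, uniform_texture = uniform_texture,
                                 image_size = image_size)
  spec$class_specs <- lapply(spec$class_specs, function(cs) {
    cs$count <- as.integer(count)
    cs
  })
  spec
}

random_image <- function(h, w, seed = 0) {
  set.seed(seed)
  matrix(sample(0:255, h * w, replace = TRUE), h, w)
}
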