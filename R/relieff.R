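#' Multi-class ReliefF feature weighting
#'
#' Estimates a quality weight `W[A]` per feature: features whose values
#' separate nearest neighbors of different classes gain weight, features
#' that separate nearest neighbors of the same class lose it. For each of
#' `m` sampled instances `R`, the `k` nearest hits (same class) subtract
#' `diff(A, R, H) / (m k)` and, for every other class `C`, the `k`
#' nearest misses in `C` add `P(C) / (1 - P(class(R)))` times
#' `diff(A, R, M) / (m k)`. `diff` is the absolute difference after
#' per-feature min-max scaling (a zero-range feature has `diff = 0`, so a
#' constant feature gets weight exactly 0). Neighbor search uses
#' Manhattan distance on the scaled features, ties broken by sample
#' index. Instances are sampled without replacement when `m <= N`, with
#' replacement otherwise.
#'
#' @param x Numeric feature matrix or data frame (rows = samples).
#' @param y Class labels (factor or character).
#' @param k Nearest hits/misses per class (default 8). Every class must
#'   have at least `k + 1` members.
#' @param m Number of sampled instances (default 20).
#' @param seed Integer seed making the sampling deterministic.
#' @return Object of class `relieff_weights`: numeric `weights` named by
#'   feature, plus the settings used.
#' @export
relieff <- function(x, y, k = 8L, m = 20L, seed = 1L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.factor(y)
  stopifnot(k >= 1, m >= 1, nrow(x) == length(y), !anyNA(x))
  N <- nrow(x); A <- ncol(x)
  counts <- table(y)
  small <- names(counts)[counts < k + 1]
  if (length(small))
    stop("class(es) with fewer than k + 1 samples: ",
         paste(small, collapse = ", "))
  rng <- apply(x, 2, range)
  span <- rng[2, ] - rng[1, ]
  z <- x
  for (j in seq_len(A))
    z[, j] <- if (span[j] > 0) (x[, j] - rng[1, j]) / span[j] else 0
  prior <- as.numeric(counts) / N
  names(prior) <- names(counts)
  classes <- levels(y)

  idx <- with_seed(seed, {
    if (m <= N) sample.int(N, m) else sample.int(N, m, replace = TRUE)
  })

  w <- numeric(A)
  for (r in idx) {
    d <- colSums(abs(t(z) - z[r, ]))   # Manhattan, scaled features
    cl <- as.character(y[r])
    hits <- setdiff(which(y == cl), r)
    hits <- hits[order(d[hits], hits)][seq_len(k)]
    w <- w - colSums(abs(z[hits, , drop = FALSE] -
                         rep(z[r, ], each = k))) / (m * k)
    for (cm in setdiff(classes, cl)) {
      miss <- which(y == cm)
      miss <- miss[order(d[miss], miss)][seq_len(k)]
      coef <- prior[cm] / (1 - prior[cl])
      w <- w + coef * colSums(abs(z[miss, , drop = FALSE] -
                                  rep(z[r, ], each = k))) / (m * k)
    }
  }
  structure(list(weights = stats::setNames(w, colnames(x)),
                 k = k, m = m, n_repeats = 1L, seed = seed),
            class = "relieff_weights")
}

#' @export
print.relieff_weights <- function(x, ...) {
  cat(sprintf("ReliefF feature weights (k = %d, m = %d, %d run%s)\n",
              x$k, x$m, x$n_repeats, if (x$n_repeats > 1) "s" else ""))
  print(round(sort(x$weights, decreasing = TRUE), 4))
  invisible(x)
}

#' Average ReliefF weights over repeated runs
#'
#' Repeats the full weighting `n_repeats` times with sub-seeds derived
#' from `seed` and returns the element-wise mean; the per-run weights are
#' kept for stability diagnostics.
#'
#' @inheritParams relieff
#' @param n_repeats Number of independent runs to average (default 20).
#' @return A `relieff_weights` object with a `runs` matrix attached
#'   (rows = runs).
#' @export
average_weight_runs <- function(x, y, k = 8L, m = 20L, n_repeats = 20L,
                                seed = 1L) {
  stopifnot(n_repeats >= 1)
  runs <- t(vapply(seq_len(n_repeats), function(i)
    relieff(x, y, k = k, m = m, seed = derive_seed(seed, i))$weights,
    numeric(ncol(as.matrix(x)))))
  structure(list(weights = colMeans(runs), k = k, m = m,
                 n_repeats = n_repeats, seed = seed, runs = runs),
            class = "relieff_weights")
}

#' Rank features by weight and select a subspace
#'
#' Feature indices in descending weight order, truncated to the leading
#' `dims`; ties broken by lower index.
#'
#' @param weights A `relieff_weights` object or numeric vector.
#' @param dims Number of features to keep.
#' @return Integer vector of feature indices, named if the weights were.
#' @export
rank_and_select <- function(weights, dims) {
  w <- if (inherits(weights, "relieff_weights")) weights$weights else weights
  stopifnot(dims >= 1, dims <= length(w))
  ord <- order(-w, seq_along(w))   # ties fall back to lower index
  sel <- ord[seq_len(dims)]
  if (!is.null(names(w))) names(sel) <- names(w)[sel]
  sel
}
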