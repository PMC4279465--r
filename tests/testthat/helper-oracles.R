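# Independent oracles used across the test files. Each re-derives the
# quantity from its defining formula, without calling the package path it
# checks.

# Gray statistics by direct re-summation over raw gray values.
oracle_gray_stats <- function(gray, gray_levels = 256) {
  N <- length(gray)
  p <- numeric(gray_levels)
  for (g in gray) p[g + 1] <- p[g + 1] + 1 / N
  k <- 0:(gray_levels - 1)
  f_bar <- 0; for (i in seq_along(p)) f_bar <- f_bar + k[i] * p[i]
  s2 <- 0; for (i in seq_along(p)) s2 <- s2 + (k[i] - f_bar)^2 * p[i]
  m3 <- 0; for (i in seq_along(p)) m3 <- m3 + (k[i] - f_bar)^3 * p[i]
  U <- 0; for (i in seq_along(p)) U <- U + p[i]^2
  e <- 0; for (i in seq_along(p)) if (p[i] > 0) e <- e - p[i] * log2(p[i])
  c(mean = f_bar, var = s2, smooth = 1 - 1 / (1 + s2), m3 = m3,
    unif = U, entropy = e)
}

# Term-by-term Hu invariants from 0-based (row, col) silhouette coords.
oracle_hu <- function(coords) {
  y <- coords[, 1]; x <- coords[, 2]
  n <- nrow(coords)
  xb <- sum(x) / n; yb <- sum(y) / n
  mu <- function(p, q) {
    acc <- 0
    for (i in seq_len(n)) acc <- acc + (x[i] - xb)^p * (y[i] - yb)^q
    acc
  }
  eta <- function(p, q) mu(p, q) / n^((p + q) / 2 + 1)
  n20 <- eta(2, 0); n02 <- eta(0, 2); n11 <- eta(1, 1)
  n30 <- eta(3, 0); n03 <- eta(0, 3); n21 <- eta(2, 1); n12 <- eta(1, 2)
  c(n20 + n02,
    (n20 - n02)^2 + 4 * n11^2,
    (n30 - 3 * n12)^2 + (3 * n21 - n03)^2,
    (n30 + n12)^2 + (n21 + n03)^2,
    (n30 - 3 * n12) * (n30 + n12) * ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
      (3 * n21 - n03) * (n21 + n03) * (3 * (n30 + n12)^2 - (n21 + n03)^2),
    (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
      4 * n11 * (n30 + n12) * (n21 + n03),
    (3 * n21 - n03) * (n30 + n12) * ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
      (n30 - 3 * n12) * (n21 + n03) * (3 * (n30 + n12)^2 - (n21 + n03)^2))
}

# Straight-line transcription of the per-pixel mixture rules for a
# one-pixel gray sequence: match in rank order (strict |x-u| < phi*sigma),
# B from pre-update sorted weights (strict cumulative > T_R), foreground
# iff no match or matched rank > B, Stauffer-Grimson update with rho =
# alpha, lowest-weight replacement, renormalization, stable re-sort by
# w/sigma with empty slots last.
oracle_gmm_1px <- function(xs, params = fminspect::gmm_params()) {
  K <- params$K
  w <- c(1, rep(0, K - 1)); u <- c(xs[1], rep(0, K - 1))
  v <- rep(params$init_var2, K); act <- c(TRUE, rep(FALSE, K - 1))
  fg <- logical(length(xs))
  snap <- vector("list", length(xs))
  snap[[1]] <- list(w = w, u = u, v = v, active = act)
  for (t in seq_along(xs)[-1]) {
    x <- xs[t]
    m <- NA_integer_
    for (k in seq_len(K)) {
      if (act[k] && abs(x - u[k]) < params$phi * sqrt(v[k])) { m <- k; break }
    }
    cw <- 0; B <- K
    for (k in seq_len(K)) { cw <- cw + w[k]; if (cw > params$T_R) { B <- k; break } }
    fg[t] <- is.na(m) || m > B
    a <- params$alpha
    if (!is.na(m)) {
      w <- (1 - a) * w
      w[m] <- w[m] + a
      u[m] <- (1 - a) * u[m] + a * x
      v[m] <- (1 - a) * v[m] + a * (x - u[m])^2
    } else {
      repl <- order(ifelse(act, w, -Inf))[1]
      w[repl] <- params$initial_weight_new
      u[repl] <- x
      v[repl] <- params$init_var2
      act[repl] <- TRUE
    }
    v <- pmax(v, params$variance_floor)
    w[!act] <- 0
    w <- w / sum(w)
    key <- ifelse(act, w / sqrt(v), -Inf)
    perm <- order(-key, seq_len(K))
    w <- w[perm]; u <- u[perm]; v <- v[perm]; act <- act[perm]
    snap[[t]] <- list(w = w, u = u, v = v, active = act)
  }
  list(fg = fg, snapshots = snap)
}

# Nearest-centroid classifier: trains class centroids on standardized
# features, predicts by minimum Euclidean distance.
nearest_centroid_accuracy <- function(train_x, train_y, test_x, test_y) {
  mu <- colMeans(train_x); sdv <- apply(train_x, 2, sd)
  sdv[sdv == 0] <- 1
  zs <- function(m) sweep(sweep(as.matrix(m), 2, mu), 2, sdv, `/`)
  ztr <- zs(train_x); zte <- zs(test_x)
  cen <- do.call(rbind, lapply(levels(train_y), function(k)
    colMeans(ztr[train_y == k, , drop = FALSE])))
  d <- as.matrix(dist(rbind(cen, zte)))[seq_len(nrow(cen)),
                                        -(seq_len(nrow(cen))), drop = FALSE]
  pred <- levels(train_y)[apply(d, 2, which.min)]
  mean(pred == as.character(test_y))
}

# Rasterized shapes used by the invariance suite.
shape_disk <- function(radius) {
  g <- expand.grid(r = -radius:radius, c = -radius:radius)
  as.matrix(g[g$r^2 + g$c^2 <= radius^2, c("r", "c")]) + radius
}

shape_ellipse <- function(a, b, angle = 0) {
  r <- ceiling(max(a, b))
  g <- expand.grid(r = -r:r, c = -r:r)
  u <- g$c * cos(angle) + g$r * sin(angle)
  v <- -g$c * sin(angle) + g$r * cos(angle)
  as.matrix(g[(u / a)^2 + (v / b)^2 <= 1, c("r", "c")]) + r
}

# Small classifier trained on features harvested from simulated scenes;
# used by the pipeline and end-to-end tests.
make_tiny_model <- function(seed = 4) {
  feats <- harvest_labeled_features(n_sequences = 2, n_frames = 20,
                                    seed = seed, frame_height = 48,
                                    frame_width = 48)
  p <- mea_params(n_superior = 2, n_temporary = 2, group_size = 8,
                  max_generations = 15, patience = 15)
  mea_bp(feats[pipeline_config()$features], feats$label, mea = p,
         epochs = 1500, seed = seed)
}

# The six-sample two-feature ReliefF toy problem: feature 1 separates the
# classes perfectly, feature 2 takes the same values in both classes.
relieff_toy <- function() {
  list(x = cbind(f1 = c(0, 0.1, 0.2, 0.8, 0.9, 1.0),
                 f2 = c(0.3, 0.5, 0.7, 0.3, 0.5, 0.7)),
       y = factor(c("a", "a", "a", "b", "b", "b")))
}
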