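#' Parameters of the per-pixel Gaussian-mixture background model
#'
#' Each pixel's gray value over time is modeled as a mixture of `K`
#' Gaussian components. A new observation matches a component when it lies
#' within `phi` standard deviations of its mean; matched components are
#' updated with learning rate `alpha`, and components are ranked by
#' weight/sigma, the first few (cumulative weight exceeding `T_R`)
#' representing the background.
#'
#' @param K Components per pixel (default 3).
#' @param alpha Learning rate in (0, 1) (default 0.05).
#' @param initial_variance Spread assigned to fresh components, on the
#'   gray-level scale. Interpreted as an initial standard deviation
#'   (so sigma^2 = `initial_variance`^2) unless `variance_is_sigma2`.
#' @param phi Match threshold in standard deviations (default 2.5).
#' @param T_R Background cumulative-weight threshold in (0, 1)
#'   (default 0.25).
#' @param initial_weight_new Weight given to a replacement component
#'   before renormalization (default 0.05): new evidence starts improbable.
#' @param variance_floor Lower bound on component variance (gray^2);
#'   keeps the match criterion and ranking well defined on constant pixels.
#' @param variance_is_sigma2 If `TRUE`, read `initial_variance` directly
#'   as a variance rather than a standard deviation (sensitivity switch).
#' @return An object of class `gmm_params`.
#' @export
gmm_params <- function(K = 3L, alpha = 0.05, initial_variance = 15,
                       phi = 2.5, T_R = 0.25, initial_weight_new = 0.05,
                       variance_floor = 4, variance_is_sigma2 = FALSE) {
  stopifnot(K >= 1, alpha > 0, alpha < 1, phi > 0, T_R > 0, T_R < 1,
            initial_variance > 0, initial_weight_new > 0, variance_floor > 0)
  v0 <- if (variance_is_sigma2) initial_variance else initial_variance^2
  structure(list(K = as.integer(K), alpha = alpha,
                 initial_variance = initial_variance, init_var2 = v0,
                 phi = phi, T_R = T_R,
                 initial_weight_new = initial_weight_new,
                 variance_floor = variance_floor),
            class = "gmm_params")
}

#' A single pixel's Gaussian mixture
#'
#' Components are kept in rank order (descending weight/sigma); empty
#' slots (no evidence yet) carry zero weight and sort last.
#'
#' @param weights,means,variances Numeric vectors of equal length.
#' @param active Logical vector; `FALSE` marks empty slots.
#' @return An object of class `pixel_mixture`.
#' @export
pixel_mixture <- function(weights, means, variances,
                          active = rep(TRUE, length(weights))) {
  stopifnot(length(means) == length(weights),
            length(variances) == length(weights),
            all(weights >= 0), all(variances[active] > 0))
  structure(list(w = as.numeric(weights), u = as.numeric(means),
                 v = as.numeric(variances), active = as.logical(active)),
            class = "pixel_mixture")
}

#' Match an observation against a pixel mixture
#'
#' A component matches when `|x - u| < phi * sigma` (strict inequality).
#' Components are tried in rank order; the first match wins.
#'
#' @param x Observed gray value.
#' @param mixture A [pixel_mixture()], rank-sorted.
#' @param phi Match threshold in standard deviations.
#' @return Index (rank position) of the matched component, or
#'   `NA_integer_` if none matches.
#' @export
match_component <- function(x, mixture, phi = 2.5) {
  ok <- mixture$active & abs(x - mixture$u) < phi * sqrt(mixture$v)
  if (any(ok)) which(ok)[1L] else NA_integer_
}

#' Rank mixture components
#'
#' Descending order of the rank key weight/sigma; empty components last;
#' ties keep the original order (stable).
#'
#' @param mixture A [pixel_mixture()].
#' @return Integer permutation of the component indices.
#' @export
rank_components <- function(mixture) {
  key <- ifelse(mixture$active, mixture$w / sqrt(mixture$v), -Inf)
  order(-key, seq_along(key))  # ties broken by lower index
}

#' Number of background components
#'
#' Over rank-sorted weights, the background is the smallest prefix whose
#' cumulative weight strictly exceeds `T_R`.
#'
#' @param weights Rank-sorted, normalized weight vector (or a
#'   [pixel_mixture()]).
#' @param T_R Threshold in (0, 1).
#' @return Integer `B` with `1 <= B <= K`.
#' @export
background_count <- function(weights, T_R = 0.25) {
  if (inherits(weights, "pixel_mixture")) weights <- weights$w
  cw <- cumsum(weights)
  b <- which(cw > T_R)
  if (length(b)) b[1L] else length(weights)
}

#' Update one pixel's mixture with a new observation
#'
#' If a component matches (first in rank order), its weight is increased,
#' `w_i <- (1 - alpha) w_i + alpha`, all other weights decay by
#' `(1 - alpha)`, and the matched mean and variance move toward the
#' observation with rate `rho = alpha`:
#' `u <- (1 - rho) u + rho x`, `sigma^2 <- (1 - rho) sigma^2 + rho (x - u_new)^2`.
#' If nothing matches, the component with the smallest weight (empty slots
#' first) is replaced by a fresh component centered at `x`. Weights are
#' then renormalized to sum to one and components re-sorted by
#' weight/sigma.
#'
#' @param x Observed gray value.
#' @param mixture A rank-sorted [pixel_mixture()].
#' @param params A [gmm_params()].
#' @return List with `mixture` (updated, re-sorted), `matched` (logical)
#'   and `matched_rank` (pre-update rank of the matched component, or
#'   `NA`).
#' @export
update_pixel <- function(x, mixture, params = gmm_params()) {
  a <- params$alpha
  m <- match_component(x, mixture, params$phi)
  w <- mixture$w; u <- mixture$u; v <- mixture$v; act <- mixture$active
  if (!is.na(m)) {
    w <- (1 - a) * w
    w[m] <- w[m] + a
    rho <- a
    u[m] <- (1 - rho) * u[m] + rho * x
    v[m] <- (1 - rho) * v[m] + rho * (x - u[m])^2
  } else {
    repl <- order(ifelse(act, w, -Inf))[1L]
    w[repl] <- params$initial_weight_new
    u[repl] <- x
    v[repl] <- params$init_var2
    act[repl] <- TRUE
  }
  v <- pmax(v, params$variance_floor)
  w[!act] <- 0
  w <- w / sum(w)
  out <- pixel_mixture(w, u, v, act)
  perm <- rank_components(out)
  out$w <- out$w[perm]; out$u <- out$u[perm]
  out$v <- out$v[perm]; out$active <- out$active[perm]
  list(mixture = out, matched = !is.na(m), matched_rank = m)
}

#' Initialize the background model from the first frame
#'
#' Per pixel, the first component gets the observed gray value as mean,
#' weight one and the configured initial spread; the remaining `K - 1`
#' slots are empty.
#'
#' @param first_frame Numeric matrix of gray values in `[0, 255]`.
#' @param params A [gmm_params()].
#' @return An object of class `bg_model` holding one mixture per pixel
#'   (stored as H x W x K slabs in rank order) and a frame counter.
#' @export
init_model <- function(first_frame, params = gmm_params()) {
  first_frame <- as.matrix(first_frame)
  if (length(first_frame) == 0L) stop("empty frame")
  H <- nrow(first_frame); W <- ncol(first_frame); K <- params$K
  w <- array(0, c(H, W, K)); w[, , 1] <- 1
  u <- array(0, c(H, W, K)); u[, , 1] <- first_frame
  v <- array(params$init_var2, c(H, W, K))
  act <- array(FALSE, c(H, W, K)); act[, , 1] <- TRUE
  structure(list(w = w, u = u, v = v, active = act,
                 t = 1L, params = params, dim = c(H, W)),
            class = "bg_model")
}

#' @export
print.bg_model <- function(x, ...) {
  cat("Per-pixel Gaussian-mixture background model\n")
  cat(sprintf("  frame: %d x %d, K = %d, frames seen: %d\n",
              x$dim[1], x$dim[2], x$params$K, x$t))
  cat(sprintf("  alpha = %g, phi = %g, T_R = %g\n",
              x$params$alpha, x$params$phi, x$params$T_R))
  invisible(x)
}

#' Extract one pixel's mixture from a model
#'
#' @param model A `bg_model`.
#' @param row,col 1-based pixel coordinates.
#' @return A [pixel_mixture()].
#' @export
pixel_at <- function(model, row, col) {
  pixel_mixture(model$w[row, col, ], model$u[row, col, ],
                model$v[row, col, ], model$active[row, col, ])
}

#' Process one frame: classify pixels and update the model
#'
#' For every pixel, the observation is matched against the current
#' (pre-update) mixture in rank order, and the number of background
#' components `B` is computed from the current sorted weights. The pixel
#' is foreground iff no component matched or the matched component ranks
#' below `B`. All pixels are then updated as in [update_pixel()].
#'
#' @param model A `bg_model`.
#' @param frame Numeric matrix matching the model dimensions.
#' @param params Optional [gmm_params()] override; defaults to the
#'   parameters stored in the model.
#' @return List with the updated `model` and `mask`, a logical foreground
#'   matrix.
#' @export
process_frame <- function(model, frame, params = NULL) {
  params <- params %||% model$params
  frame <- as.matrix(frame)
  if (!all(dim(frame) == model$dim)) stop("frame dimensions do not match model")
  H <- model$dim[1]; W <- model$dim[2]; K <- params$K
  npx <- H * W
  x <- as.numeric(frame)
  wm <- matrix(model$w, npx, K); um <- matrix(model$u, npx, K)
  vm <- matrix(model$v, npx, K); am <- matrix(model$active, npx, K)

  # first matching component in rank order (slabs are stored rank-sorted)
  matched <- rep(NA_integer_, npx)
  for (k in seq_len(K)) {
    hit <- is.na(matched) & am[, k] & abs(x - um[, k]) < params$phi * sqrt(vm[, k])
    matched[hit] <- k
  }
  # background component count from the pre-update sorted weights
  B <- rep(NA_integer_, npx)
  cw <- rep(0, npx)
  for (k in seq_len(K)) {
    cw <- cw + wm[, k]
    B[is.na(B) & cw > params$T_R] <- k
  }
  B[is.na(B)] <- K
  fg <- is.na(matched) | matched > B

  # --- update ---
  a <- params$alpha
  has <- !is.na(matched)
  if (any(has)) {
    wm[has, ] <- (1 - a) * wm[has, ]
    mi <- cbind(which(has), matched[has])
    wm[mi] <- wm[mi] + a
    um[mi] <- (1 - a) * um[mi] + a * x[has]
    vm[mi] <- (1 - a) * vm[mi] + a * (x[has] - um[mi])^2
  }
  if (any(!has)) {
    rows <- which(!has)
    wrep <- ifelse(am[rows, , drop = FALSE],
                   wm[rows, , drop = FALSE], -Inf)
    repl <- max.col(-wrep, ties.method = "first")
    ri <- cbind(rows, repl)
    wm[ri] <- params$initial_weight_new
    um[ri] <- x[rows]
    vm[ri] <- params$init_var2
    am[ri] <- TRUE
  }
  vm <- pmax(vm, params$variance_floor)
  wm[!am] <- 0
  wm <- wm / rowSums(wm)

  # stable re-sort by descending w/sigma, empty slots last
  key <- ifelse(am, wm / sqrt(vm), -Inf)
  pos <- matrix(1L, npx, K)
  if (K > 1) {
    for (i in seq_len(K)) for (j in seq_len(K)) {
      if (i == j) next
      pos[, i] <- pos[, i] + (key[, j] > key[, i] | (key[, j] == key[, i] & j < i))
    }
  }
  dst <- cbind(rep(seq_len(npx), K), as.integer(pos))
  w2 <- wm; u2 <- um; v2 <- vm; a2 <- am
  w2[dst] <- wm; u2[dst] <- um; v2[dst] <- vm; a2[dst] <- am

  model$w <- array(w2, c(H, W, K)); model$u <- array(u2, c(H, W, K))
  model$v <- array(v2, c(H, W, K)); model$active <- array(a2, c(H, W, K))
  model$t <- model$t + 1L
  list(model = model, mask = matrix(fg, H, W))
}

#' Run background subtraction over a whole sequence
#'
#' Initializes the model from the first frame and processes the remaining
#' frames, collecting one foreground mask per frame (the first frame's
#' mask is all background by construction).
#'
#' @param frames H x W x n numeric array (or list of matrices).
#' @param params A [gmm_params()].
#' @return List with `masks` (H x W x n logical array) and the final
#'   `model`.
#' @export
subtract_background <- function(frames, params = gmm_params()) {
  if (is.list(frames)) frames <- simplify2array(frames)
  stopifnot(length(dim(frames)) == 3, dim(frames)[3] >= 1)
  n <- dim(frames)[3]
  model <- init_model(frames[, , 1], params)
  masks <- array(FALSE, dim = dim(frames))
  if (n > 1) for (t in 2:n) {
    step <- process_frame(model, frames[, , t])
    model <- step$model
    masks[, , t] <- step$mask
  }
  list(masks = masks, model = model)
}
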