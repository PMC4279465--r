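#' Label connected foreground components
#'
#' Flood-fill labeling of a binary mask under 4- or 8-connectivity.
#' Blobs are numbered 1..k in raster order (top-to-bottom, left-to-right)
#' of their first pixel; components smaller than `min_area` are dropped.
#' Coordinates are 0-based with row = y, col = x.
#'
#' @param mask Logical (or 0/1) matrix.
#' @param connectivity 4 or 8 (default 8).
#' @param min_area Minimum pixel count to keep a blob (default 4).
#' @param frame Optional gray-value matrix from which each blob samples
#'   its member pixels.
#' @return List of `blob` objects: `id`, `coords` (0-based two-column
#'   matrix, row/col), `gray` (if `frame` given), `bbox`
#'   (`rmin, rmax, cmin, cmax`, 0-based inclusive), `area`.
#' @export
label_components <- function(mask, connectivity = 8, min_area = 4,
                             frame = NULL) {
  mask <- as.matrix(mask) != 0
  connectivity <- match.arg(as.character(connectivity), c("8", "4"))
  H <- nrow(mask); W <- ncol(mask)
  nbr <- if (connectivity == "4")
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  else
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  labels <- matrix(0L, H, W)
  nextlab <- 0L
  # scan in raster order (rows, then columns) so label ids follow it
  for (r in seq_len(H)) for (c in seq_len(W)) {
    if (!mask[r, c] || labels[r, c] != 0L) next
    nextlab <- nextlab + 1L
    stack <- matrix(c(r, c), 1L, 2L)
    labels[r, c] <- nextlab
    while (nrow(stack) > 0L) {
      p <- stack[nrow(stack), ]
      stack <- stack[-nrow(stack), , drop = FALSE]
      rr <- p[1] + nbr[, 1]; cc <- p[2] + nbr[, 2]
      ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
      rr <- rr[ok]; cc <- cc[ok]
      idx <- cbind(rr, cc)
      new <- mask[idx] & labels[idx] == 0L
      if (any(new)) {
        labels[idx[new, , drop = FALSE]] <- nextlab
        stack <- rbind(stack, idx[new, , drop = FALSE])
      }
    }
  }
  if (nextlab == 0L) return(list())
  blobs <- list()
  id <- 0L
  for (l in seq_len(nextlab)) {
    which_px <- which(labels == l, arr.ind = TRUE)
    if (nrow(which_px) < min_area) next
    id <- id + 1L
    coords <- cbind(row = which_px[, 1] - 1L, col = which_px[, 2] - 1L)
    b <- structure(list(
      id = id, coords = coords,
      gray = if (!is.null(frame)) as.numeric(frame[which_px]) else NULL,
      bbox = c(rmin = min(coords[, 1]), rmax = max(coords[, 1]),
               cmin = min(coords[, 2]), cmax = max(coords[, 2])),
      area = nrow(coords)), class = "blob")
    blobs[[id]] <- b
  }
  blobs
}

#' Normalized gray-level histogram of a blob
#'
#' `p(k) = n_k / N` over the blob's member pixels only (not its bounding
#' box), for gray levels `k = 0, ..., gray_levels - 1`.
#'
#' @param blob A `blob` with sampled `gray` values, or a numeric vector
#'   of gray values.
#' @param gray_levels Number of gray levels (default 256).
#' @return Numeric vector of length `gray_levels` summing to one.
#' @export
gray_histogram <- function(blob, gray_levels = 256L) {
  g <- if (inherits(blob, "blob")) blob$gray else as.numeric(blob)
  if (is.null(g) || length(g) == 0L) stop("empty blob or no gray values")
  k <- pmin(pmax(as.integer(round(g)), 0L), gray_levels - 1L)
  tabulate(k + 1L, nbins = gray_levels) / length(k)
}

#' Gray-histogram statistics of a blob
#'
#' The six first-order statistics of the normalized histogram `p(k)`:
#' mean gray, gray variance, relative smoothness `R = 1 - 1/(1 + sigma^2)`,
#' third moment, uniformity `U = sum p(k)^2`, and entropy
#' `e = -sum p(k) log2 p(k)` (zero-probability terms contribute zero).
#'
#' @param p Normalized histogram over gray levels `0..length(p)-1`.
#' @return Named numeric vector `mean, var, smooth, m3, unif, entropy`.
#' @export
gray_statistics <- function(p) {
  if (abs(sum(p) - 1) > 1e-6) stop("histogram is not normalized")
  k <- seq_along(p) - 1
  f_bar <- sum(k * p)
  sigma2 <- sum((k - f_bar)^2 * p)
  R <- 1 - 1 / (1 + sigma2)
  u3 <- sum((k - f_bar)^3 * p)
  U <- sum(p^2)
  nz <- p > 0
  e <- -sum(p[nz] * log2(p[nz]))
  c(mean = f_bar, var = sigma2, smooth = R, m3 = u3, unif = U, entropy = e)
}

#' Blob area and bounding-rectangle side ratio
#'
#' Area is the pixel count. The axis-aligned bounding rectangle's extents
#' use the inclusive `max - min + 1` correction so one-pixel-wide shapes
#' get a finite ratio; `W` is the x (column) extent and `L` the y (row)
#' extent, and the ratio is `W / L` (set `invert` to report `L / W`).
#' A rasterized disk — a bubble — has ratio 1.
#'
#' @param blob A `blob`.
#' @param invert Report `L / W` instead of `W / L`.
#' @return Named vector `area, wl_ratio`.
#' @export
geometry <- function(blob, invert = FALSE) {
  bb <- blob$bbox
  Wx <- bb["cmax"] - bb["cmin"] + 1
  Ly <- bb["rmax"] - bb["rmin"] + 1
  ratio <- if (invert) Ly / Wx else Wx / Ly
  c(area = blob$area, wl_ratio = unname(ratio))
}

#' Seven Hu moment invariants of a blob silhouette
#'
#' Central moments `u_pq = sum (x - xbar)^p (y - ybar)^q f(x, y)` are
#' computed on the binary silhouette (`f = 1` on member pixels), then
#' scale-normalized, `eta_pq = u_pq / u_00^((p+q)/2 + 1)`, and combined
#' into the seven standard invariants, which are invariant to
#' translation, rotation and (up to rasterization) scaling. Set
#' `gray_weighted` to use the blob's gray values as `f`.
#'
#' @param blob A `blob`, or a two-column 0-based coordinate matrix
#'   (row, col).
#' @param gray_weighted Weight moments by gray value instead of the
#'   silhouette (requires sampled gray values).
#' @return Named numeric vector `hu1..hu7`.
#' @export
hu_moments <- function(blob, gray_weighted = FALSE) {
  if (inherits(blob, "blob")) {
    coords <- blob$coords
    f <- if (gray_weighted) blob$gray else rep(1, nrow(coords))
  } else {
    coords <- as.matrix(blob)
    f <- rep(1, nrow(coords))
  }
  if (nrow(coords) == 0L) stop("empty blob")
  x <- coords[, 2]; y <- coords[, 1]   # col = x, row = y
  s <- sum(f)
  xb <- sum(x * f) / s; yb <- sum(y * f) / s
  mu <- function(p, q) sum((x - xb)^p * (y - yb)^q * f)
  eta <- function(p, q) mu(p, q) / s^((p + q) / 2 + 1)
  n20 <- eta(2, 0); n02 <- eta(0, 2); n11 <- eta(1, 1)
  n30 <- eta(3, 0); n03 <- eta(0, 3); n21 <- eta(2, 1); n12 <- eta(1, 2)
  h1 <- n20 + n02
  h2 <- (n20 - n02)^2 + 4 * n11^2
  h3 <- (n30 - 3 * n12)^2 + (3 * n21 - n03)^2
  h4 <- (n30 + n12)^2 + (n21 + n03)^2
  h5 <- (n30 - 3 * n12) * (n30 + n12) *
          ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
        (3 * n21 - n03) * (n21 + n03) *
          (3 * (n30 + n12)^2 - (n21 + n03)^2)
  h6 <- (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
        4 * n11 * (n30 + n12) * (n21 + n03)
  h7 <- (3 * n21 - n03) * (n30 + n12) *
          ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
        (n30 - 3 * n12) * (n21 + n03) *
          (3 * (n30 + n12)^2 - (n21 + n03)^2)
  c(hu1 = h1, hu2 = h2, hu3 = h3, hu4 = h4, hu5 = h5, hu6 = h6, hu7 = h7)
}

#' Extract the fifteen-feature descriptor of one blob
#'
#' Six gray-histogram statistics, area, bounding-rectangle side ratio and
#' the seven Hu invariants, in canonical order ([feature_names()]). A
#' pure function of the blob and frame.
#'
#' @param blob A `blob`.
#' @param frame Gray frame to sample pixel values from (unneeded if the
#'   blob already carries them).
#' @param gray_levels Histogram size (default 256).
#' @param invert_ratio Report `L / W` for feature 8.
#' @param gray_weighted_hu Use gray-weighted rather than silhouette Hu
#'   moments.
#' @return Named numeric vector of length 15.
#' @export
extract_features <- function(blob, frame = NULL, gray_levels = 256L,
                             invert_ratio = FALSE, gray_weighted_hu = FALSE) {
  stopifnot(inherits(blob, "blob"))
  if (is.null(blob$gray)) {
    if (is.null(frame)) stop("blob has no gray values and no frame given")
    blob$gray <- as.numeric(frame[blob$coords + 1L])
  }
  gs <- gray_statistics(gray_histogram(blob, gray_levels))
  geo <- geometry(blob, invert = invert_ratio)
  hu <- hu_moments(blob, gray_weighted = gray_weighted_hu)
  stats::setNames(c(gs, geo, hu), feature_names())
}

#' Build a feature table from labeled masks and frames
#'
#' Runs [label_components()] and [extract_features()] over a stack of
#' masks and frames.
#'
#' @param masks H x W x n logical array of foreground masks.
#' @param frames H x W x n gray array.
#' @param frames_used Indices of frames to harvest (default all).
#' @param ... Passed to [label_components()].
#' @return Data frame: `frame`, `blob_id`, the 15 feature columns.
#' @export
blob_feature_table <- function(masks, frames, frames_used = NULL, ...) {
  n <- dim(masks)[3]
  frames_used <- frames_used %||% seq_len(n)
  rows <- list()
  for (t in frames_used) {
    blobs <- label_components(masks[, , t], frame = frames[, , t], ...)
    for (b in blobs) {
      fv <- extract_features(b)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(frame = t, blob_id = b$id), as.data.frame(t(fv)))
    }
  }
  if (!length(rows)) {
    out <- cbind(data.frame(frame = integer(), blob_id = integer()),
                 as.data.frame(matrix(numeric(), 0, 15,
                                      dimnames = list(NULL, feature_names()))))
    return(out)
  }
  do.call(rbind, rows)
}
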