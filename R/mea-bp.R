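#' Three-layer perceptron parameters
#'
#' One hidden layer, sigmoid activations on hidden and output units,
#' one-hot output coding. `W1` is hidden x input, `W2` output x hidden;
#' `b1`, `b2` are the threshold (bias) vectors. The whole parameter set
#' flattens losslessly to a single genome vector (the MEA individual).
#'
#' @param n_in,n_hidden,n_out Layer sizes.
#' @param genome Optional numeric vector to unflatten; if omitted,
#'   parameters are zero.
#' @return Object of class `mlp_parameters`.
#' @export
mlp_parameters <- function(n_in, n_hidden, n_out, genome = NULL) {
  stopifnot(n_in >= 1, n_hidden >= 1, n_out >= 1)
  n_par <- n_hidden * n_in + n_hidden + n_out * n_hidden + n_out
  if (is.null(genome)) genome <- numeric(n_par)
  stopifnot(length(genome) == n_par, all(is.finite(genome)))
  i <- 0L
  take <- function(n) { v <- genome[i + seq_len(n)]; i <<- i + n; v }
  structure(list(
    n_in = n_in, n_hidden = n_hidden, n_out = n_out,
    W1 = matrix(take(n_hidden * n_in), n_hidden, n_in),
    b1 = take(n_hidden),
    W2 = matrix(take(n_out * n_hidden), n_out, n_hidden),
    b2 = take(n_out)), class = "mlp_parameters")
}

#' Flatten perceptron parameters to a genome vector
#' @param mlp An `mlp_parameters` object.
#' @return Numeric vector.
#' @export
mlp_flatten <- function(mlp) {
  c(as.numeric(mlp$W1), mlp$b1, as.numeric(mlp$W2), mlp$b2)
}

#' Forward pass of the perceptron
#'
#' @param mlp An `mlp_parameters` object.
#' @param x Feature matrix (rows = samples, already scaled to `[0, 1]`)
#'   or a single feature vector.
#' @return Matrix of output activations in `(0, 1)`, rows = samples.
#' @export
mlp_forward <- function(mlp, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != mlp$n_in) stop("input size mismatch")
  a1 <- sigmoid(sweep(x %*% t(mlp$W1), 2, mlp$b1, `+`))
  sigmoid(sweep(a1 %*% t(mlp$W2), 2, mlp$b2, `+`))
}

#' Batch evaluation error
#'
#' The mean half-sum-of-squares over the batch:
#' `xi = (1 / 2S) * sum_n sum_j (d_nj - y_nj)^2`. Duplicating the batch
#' leaves it unchanged.
#'
#' @param y Output matrix (rows = samples).
#' @param d Target matrix, same shape.
#' @return Non-negative scalar; zero iff the outputs match exactly.
#' @export
evaluation_xi <- function(y, d) {
  y <- as.matrix(y); d <- as.matrix(d)
  if (!all(dim(y) == dim(d))) stop("shape mismatch")
  if (nrow(y) == 0L) stop("empty batch")
  sum((d - y)^2) / (2 * nrow(y))
}

#' Individual fitness score
#'
#' `f = 1 / xi`; a perfect fit (`xi = 0`) maps to the finite sentinel
#' `1e12` so fitness comparisons stay total.
#'
#' @param xi Non-negative evaluation error.
#' @return Fitness value.
#' @export
score_fitness <- function(xi) {
  stopifnot(xi >= 0)
  if (xi == 0) 1e12 else 1 / xi
}

# Gradient of xi w.r.t. all parameters, as a genome-ordered vector.
mlp_gradient <- function(mlp, x, d) {
  S <- nrow(x)
  a1 <- sigmoid(sweep(x %*% t(mlp$W1), 2, mlp$b1, `+`))
  y <- sigmoid(sweep(a1 %*% t(mlp$W2), 2, mlp$b2, `+`))
  d2 <- ((y - d) / S) * y * (1 - y)
  gW2 <- t(d2) %*% a1
  gb2 <- colSums(d2)
  d1 <- (d2 %*% mlp$W2) * a1 * (1 - a1)
  gW1 <- t(d1) %*% x
  gb1 <- colSums(d1)
  list(grad = c(as.numeric(gW1), gb1, as.numeric(gW2), gb2),
       xi = sum((d - y)^2) / (2 * S))
}

#' Train the perceptron by plain backpropagation
#'
#' Full-batch gradient descent on the evaluation error; stops after
#' `epochs` or when `xi <= target_xi`.
#'
#' @param mlp Starting `mlp_parameters`.
#' @param x Scaled feature matrix.
#' @param d One-hot target matrix.
#' @param lr Learning rate (default 0.1).
#' @param epochs Maximum epochs (default 5000).
#' @param target_xi Early-stopping error (default 1e-3).
#' @return List with the trained `mlp` and `xi_trace` (error per epoch,
#'   including the starting error as element one).
#' @export
bp_train <- function(mlp, x, d, lr = 0.1, epochs = 5000L, target_xi = 1e-3) {
  x <- as.matrix(x); d <- as.matrix(d)
  g <- mlp_flatten(mlp)
  trace <- numeric(0)
  gr <- mlp_gradient(mlp, x, d)
  trace <- gr$xi
  if (epochs >= 1) for (ep in seq_len(epochs)) {
    if (trace[length(trace)] <= target_xi) break
    g <- g - lr * gr$grad
    if (!all(is.finite(g)))
      stop("non-finite parameters during training (learning rate too high?)")
    mlp <- mlp_parameters(mlp$n_in, mlp$n_hidden, mlp$n_out, g)
    gr <- mlp_gradient(mlp, x, d)
    trace <- c(trace, gr$xi)
  }
  list(mlp = mlp, xi_trace = trace)
}

#' Mind Evolutionary Algorithm settings
#'
#' The colony is split into superior and temporary groups of equal size.
#' Similartaxis: each group's individuals are resampled as Gaussian
#' perturbations of the group's best genome and compete locally.
#' Dissimilation: a temporary group whose best score beats the worst
#' superior group's best displaces it, and the displaced group is
#' re-seeded by global random scattering.
#'
#' @param n_superior,n_temporary Number of superior / temporary groups.
#' @param group_size Individuals per group.
#' @param max_generations Generation cap.
#' @param patience Stop after this many generations without improvement
#'   of the global best.
#' @param sigma0 Initial perturbation SD; decays by `sigma_decay` each
#'   generation.
#' @param sigma_decay Multiplicative SD decay per generation.
#' @param init_range Genomes initialized uniformly in
#'   `[-init_range, init_range]`.
#' @return Object of class `mea_params`.
#' @export
mea_params <- function(n_superior = 5L, n_temporary = 5L, group_size = 20L,
                       max_generations = 50L, patience = 20L,
                       sigma0 = 0.5, sigma_decay = 0.95, init_range = 1) {
  stopifnot(n_superior >= 1, n_temporary >= 0, group_size >= 1,
            max_generations >= 1, patience >= 1, sigma0 > 0,
            sigma_decay > 0, sigma_decay <= 1, init_range > 0)
  structure(list(n_superior = as.integer(n_superior),
                 n_temporary = as.integer(n_temporary),
                 group_size = as.integer(group_size),
                 population = (as.integer(n_superior) + as.integer(n_temporary)) *
                   as.integer(group_size),
                 max_generations = as.integer(max_generations),
                 patience = as.integer(patience), sigma0 = sigma0,
                 sigma_decay = sigma_decay, init_range = init_range),
            class = "mea_params")
}

#' Optimize a fitness function with the Mind Evolutionary Algorithm
#'
#' General-purpose maximizer used to find initial network weights; the
#' best-so-far score is non-decreasing across generations and the whole
#' run is deterministic for a fixed seed.
#'
#' @param fitness Function mapping a genome vector to a scalar score
#'   (larger is better).
#' @param n_par Genome length.
#' @param params An [mea_params()].
#' @param seed Integer seed.
#' @return List: `genome` (best found), `score`, `trace` (best-so-far
#'   score per generation), `generations`.
#' @export
mea_optimize <- function(fitness, n_par, params = mea_params(), seed = 1L) {
  stopifnot(inherits(params, "mea_params"), n_par >= 1)
  ng <- params$n_superior + params$n_temporary
  with_seed(seed, {
    scatter <- function(n) matrix(stats::runif(n * n_par, -params$init_range,
                                               params$init_range), n, n_par)
    # initial scattering: best ng individuals become group centers
    init <- scatter(params$population)
    sc <- apply(init, 1, fitness)
    ord <- order(-sc, seq_along(sc))
    centers <- init[ord[seq_len(ng)], , drop = FALSE]
    cscore <- sc[ord[seq_len(ng)]]
    is_superior <- c(rep(TRUE, params$n_superior),
                     rep(FALSE, params$n_temporary))
    best_i <- which.max(cscore)
    best <- centers[best_i, ]; best_score <- cscore[best_i]
    trace <- numeric(0)
    stall <- 0L
    sigma <- params$sigma0
    gens <- 0L
    for (gen in seq_len(params$max_generations)) {
      gens <- gen
      # similartaxis: resample each group around its best, keep the winner
      for (gi in seq_len(ng)) {
        cand <- centers[rep(gi, params$group_size), , drop = FALSE] +
          matrix(stats::rnorm(params$group_size * n_par, 0, sigma),
                 params$group_size, n_par)
        csc <- apply(cand, 1, fitness)
        wi <- which.max(csc)
        if (csc[wi] > cscore[gi]) {
          centers[gi, ] <- cand[wi, ]
          cscore[gi] <- csc[wi]
        }
      }
      # dissimilation: winning temporary groups displace losing superior ones
      if (params$n_temporary > 0) {
        for (ti in which(!is_superior)) {
          ws <- which(is_superior)[which.min(cscore[is_superior])]
          if (cscore[ti] > cscore[ws]) {
            tmp_g <- centers[ws, ]; tmp_s <- cscore[ws]
            centers[ws, ] <- centers[ti, ]; cscore[ws] <- cscore[ti]
            # displaced group is released and re-seeded globally
            centers[ti, ] <- scatter(1)
            cscore[ti] <- fitness(centers[ti, ])
          }
        }
      }
      gbest <- which.max(cscore)
      if (cscore[gbest] > best_score) {
        best <- centers[gbest, ]; best_score <- cscore[gbest]
        stall <- 0L
      } else stall <- stall + 1L
      trace <- c(trace, best_score)
      sigma <- sigma * params$sigma_decay
      if (stall >= params$patience) break
    }
    list(genome = best, score = best_score, trace = trace,
         generations = gens)
  })
}

one_hot <- function(y) {
  y <- as.factor(y)
  d <- matrix(0, length(y), nlevels(y),
              dimnames = list(NULL, levels(y)))
  d[cbind(seq_along(y), as.integer(y))] <- 1
  d
}

scale_minmax <- function(x, rng = NULL) {
  x <- as.matrix(x)
  if (is.null(rng)) rng <- apply(x, 2, range)
  span <- rng[2, ] - rng[1, ]
  span[span == 0] <- 1
  out <- sweep(sweep(x, 2, rng[1, ]), 2, span, `/`)
  attr(out, "rng") <- rng
  out
}

#' Fit the moving-object classifier
#'
#' Fits a three-layer sigmoid perceptron to labeled blob descriptors.
#' With `method = "mea-bp"` (the default) the connection weights and
#' thresholds are first optimized globally by the Mind Evolutionary
#' Algorithm (fitness `1/xi` on the training batch) and then fine-tuned
#' by plain full-batch backpropagation; `method = "bp"` starts from a
#' random genome instead. Features are min-max scaled to `[0, 1]` with
#' ranges learned on the training data and stored in the model.
#'
#' @param x Feature matrix or data frame (or a formula; see
#'   [mea_bp.formula()]).
#' @param y Class labels (factor; levels fix the output order).
#' @param hidden Hidden-layer size (default 5).
#' @param method `"mea-bp"` or `"bp"`.
#' @param mea [mea_params()] for the evolutionary stage.
#' @param lr,epochs,target_xi Backpropagation settings.
#' @param seed Integer seed covering both stages.
#' @param ... Unused.
#' @return Object of class `mea_bp` with `print`, `summary`, `predict`,
#'   `coef` and `plot` methods.
#' @export
mea_bp <- function(x, ...) UseMethod("mea_bp")

#' @rdname mea_bp
#' @export
mea_bp.default <- function(x, y, hidden = 5L, method = c("mea-bp", "bp"),
                           mea = mea_params(), lr = 0.1, epochs = 5000L,
                           target_xi = 1e-3, seed = 1L, ...) {
  method <- match.arg(method)
  x <- as.matrix(x)
  y <- as.factor(y)
  stopifnot(nrow(x) == length(y), hidden >= 1)
  xs <- scale_minmax(x)
  rng <- attr(xs, "rng")
  d <- one_hot(y)
  n_in <- ncol(x); n_out <- nlevels(y)
  n_par <- hidden * n_in + hidden + n_out * hidden + n_out
  fit_xi <- function(g) {
    m <- mlp_parameters(n_in, hidden, n_out, g)
    evaluation_xi(mlp_forward(m, xs), d)
  }
  mea_result <- NULL
  if (method == "mea-bp") {
    mea_result <- mea_optimize(function(g) score_fitness(fit_xi(g)),
                               n_par, mea, seed = seed)
    g0 <- mea_result$genome
  } else {
    g0 <- with_seed(seed, stats::runif(n_par, -mea$init_range, mea$init_range))
  }
  mlp0 <- mlp_parameters(n_in, hidden, n_out, g0)
  bp <- bp_train(mlp0, xs, d, lr = lr, epochs = epochs, target_xi = target_xi)
  yhat <- max.col(mlp_forward(bp$mlp, xs), ties.method = "first")
  obj <- structure(list(
    mlp = bp$mlp, levels = levels(y), features = colnames(x),
    scaling = rng, method = method, seed = seed,
    mea = mea_result, xi_trace = bp$xi_trace,
    train_accuracy = mean(yhat == as.integer(y)),
    call = match.call()), class = "mea_bp")
  obj
}

#' @rdname mea_bp
#' @param formula Model formula such as `label ~ .`.
#' @param data Data frame holding features and the label.
#' @export
mea_bp.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data)
  y <- stats::model.response(mf)
  xm <- mf[, -1L, drop = FALSE]
  mea_bp.default(as.matrix(xm), y, ...)
}

#' @export
print.mea_bp <- function(x, ...) {
  cat("Moving-object classifier (",
      if (x$method == "mea-bp") "MEA-initialized BP network" else "BP network",
      ")\n", sep = "")
  cat(sprintf("  architecture: %d-%d-%d (sigmoid)\n",
              x$mlp$n_in, x$mlp$n_hidden, x$mlp$n_out))
  cat("  classes:", paste(x$levels, collapse = ", "), "\n")
  cat(sprintf("  final training error xi = %.4g, training accuracy = %.1f%%\n",
              x$xi_trace[length(x$xi_trace)], 100 * x$train_accuracy))
  invisible(x)
}

#' @export
summary.mea_bp <- function(object, ...) {
  out <- list(
    architecture = c(object$mlp$n_in, object$mlp$n_hidden, object$mlp$n_out),
    method = object$method, levels = object$levels,
    epochs_run = length(object$xi_trace) - 1L,
    xi_start = object$xi_trace[1], xi_final = object$xi_trace[length(object$xi_trace)],
    train_accuracy = object$train_accuracy,
    mea_generations = if (!is.null(object$mea)) object$mea$generations else NA_integer_,
    mea_best_score = if (!is.null(object$mea)) object$mea$score else NA_real_)
  class(out) <- "summary.mea_bp"
  out
}

#' @export
print.summary.mea_bp <- function(x, ...) {
  cat(sprintf("Architecture %d-%d-%d, method %s\n",
              x$architecture[1], x$architecture[2], x$architecture[3], x$method))
  if (!is.na(x$mea_generations))
    cat(sprintf("MEA: %d generations, best fitness %.4g\n",
                x$mea_generations, x$mea_best_score))
  cat(sprintf("BP: %d epochs, xi %.4g -> %.4g\n",
              x$epochs_run, x$xi_start, x$xi_final))
  cat(sprintf("Training accuracy: %.1f%%\n", 100 * x$train_accuracy))
  invisible(x)
}

#' @export
coef.mea_bp <- function(object, ...) {
  stats::setNames(mlp_flatten(object$mlp),
                  c(outer(seq_len(object$mlp$n_hidden),
                          seq_len(object$mlp$n_in),
                          function(h, i) sprintf("W1[%d,%d]", h, i)),
                    sprintf("b1[%d]", seq_len(object$mlp$n_hidden)),
                    c(outer(seq_len(object$mlp$n_out),
                            seq_len(object$mlp$n_hidden),
                            function(o, h) sprintf("W2[%d,%d]", o, h))),
                    sprintf("b2[%d]", seq_len(object$mlp$n_out))))
}

#' @export
plot.mea_bp <- function(x, ...) {
  graphics::plot(seq_along(x$xi_trace) - 1L, x$xi_trace, type = "l",
                 xlab = "epoch", ylab = expression(xi),
                 main = "Training error", log = "y", ...)
  invisible(x)
}

#' Predict classes or class activations
#'
#' @param object A fitted `mea_bp` model.
#' @param newdata Feature matrix or data frame containing the model's
#'   feature columns.
#' @param type `"class"` (default) or `"prob"` (raw sigmoid activations).
#' @param ... Unused.
#' @return Factor of class calls (ties resolved to the lowest class
#'   index), or the activation matrix.
#' @export
predict.mea_bp <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (is.data.frame(newdata)) {
    if (!is.null(object$features) && all(object$features %in% names(newdata)))
      newdata <- newdata[, object$features, drop = FALSE]
    newdata <- as.matrix(newdata)
  }
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  xs <- scale_minmax(newdata, rng = object$scaling)
  # scaling ranges come from training: clamp unseen values into [0, 1]
  xs <- clamp01(xs)
  y <- mlp_forward(object$mlp, xs)
  colnames(y) <- object$levels
  if (type == "prob") return(y)
  factor(object$levels[max.col(y, ties.method = "first")],
         levels = object$levels)
}

#' Confusion matrix and inspection error rates
#'
#' Builds the row-normalized percentage confusion matrix (rows = true
#' class, columns = decided class) and the inspection rates: the
#' misdetection rate is the fraction of foreign-matter samples decided as
#' the qualified class, the false alarm rate is the fraction of qualified
#' samples decided as any foreign class, and each foreign class's
#' misclassification rate is the fraction of its samples decided as a
#' different foreign class.
#'
#' @param truth True labels (factor or character).
#' @param predicted Decided labels, same levels.
#' @param qualified Name of the qualified (benign) class, default
#'   `"bubble"`.
#' @return Object of class `fm_report`: `confusion` (percent),
#'   `counts`, `misdetection_rate`, `false_alarm_rate`,
#'   `misclassification_rate` (per foreign class), `accuracy` (percent,
#'   overall).
#' @export
confusion_report <- function(truth, predicted, qualified = "bubble") {
  lv <- if (is.factor(truth)) levels(truth) else sort(unique(as.character(truth)))
  truth <- factor(truth, levels = lv)
  predicted <- factor(predicted, levels = lv)
  if (anyNA(truth) || anyNA(predicted)) stop("unknown label")
  if (!qualified %in% lv) stop("unknown qualified class: ", qualified)
  counts <- table(truth = truth, decided = predicted)
  pct <- 100 * sweep(counts, 1, pmax(rowSums(counts), 1), `/`)
  foreign <- setdiff(lv, qualified)
  is_foreign <- truth %in% foreign
  misdet <- if (any(is_foreign))
    100 * mean(predicted[is_foreign] == qualified) else 0
  is_q <- truth == qualified
  falarm <- if (any(is_q)) 100 * mean(predicted[is_q] != qualified) else 0
  miscls <- vapply(foreign, function(k) {
    sel <- truth == k
    if (!any(sel)) return(0)
    100 * mean(predicted[sel] %in% setdiff(foreign, k))
  }, numeric(1))
  structure(list(confusion = pct, counts = counts,
                 misdetection_rate = misdet, false_alarm_rate = falarm,
                 misclassification_rate = miscls,
                 accuracy = 100 * mean(truth == predicted),
                 qualified = qualified),
            class = "fm_report")
}

#' @export
print.fm_report <- function(x, ...) {
  cat("Confusion matrix (% of true class):\n")
  print(round(unclass(x$confusion), 3))
  cat(sprintf("misdetection rate: %.3f%%   false alarm rate: %.3f%%\n",
              x$misdetection_rate, x$false_alarm_rate))
  cat("misclassification rate per foreign class:\n")
  print(round(x$misclassification_rate, 3))
  cat(sprintf("overall accuracy: %.3f%%\n", x$accuracy))
  invisible(x)
}

#' Evaluate a fitted classifier on a labeled set
#'
#' @param object A fitted `mea_bp` model.
#' @param x Feature matrix or data frame.
#' @param y True labels.
#' @param qualified Qualified class name (default `"bubble"`).
#' @return An `fm_report` (see [confusion_report()]).
#' @export
evaluate_classifier <- function(object, x, y, qualified = "bubble") {
  confusion_report(factor(y, levels = object$levels),
                   predict(object, x), qualified = qualified)
}
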