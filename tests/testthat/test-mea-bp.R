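test_that("parameter genomes flatten and unflatten losslessly", {
  set.seed(1)
  g <- rnorm(5 * 3 + 5 + 4 * 5 + 4)
  mlp <- mlp_parameters(3, 5, 4, g)
  expect_identical(mlp_flatten(mlp), g)
  expect_error(mlp_parameters(3, 5, 4, g[-1]))
})

test_that("forward pass symmetries hold", {
  mlp <- mlp_parameters(4, 3, 2)           # all-zero parameters
  y <- mlp_forward(mlp, matrix(runif(8), 2, 4))
  expect_true(all(y == 0.5))
  expect_error(mlp_forward(mlp, matrix(0, 2, 5)), "mismatch")
  # output ignores a feature whose fan-out weights are zero
  set.seed(2)
  g <- rnorm(3 * 4 + 3 + 2 * 3 + 2)
  mlp2 <- mlp_parameters(4, 3, 2, g)
  mlp2$W1[, 2] <- 0
  x1 <- c(0.1, 0.5, 0.9, 0.3)
  x2 <- x1; x2[2] <- 0.99
  expect_identical(mlp_forward(mlp2, x1), mlp_forward(mlp2, x2))
})

test_that("the batch error and fitness score follow their formulas", {
  expect_equal(evaluation_xi(matrix(c(0, 0), 1), matrix(c(1, 0), 1)), 0.5)
  y <- matrix(runif(12), 3, 4)
  expect_equal(evaluation_xi(y, y), 0)
  d <- matrix(runif(12), 3, 4)
  expect_equal(evaluation_xi(rbind(y, y), rbind(d, d)), evaluation_xi(y, d))
  expect_error(evaluation_xi(y, d[1:2, ]), "shape")
  expect_equal(score_fitness(0.5), 2)
  expect_equal(score_fitness(0), 1e12)
  set.seed(3)
  xi <- sort(runif(20, 1e-6, 10))
  expect_true(all(diff(vapply(xi, score_fitness, numeric(1))) < 0))
})

test_that("backprop gradients match central finite differences", {
  set.seed(4)
  n_par <- 4 * 3 + 4 + 2 * 4 + 2
  g <- rnorm(n_par, 0, 0.5)
  x <- matrix(runif(15), 5, 3)
  d <- matrix(rbinom(10, 1, 0.5), 5, 2)
  mlp <- mlp_parameters(3, 4, 2, g)
  analytic <- fminspect:::mlp_gradient(mlp, x, d)$grad
  eps <- 1e-6
  fd <- vapply(seq_len(n_par), function(i) {
    gp <- g; gp[i] <- gp[i] + eps
    gm <- g; gm[i] <- gm[i] - eps
    (evaluation_xi(mlp_forward(mlp_parameters(3, 4, 2, gp), x), d) -
     evaluation_xi(mlp_forward(mlp_parameters(3, 4, 2, gm), x), d)) / (2 * eps)
  }, numeric(1))
  expect_equal(analytic, fd, tolerance = 1e-6)
})

test_that("gradient descent trains a separable toy problem to zero error", {
  set.seed(5)
  x <- rbind(cbind(runif(20, 0, 0.3), runif(20)),
             cbind(runif(20, 0.7, 1), runif(20)))
  d <- rbind(matrix(rep(c(1, 0), each = 20), 20),
             matrix(rep(c(0, 1), each = 20), 20))
  mlp0 <- mlp_parameters(2, 3, 2, runif(2 * 3 + 3 + 2 * 3 + 2, -1, 1))
  out <- bp_train(mlp0, x, d, lr = 0.5, epochs = 5000)
  pred <- max.col(mlp_forward(out$mlp, x))
  expect_equal(pred, max.col(d))
  expect_lt(out$xi_trace[length(out$xi_trace)], out$xi_trace[1])
  # zero epochs leaves the parameters untouched
  same <- bp_train(mlp0, x, d, epochs = 0)
  expect_identical(mlp_flatten(same$mlp), mlp_flatten(mlp0))
})

test_that("the evolutionary stage is deterministic with non-decreasing best score", {
  quad <- function(g) 1 / ((g[1] - 0.3)^2 + 1e-9)
  p <- mea_params(n_superior = 2, n_temporary = 2, group_size = 10,
                  max_generations = 40, patience = 40)
  r1 <- mea_optimize(quad, 1, p, seed = 9)
  r2 <- mea_optimize(quad, 1, p, seed = 9)
  expect_identical(r1$genome, r2$genome)
  expect_true(all(diff(r1$trace) >= 0))
  expect_lt(abs(r1$genome - 0.3), 1e-2)
  # degenerate one-group-of-one config still returns a finite genome
  tiny <- mea_params(n_superior = 1, n_temporary = 0, group_size = 1,
                     max_generations = 10, patience = 10)
  r3 <- mea_optimize(quad, 1, tiny, seed = 1)
  expect_true(is.finite(r3$genome))
})

test_that("seeded end-to-end training is bit-reproducible", {
  d <- generate_feature_dataset(15, seed = 51)
  feats <- c("f02_var", "f06_entropy", "f09_hu1")
  p <- mea_params(n_superior = 2, n_temporary = 2, group_size = 5,
                  max_generations = 10, patience = 10)
  f1 <- mea_bp(d[feats], d$label, hidden = 3, mea = p, epochs = 300, seed = 12)
  f2 <- mea_bp(d[feats], d$label, hidden = 3, mea = p, epochs = 300, seed = 12)
  expect_identical(coef(f1), coef(f2))
  expect_identical(predict(f1, d[feats]), predict(f2, d[feats]))
})

test_that("the formula interface matches the default interface", {
  d <- generate_feature_dataset(10, seed = 52)
  sub <- d[c("f02_var", "f06_entropy", "label")]
  p <- mea_params(n_superior = 1, n_temporary = 1, group_size = 5,
                  max_generations = 5, patience = 5)
  f1 <- mea_bp(label ~ f02_var + f06_entropy, data = sub, hidden = 2,
               mea = p, epochs = 100, seed = 3)
  f2 <- mea_bp(sub[c("f02_var", "f06_entropy")], sub$label, hidden = 2,
               mea = p, epochs = 100, seed = 3)
  expect_equal(coef(f1), coef(f2))
})

test_that("class predictions agree with an independent classifier on easy data", {
  skip_if_not_installed("nnet")
  train <- generate_feature_dataset(30, seed = 53)
  test <- generate_feature_dataset(20, seed = 54)
  feats <- c("f02_var", "f06_entropy", "f09_hu1", "f10_hu2")
  fit <- mea_bp(train[feats], train$label, method = "bp", epochs = 2000,
                seed = 5)
  acc <- mean(predict(fit, test[feats]) == test$label)
  ztr <- scale(train[feats])
  zte <- scale(test[feats], attr(ztr, "scaled:center"),
               attr(ztr, "scaled:scale"))
  set.seed(6)
  nn <- nnet::nnet(x = ztr, y = fminspect:::one_hot(train$label),
                   size = 5, maxit = 1000, decay = 1e-4, trace = FALSE)
  nn_acc <- mean(max.col(predict(nn, zte)) == as.integer(test$label))
  expect_gt(acc, 0.9)
  expect_gt(nn_acc, 0.9)
})

test_that("the confusion report computes inspection rates correctly", {
  lv <- fm_classes()
  perfect <- confusion_report(factor(lv[c(1, 2, 3, 4)], levels = lv),
                              factor(lv[c(1, 2, 3, 4)], levels = lv))
  expect_equal(unname(diag(unclass(perfect$confusion))), rep(100, 4))
  expect_equal(perfect$misdetection_rate, 0)
  expect_equal(perfect$false_alarm_rate, 0)
  expect_equal(unname(perfect$misclassification_rate), rep(0, 3))
  # hand-built 10-sample prediction list
  truth <- factor(c("rubber", "rubber", "hair", "hair", "debris", "debris",
                    "bubble", "bubble", "bubble", "bubble"), levels = lv)
  pred <- factor(c("rubber", "bubble", "hair", "debris", "debris", "debris",
                   "bubble", "rubber", "bubble", "bubble"), levels = lv)
  rep10 <- confusion_report(truth, pred)
  expect_equal(rep10$misdetection_rate, 100 * 1 / 6)   # 1 foreign passed
  expect_equal(rep10$false_alarm_rate, 100 * 1 / 4)    # 1 bubble failed
  expect_equal(unname(rep10$misclassification_rate["hair"]), 50)
  expect_equal(unname(rep10$misclassification_rate["rubber"]), 0)
  expect_equal(unname(rowSums(unclass(rep10$confusion))), rep(100, 4))
  expect_error(confusion_report(truth, pred, qualified = "water"), "unknown")
})

test_that("model files round-trip through JSON", {
  d <- generate_feature_dataset(10, seed = 55)
  feats <- c("f02_var", "f09_hu1")
  fit <- mea_bp(d[feats], d$label, hidden = 2, method = "bp", epochs = 50,
                seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(fit, path)
  back <- load_model(path)
  expect_identical(predict(back, d[feats]), predict(fit, d[feats]))
  expect_equal(coef(back), coef(fit))
})
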