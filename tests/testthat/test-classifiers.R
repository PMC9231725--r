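# Small 2-D synthetic problems keep the grid-search tests fast.
two_blob_data <- function(n = 40L, gap = 4, seed = 3L) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n, mean = 0), ncol = 2),
               matrix(rnorm(n, mean = gap), ncol = 2))
    colnames(X) <- c("f1", "f2")
    list(X = X, y = rep(c(0L, 1L), each = n / 2))
  })
}

test_that("stratified folds partition indices and preserve class balance", {
  y <- rep(c(0L, 1L), c(40L, 60L))
  fold <- stratified_folds(y, 10L, seed = 5L)
  expect_equal(sort(unique(fold)), 1:10)
  expect_equal(tabulate(fold), rep(10L, 10))
  for (f in 1:10) {
    expect_equal(sum(y[fold == f] == 1L), 6L)
  }
  expect_identical(fold, stratified_folds(y, 10L, seed = 5L))
  expect_false(identical(fold, stratified_folds(y, 10L, seed = 6L)))
  expect_error(stratified_folds(y, 1L), "at least 2")
  expect_error(stratified_folds(c(2, 3), 2L), "binary")
})

test_that("SVM separates linearly separable data perfectly", {
  d <- two_blob_data(gap = 6)
  spec <- classifier_spec("svm",
                          grid = data.frame(kernel = "linear",
                                            cost = c(0.1, 1, 10),
                                            gamma = NA_real_,
                                            stringsAsFactors = FALSE),
                          inner_folds = 4L, seed = 2L)
  fitted <- grid_search_fit(spec, d$X, d$y)
  expect_equal(as.integer(predict(fitted, d$X)), d$y)
})

test_that("1-NN memorizes its training points", {
  d <- two_blob_data(gap = 2)
  spec <- classifier_spec("knn", grid = data.frame(k = 1L),
                          inner_folds = 4L, seed = 2L)
  fitted <- grid_search_fit(spec, d$X, d$y, calibrate = FALSE)
  expect_equal(as.integer(predict(fitted, d$X)), d$y)
})

test_that("grid search equals manual inner-CV evaluation of each grid point", {
  d <- two_blob_data(n = 40L, gap = 2.5, seed = 9L)
  grid <- data.frame(k = c(1L, 15L))
  spec <- classifier_spec("knn", grid = grid, inner_folds = 5L, seed = 4L)
  fitted <- grid_search_fit(spec, d$X, d$y, calibrate = FALSE)
  # brute-force oracle: replay the same stratified folds by hand
  fold <- stratified_folds(d$y, 5L, seed = 4L)
  manual <- sapply(grid$k, function(kk) {
    mean(sapply(1:5, function(f) {
      tr <- fold != f
      pred <- class::knn(d$X[tr, ], d$X[!tr, ],
                         cl = factor(d$y[tr], levels = c(0L, 1L)),
                         k = kk, prob = TRUE, use.all = TRUE)
      p <- attr(pred, "prob")
      p_pos <- ifelse(pred == "1", p, 1 - p)
      mean((p_pos > 0.5) == (d$y[!tr] == 1L))
    }))
  })
  expect_equal(unname(fitted$grid_accuracy), unname(manual))
  expect_equal(fitted$chosen$k, grid$k[which.max(manual)])
})

test_that("every family refits deterministically under a fixed seed", {
  d <- two_blob_data(n = 60L, gap = 3, seed = 12L)
  for (alg in c("svm", "naive_bayes", "knn", "gbdt")) {
    grid <- default_grid(alg)[1:2, , drop = FALSE]
    spec <- classifier_spec(alg, grid = grid, inner_folds = 3L, seed = 31L)
    f1 <- grid_search_fit(spec, d$X, d$y)
    f2 <- grid_search_fit(spec, d$X, d$y)
    expect_equal(f1$chosen, f2$chosen)
    expect_equal(f1$calibration, f2$calibration)
    expect_identical(predict(f1, d$X, type = "probability"),
                     predict(f2, d$X, type = "probability"))
  }
})

test_that("grid search validates its inputs", {
  d <- two_blob_data()
  spec <- classifier_spec("knn", grid = data.frame(k = 3L),
                          inner_folds = 4L)
  expect_error(grid_search_fit(spec, d$X, rep(1L, nrow(d$X))),
               "both classes")
  few <- c(1:3, 21:23)  # both classes present but too few rows
  expect_error(grid_search_fit(spec, d$X[few, ], d$y[few]),
               "2 observations per inner fold")
  expect_error(classifier_spec("knn", grid = data.frame()), "non-empty")
  expect_error(classifier_spec("knn", inner_folds = 1L), "at least 2")
})

test_that("Platt probabilities sit at 0.5 on the sigmoid midpoint and are monotone", {
  d <- two_blob_data(n = 80L, gap = 3)
  spec <- classifier_spec("svm",
                          grid = data.frame(kernel = "linear", cost = 1,
                                            gamma = NA_real_,
                                            stringsAsFactors = FALSE),
                          inner_folds = 4L, seed = 6L)
  fitted <- grid_search_fit(spec, d$X, d$y)
  cal <- fitted$calibration
  midpoint <- -cal$intercept / cal$slope
  expect_equal(stats::plogis(cal$intercept + cal$slope * midpoint), 0.5)
  dv <- predict(fitted, d$X, type = "decision")
  p <- predict(fitted, d$X, type = "probability")
  expect_true(all(p > 0 & p < 1))
  ord <- order(dv)
  expect_true(all(diff(p[ord]) * sign(cal$slope) >= 0))
  # calibrated probabilities are order-isomorphic to decision values
  expect_equal(order(p), order(dv * sign(cal$slope)))
  # probability output demands calibration
  uncal <- grid_search_fit(spec, d$X, d$y, calibrate = FALSE)
  expect_error(predict(uncal, d$X, type = "probability"),
               "no Platt calibration")
})

test_that("Platt scaling recovers generating probabilities on logistic data", {
  withr::with_seed(77, {
    n <- 2000L
    dv <- rnorm(n, 0, 2)
    p_true <- stats::plogis(1.2 * dv - 0.4)
    y <- as.integer(runif(n) < p_true)
    cal <- caaxpred:::fit_platt(dv, y)
    p_hat <- stats::plogis(cal$intercept + cal$slope * dv)
    expect_lt(max(abs(p_hat - p_true)), 0.1)
  })
})

test_that("all four families exceed 95% CV accuracy on a fully separated screen", {
  scr <- separable_screen(n = 200L, seed = 7L)
  X <- encode_onehot(scr$motif)
  red <- fit_pca(X, 0.99)
  Xr <- pca_transform(red, X)
  grids <- list(
    svm = data.frame(kernel = "radial", cost = 10, gamma = NA_real_,
                     stringsAsFactors = FALSE),
    naive_bayes = data.frame(var_smoothing = 1e-9),
    knn = data.frame(k = 7L),
    gbdt = data.frame(nrounds = 100L, max_depth = 2L, eta = 0.1)
  )
  for (alg in names(grids)) {
    spec <- classifier_spec(alg, grid = grids[[alg]], seed = 7L)
    cv <- cross_validate(classifier_trainer(spec), unclass(Xr), scr$truth,
                         k = 10L, seed = 7L)
    expect_gte(cv$mean[["accuracy"]], 0.95)
  }
})
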