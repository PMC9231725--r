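# Evaluate expr under a fixed RNG seed without disturbing the caller's RNG.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Stratified fold assignment
#'
#' Assigns each observation to one of `k` folds, preserving the class ratio
#' in every fold; deterministic under `seed`.
#'
#' @param labels Binary labels (0/1, logical, or 2-level factor).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in 1..k.
#' @export
stratified_folds <- function(labels, k, seed = 1L) {
  y <- as_binary_labels(labels)
  if (k < 2L) stop("k must be at least 2")
  if (k > length(y)) stop("more folds than observations")
  fold <- integer(length(y))
  with_local_seed(seed, {
    # the round-robin counter continues across classes so every fold is
    # filled even when a class has fewer members than there are folds
    # (e.g. leave-one-out)
    offset <- 0L
    for (cls in sort(unique(y))) {
      idx <- sample(which(y == cls))
      fold[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
      offset <- offset + length(idx)
    }
  })
  fold
}

as_binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.logical(labels)) labels <- as.integer(labels)
  if (is.character(labels)) {
    u <- sort(unique(labels))
    if (!all(u %in% c("0", "1"))) {
      stop("labels must be coercible to 0/1; got: ",
           paste(u, collapse = ", "))
    }
    labels <- as.integer(labels)
  }
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  as.integer(labels)
}

#' Default hyperparameter grids for the four classifier families
#'
#' SVM: linear and radial kernels, cost 0.1/1/10/100, radial width from the
#' scale heuristic (NA) or 0.01/0.001. kNN: k in 3/5/7/11/15. GBDT: 100 or
#' 300 trees, depth 2/3, learning rate 0.05/0.1. Naive Bayes: Gaussian
#' likelihood with variance smoothing 1e-9/1e-6 (fraction of the largest
#' feature variance added to every class variance).
#'
#' @param algorithm One of `"svm"`, `"naive_bayes"`, `"knn"`, `"gbdt"`.
#' @return data.frame, one row per grid point.
#' @export
default_grid <- function(algorithm = c("svm", "naive_bayes", "knn", "gbdt")) {
  algorithm <- match.arg(algorithm)
  switch(algorithm,
    svm = rbind(
      expand.grid(kernel = "linear", cost = c(0.1, 1, 10, 100),
                  gamma = NA_real_, stringsAsFactors = FALSE),
      expand.grid(kernel = "radial", cost = c(0.1, 1, 10, 100),
                  gamma = c(NA_real_, 0.01, 0.001), stringsAsFactors = FALSE)
    ),
    knn = data.frame(k = c(3L, 5L, 7L, 11L, 15L)),
    gbdt = expand.grid(nrounds = c(100L, 300L), max_depth = c(2L, 3L),
                       eta = c(0.05, 0.1)),
    naive_bayes = data.frame(var_smoothing = c(1e-9, 1e-6))
  )
}

#' Specification of a classifier family with its search grid
#'
#' @param algorithm One of `"svm"`, `"naive_bayes"`, `"knn"`, `"gbdt"`.
#' @param grid data.frame of hyperparameter candidates (default
#'   [default_grid()]); must be non-empty.
#' @param inner_folds Stratified folds for the grid search (default 5).
#' @param seed Integer seed controlling fold assignment and any stochastic
#'   fitting.
#' @return List of class `classifier_spec`.
#' @export
classifier_spec <- function(algorithm = c("svm", "naive_bayes", "knn", "gbdt"),
                            grid = NULL, inner_folds = 5L, seed = 1L) {
  algorithm <- match.arg(algorithm)
  if (is.null(grid)) grid <- default_grid(algorithm)
  if (!is.data.frame(grid) || nrow(grid) == 0L) {
    stop("hyperparameter grid must be a non-empty data.frame")
  }
  if (inner_folds < 2L) stop("inner_folds must be at least 2")
  structure(list(algorithm = algorithm, grid = grid,
                 inner_folds = as.integer(inner_folds),
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

scale_gamma <- function(X) {
  v <- mean(apply(X, 2L, stats::var))
  if (!is.finite(v) || v <= 0) v <- 1
  1 / (ncol(X) * v)
}

fit_algo <- function(algorithm, params, X, y, seed) {
  y <- as_binary_labels(y)
  switch(algorithm,
    svm = {
      gamma <- params$gamma
      if (is.null(gamma) || is.na(gamma)) gamma <- scale_gamma(X)
      e1071::svm(x = X, y = factor(y, levels = c(0L, 1L)),
                 kernel = as.character(params$kernel), cost = params$cost,
                 gamma = gamma, scale = FALSE)
    },
    knn = list(X = X, y = y, k = params$k),
    naive_bayes = {
      fit <- e1071::naiveBayes(x = as.data.frame(X),
                               y = factor(y, levels = c(0L, 1L)))
      # variance smoothing: floor every class sd at a fraction of the
      # largest overall feature variance (stabilizes near-constant columns)
      vmax <- max(apply(X, 2L, stats::var))
      floor_sd <- sqrt(params$var_smoothing * max(vmax, .Machine$double.eps))
      fit$tables <- lapply(fit$tables, function(tab) {
        tab[, 2L] <- pmax(tab[, 2L], floor_sd)
        tab
      })
      fit
    },
    gbdt = {
      dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1L)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = params$max_depth, eta = params$eta,
                      nthread = 1L, seed = seed),
        data = dtrain, nrounds = params$nrounds, verbose = 0
      )
    },
    stop("unknown algorithm: ", algorithm)
  )
}

decide_algo <- function(algorithm, model, X) {
  switch(algorithm,
    svm = {
      pred <- stats::predict(model, X, decision.values = TRUE)
      dv <- as.numeric(attr(pred, "decision.values"))
      # libsvm orients the decision value toward the first training class
      if (startsWith(colnames(attr(pred, "decision.values"))[1], "0")) {
        dv <- -dv
      }
      dv
    },
    knn = {
      pred <- class::knn(train = model$X, test = X,
                         cl = factor(model$y, levels = c(0L, 1L)),
                         k = model$k, prob = TRUE, use.all = TRUE)
      p_win <- attr(pred, "prob")
      p_pos <- ifelse(pred == "1", p_win, 1 - p_win)
      p_pos - 0.5
    },
    naive_bayes = {
      raw <- stats::predict(model, as.data.frame(X), type = "raw")
      log(pmax(raw[, "1"], 1e-300)) - log(pmax(raw[, "0"], 1e-300))
    },
    gbdt = stats::predict(model, X, outputmargin = TRUE)
  )
}

#' Fit a classifier with stratified grid search
#'
#' Every grid point is scored by mean accuracy over stratified inner
#' cross-validation folds (seeded by `spec$seed`); the best point (ties go
#' to the earlier grid row) is refit on all data. Platt-scaling sigmoid
#' parameters are then fit on cross-validated decision values (never on
#' resubstitution values), using the standard smoothed targets
#' `(n1 + 1)/(n1 + 2)` and `1/(n0 + 2)`.
#'
#' @param spec A [classifier_spec()].
#' @param features Numeric feature matrix (rows = motifs).
#' @param labels Binary labels.
#' @param calibrate Fit Platt-scaling parameters (default TRUE).
#' @return List of class `caax_classifier`: `spec`, `chosen` (best grid
#'   row), `grid_accuracy`, `model`, `calibration` (intercept/slope or
#'   NULL), `scheme`.
#' @export
grid_search_fit <- function(spec, features, labels, calibrate = TRUE) {
  stopifnot(inherits(spec, "classifier_spec"))
  y <- as_binary_labels(labels)
  X <- unclass(features)
  if (is.null(dim(X))) stop("features must be a matrix")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (nrow(X) < 2L * spec$inner_folds) {
    stop("need at least 2 observations per inner fold")
  }
  fold <- stratified_folds(y, spec$inner_folds, spec$seed)
  grid_acc <- vapply(seq_len(nrow(spec$grid)), function(g) {
    params <- as.list(spec$grid[g, , drop = FALSE])
    accs <- vapply(seq_len(spec$inner_folds), function(f) {
      tr <- fold != f
      model <- fit_algo(spec$algorithm, params, X[tr, , drop = FALSE],
                        y[tr], seed = spec$seed + f)
      dv <- decide_algo(spec$algorithm, model, X[!tr, , drop = FALSE])
      mean((dv > 0) == (y[!tr] == 1L))
    }, numeric(1))
    mean(accs)
  }, numeric(1))
  best <- which.max(grid_acc)
  params <- as.list(spec$grid[best, , drop = FALSE])
  model <- fit_algo(spec$algorithm, params, X, y, seed = spec$seed)

  calibration <- NULL
  if (calibrate) {
    dv_cv <- rep(NA_real_, length(y))
    for (f in seq_len(spec$inner_folds)) {
      tr <- fold != f
      m_f <- fit_algo(spec$algorithm, params, X[tr, , drop = FALSE], y[tr],
                      seed = spec$seed + f)
      dv_cv[!tr] <- decide_algo(spec$algorithm, m_f, X[!tr, , drop = FALSE])
    }
    calibration <- fit_platt(dv_cv, y)
  }
  structure(
    list(spec = spec, chosen = params,
         grid_accuracy = grid_acc, model = model,
         calibration = calibration,
         scheme = attr(features, "scheme")),
    class = "caax_classifier"
  )
}

# Platt (1999) sigmoid fit with smoothed targets; returns intercept and
# slope of P(y = 1 | d) = plogis(intercept + slope * d).
fit_platt <- function(decision, y) {
  y <- as_binary_labels(y)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  target <- ifelse(y == 1L, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))
  fit <- suppressWarnings(
    stats::glm(target ~ decision, family = stats::quasibinomial())
  )
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]))
}

#' @export
print.caax_classifier <- function(x, ...) {
  ch <- paste(names(x$chosen), vapply(x$chosen, format, character(1)),
              sep = "=", collapse = ", ")
  cat(sprintf("<caax_classifier: %s>  chosen: %s%s\n", x$spec$algorithm, ch,
              if (is.null(x$calibration)) "" else "  [Platt-calibrated]"))
  invisible(x)
}

#' Predict with a fitted classifier
#'
#' `type = "call"` returns binary calls: probability > 0.5 for calibrated
#' models, sign of the decision value otherwise. `type = "decision"`
#' returns raw decision values; `type = "probability"` returns
#' Platt-calibrated probabilities and errors on uncalibrated models.
#'
#' @param object A `caax_classifier`.
#' @param features Feature matrix encoded with the same scheme used for
#'   training.
#' @param type `"call"`, `"probability"` or `"decision"`.
#' @param ... Unused.
#' @return Logical (call), or numeric vector.
#' @export
predict.caax_classifier <- function(object, features,
                                    type = c("call", "probability",
                                             "decision"), ...) {
  type <- match.arg(type)
  sch <- attr(features, "scheme")
  if (!is.null(sch) && !is.null(object$scheme) && sch != object$scheme) {
    stop("feature scheme mismatch: classifier trained on '", object$scheme,
         "', given '", sch, "'")
  }
  dv <- decide_algo(object$spec$algorithm, object$model, unclass(features))
  if (type == "decision") return(dv)
  if (type == "probability" || !is.null(object$calibration)) {
    if (is.null(object$calibration)) {
      stop("classifier has no Platt calibration; refit with calibrate = TRUE")
    }
    p <- stats::plogis(object$calibration$intercept +
                         object$calibration$slope * dv)
    if (type == "probability") return(p)
    return(p > 0.5)
  }
  dv > 0
}
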