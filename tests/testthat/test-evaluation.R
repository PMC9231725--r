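test_that("metric formulas match hand-worked confusion tables", {
  perfect <- compute_metrics(tp = 5, fp = 0, tn = 5, fn = 0)
  expect_equal(perfect[c("accuracy", "precision", "recall", "f1")],
               list(accuracy = 1, precision = 1, recall = 1, f1 = 1))
  expect_length(perfect$undefined, 0L)

  all_neg <- compute_metrics(tp = 0, fp = 0, tn = 5, fn = 5)
  expect_equal(all_neg$accuracy, 0.5)
  expect_equal(all_neg$precision, 0)
  expect_equal(all_neg$recall, 0)
  expect_setequal(all_neg$undefined, c("precision", "f1"))

  mixed <- compute_metrics(tp = 3, fp = 1, tn = 4, fn = 2)
  expect_equal(mixed$accuracy, 0.7)
  expect_equal(mixed$precision, 0.75)
  expect_equal(mixed$recall, 0.6)
  expect_equal(mixed$f1, 2 / 3, tolerance = 1e-12)

  expect_error(compute_metrics(0, 0, 0, 0), "all zero")
  expect_error(compute_metrics(-1, 0, 1, 0), "non-negative")
})

test_that("metrics agree with direct formula evaluation on random tables", {
  set.seed(21)
  for (i in 1:2000) {
    cc <- sample(0:30, 4, replace = TRUE)
    if (sum(cc) == 0) next
    m <- compute_metrics(cc[1], cc[2], cc[3], cc[4])
    expect_equal(m$accuracy, (cc[1] + cc[3]) / sum(cc))
    prec <- if (cc[1] + cc[2] == 0) 0 else cc[1] / (cc[1] + cc[2])
    rec <- if (cc[1] + cc[4] == 0) 0 else cc[1] / (cc[1] + cc[4])
    expect_equal(m$precision, prec)
    expect_equal(m$recall, rec)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    expect_equal(m$f1, f1)
  }
})

test_that("cross-validation folds cover every index exactly once", {
  sets <- cached_sets()
  tm <- training_matrix(sets$prenylation)
  fold <- stratified_folds(tm$labels, 10L, seed = 3L)
  expect_length(fold, length(tm$labels))
  expect_equal(sort(unique(fold)), 1:10)
  # a constant always-positive trainer scores the class fraction
  trainer <- function(x, y) function(x_new) {
    rep(TRUE, if (is.null(dim(x_new))) length(x_new) else nrow(x_new))
  }
  cv <- cross_validate(trainer, tm$motifs, tm$labels, k = 10L, seed = 3L)
  expect_equal(cv$mean[["accuracy"]], mean(tm$labels == 1L),
               tolerance = 0.01)
  expect_equal(cv$mean[["recall"]], 1)
  expect_equal(nrow(cv$per_fold), 10L)
})

test_that("leave-one-out equals a hand-run fold loop on a 6-point set", {
  motifs <- c("CVIA", "CVIL", "CVIM", "CDDD", "CEED", "CDKE")
  labels <- c(1L, 1L, 1L, 0L, 0L, 0L)
  nearest_trainer <- function(x, y) {
    train_x <- x; train_y <- y
    function(x_new) {
      vapply(x_new, function(m) {
        d <- vapply(train_x, function(t) {
          sum(strsplit(m, "")[[1]] != strsplit(t, "")[[1]])
        }, numeric(1))
        train_y[which.min(d)] == 1L
      }, logical(1))
    }
  }
  cv <- cross_validate(nearest_trainer, motifs, labels, k = 6L, seed = 2L)
  fold <- stratified_folds(labels, 6L, seed = 2L)
  manual_acc <- sapply(1:6, function(f) {
    pred <- nearest_trainer(motifs[fold != f], labels[fold != f])
    mean(as.integer(pred(motifs[fold == f])) == labels[fold == f])
  })
  expect_equal(unname(cv$per_fold$accuracy), unname(manual_acc))
})

test_that("cross-validation rejects degenerate inputs", {
  expect_error(cross_validate(function(x, y) identity, c("CVIA", "CVIL"),
                              c(1L, 1L), k = 2L), "both classes")
  expect_error(cross_validate(function(x, y) identity,
                              c("CVIA", "CVIL", "CDDD"), c(1L, 1L, 0L),
                              k = 5L), "more folds")
})

test_that("PSSM resubstitution accuracy is at least its CV accuracy", {
  sets <- cached_sets()
  tm <- training_matrix(sets$prenylation)
  model <- train_pssm(sets$prenylation)
  resub <- mean((call_pssm(model, tm$motifs)) == (tm$labels == 1L))
  cv_accs <- sapply(1:5, function(s) {
    cross_validate(pssm_trainer(), tm$motifs, tm$labels, 10L,
                   seed = s)$mean[["accuracy"]]
  })
  expect_gte(resub, mean(cv_accs) - 1e-9)
})

test_that("validation tallies reproduce the empirical agreement counts", {
  vt <- validation_fixture()
  t3 <- vt[vt$panel == "proteome", ]

  svm3 <- tally_validation(t3, "svm", "prenylation")
  expect_equal(svm3$matches, 16L)
  expect_equal(svm3$eligible, 19L)
  expect_equal(svm3$percent, 100 * 16 / 19, tolerance = 1e-10)

  svm_all <- tally_validation(vt, "svm", "prenylation")
  expect_equal(svm_all$matches, 25L)
  expect_equal(svm_all$eligible, 31L)
  expect_equal(round(svm_all$percent), 81)

  expect_equal(tally_validation(t3, "preps", "prenylation")$matches, 15L)
  expect_equal(tally_validation(t3, "freq", "prenylation")$matches, 14L)
  expect_equal(tally_validation(t3, "fpb", "prenylation")$matches, 11L)
  expect_equal(tally_validation(vt, "preps", "prenylation")$matches, 19L)
  expect_equal(tally_validation(vt, "freq", "prenylation")$matches, 24L)
  expect_equal(tally_validation(vt, "fpb", "prenylation")$matches, 11L)

  # cleavage is tallied only over the 14 motifs observed prenylated
  freq_clv <- tally_validation(t3, "freq", "cleavage")
  expect_equal(freq_clv$eligible, 14L)
  expect_equal(freq_clv$matches, 13L)
  expect_equal(freq_clv$percent, 100 * 13 / 14, tolerance = 1e-10)
  svm_clv <- tally_validation(t3, "svm", "cleavage")
  expect_equal(svm_clv$matches, 10L)

  expect_error(tally_validation(vt, "preps", "cleavage"), "no cleavage")
  expect_error(tally_validation(vt[0, ], "svm", "prenylation"), "empty")
})

test_that("disjoint validation tables combine additively", {
  vt <- validation_fixture()
  a <- tally_validation(vt[vt$panel == "proteome", ], "svm", "prenylation")
  b <- tally_validation(vt[vt$panel == "reporter", ], "svm", "prenylation")
  all_rows <- tally_validation(vt, "svm", "prenylation")
  expect_equal(a$matches + b$matches, all_rows$matches)
  expect_equal(a$eligible + b$eligible, all_rows$eligible)
  expect_lte(all_rows$matches, all_rows$eligible)
})

test_that("false-call rates use the method's own calls as denominators", {
  vt <- validation_fixture()
  svm <- false_rate_summary(vt, "svm", "prenylation")
  expect_equal(svm$positive_calls, 20L)
  expect_equal(svm$wrong_positive, 0L)
  expect_equal(svm$false_positive, 0)
  expect_equal(svm$negative_calls, 11L)
  expect_equal(svm$wrong_negative, 6L)
  expect_equal(svm$false_negative, 6 / 11, tolerance = 1e-12)

  fpb <- false_rate_summary(vt, "fpb", "prenylation")
  expect_equal(fpb$positive_calls, 6L)
  expect_equal(fpb$wrong_negative, 20L)
  expect_equal(fpb$negative_calls, 25L)

  # toy table with hand tallies
  toy <- data.frame(
    motif = c("CAAA", "CAAC", "CAAD", "CAAE"),
    svm = c("+", "+", "-", "-"),
    observed_prenylation = c("+", "-", "+", "-"),
    stringsAsFactors = FALSE
  )
  rates <- false_rate_summary(toy, "svm", "prenylation")
  expect_equal(rates$false_positive, 1 / 2)
  expect_equal(rates$false_negative, 1 / 2)

  all_right <- toy
  all_right$svm <- all_right$observed_prenylation
  rates2 <- false_rate_summary(all_right, "svm", "prenylation")
  expect_equal(rates2$false_positive, 0)
  expect_equal(rates2$false_negative, 0)

  # zero calls of a class is flagged undefined
  all_pos <- toy
  all_pos$svm <- "+"
  rates3 <- false_rate_summary(all_pos, "svm", "prenylation")
  expect_true(is.na(rates3$false_negative))
  expect_equal(rates3$undefined, "false_negative")
})

test_that("cleavage observations on non-prenylated motifs are rejected", {
  bad <- data.frame(motif = "CAAA", svm = "+", observed_prenylation = "-",
                    svm_cleave = "+", freq_cleave = "+",
                    observed_cleavage = "+", stringsAsFactors = FALSE)
  expect_error(tally_validation(bad, "svm", "prenylation"),
               "prenyl")
})
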