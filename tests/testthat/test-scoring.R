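test_that("the BLOSUM62 background is a proper distribution with known marginals", {
  bg <- background_from_blosum62()
  expect_equal(sum(bg), 1, tolerance = 1e-12)
  expect_true(all(bg > 0))
  expect_named(bg, AA_ALPHABET)
  # independently summed rows of the published joint-frequency table
  q <- blosum62_frequencies()
  manual <- rowSums(q) / sum(q)
  expect_equal(bg, manual)
  # spot checks against the published marginal frequencies
  expect_equal(unname(bg["A"]), 0.074, tolerance = 0.01)
  expect_equal(unname(bg["L"]), 0.099, tolerance = 0.01)
  expect_equal(unname(bg["W"]), 0.013, tolerance = 0.03)
  expect_true(bg["L"] == max(bg) && bg["W"] == min(bg))
})

test_that("PSSM log-odds match hand evaluation of the pseudocount formula", {
  sets <- toy_pssm_sets()
  model <- fit_pssm(sets$positives, uniform_background(), pseudocount = 0.05)
  # x1 = V in both of 2 motifs: ln(((2 + 0.05) / (2 + 1)) / 0.05)
  expect_equal(unname(model$log_odds["x1", "V"]),
               log((2.05 / 3) / 0.05), tolerance = 1e-12)
  expect_equal(unname(model$log_odds["x1", "V"]), 2.615, tolerance = 1e-3)
  # x3 splits A/S: ln(((1 + 0.05) / 3) / 0.05) each
  expect_equal(unname(model$log_odds["x3", "A"]), log((1.05 / 3) / 0.05))
  expect_equal(unname(model$log_odds["x3", "A"]),
               unname(model$log_odds["x3", "S"]))
  # unseen residue scores below zero against a common background
  expect_lt(model$log_odds["x1", "A"], 0)
  expect_equal(unname(model$log_odds["x1", "A"]), log((0.05 / 3) / 0.05))
})

test_that("PSSM scores are positionwise sums and symmetric fits agree", {
  sets <- toy_pssm_sets()
  model <- fit_pssm(sets$positives, uniform_background(), 0.05)
  s <- score_pssm(model, c("CVIA", "CVIS"))
  expected <- 2 * log((2.05 / 3) / 0.05) + log((1.05 / 3) / 0.05)
  expect_equal(unname(s["CVIA"]), expected, tolerance = 1e-12)
  expect_equal(unname(s["CVIA"]), 7.18, tolerance = 1e-2)
  expect_equal(unname(s["CVIA"]), unname(s["CVIS"]))  # fit is symmetric
  # additivity: a single-position substitution shifts the score by the
  # difference of the two log-odds entries
  d <- score_pssm(model, "CVIW") - score_pssm(model, "CVIA")
  expect_equal(unname(d), unname(model$log_odds["x3", "W"] -
                                   model$log_odds["x3", "A"]))
  # zero log-odds scores zero
  zero <- model
  zero$log_odds[] <- 0
  expect_equal(unname(score_pssm(zero, "CWWW")), 0)
})

test_that("a uniform positive set gives vanishing log-odds as n grows", {
  model <- fit_pssm(paste0("C", AA_ALPHABET, AA_ALPHABET, AA_ALPHABET),
                    uniform_background(), pseudocount = 0.05)
  expect_true(all(abs(model$log_odds) < 1e-12))
})

test_that("pseudocount domination drives log-odds to the prior limit", {
  sets <- toy_pssm_sets()
  bg <- background_from_blosum62()
  model <- fit_pssm(sets$positives, bg, pseudocount = 1e8)
  limit <- matrix(log((1 / 20) / bg), nrow = 3, ncol = 20, byrow = TRUE)
  expect_equal(unname(model$log_odds), unname(limit), tolerance = 1e-6)
})

test_that("cutoff calibration equals exhaustive threshold search", {
  expect_equal(calibrate_cutoff(c(2, 3), c(0, 1)), 1.5)
  # inseparable degenerate case returns the smallest sentinel
  expect_equal(calibrate_cutoff(1, 1), 0)
  brute_force <- function(sp, sn) {
    cands <- sort(unique(c(sp, sn)))
    cands <- c(cands - 1e-9, cands + 1e-9)
    acc <- sapply(cands, function(t) sum(sp > t) + sum(sn <= t))
    best <- max(acc)
    min(cands[acc == best])
  }
  set.seed(13)
  for (i in 1:20) {
    sp <- round(rnorm(sample(3:50, 1), mean = 1), 2)
    sn <- round(rnorm(sample(3:50, 1), mean = -1), 2)
    t_pkg <- calibrate_cutoff(sp, sn)
    t_ref <- brute_force(sp, sn)
    acc_of <- function(t) sum(sp > t) + sum(sn <= t)
    expect_equal(acc_of(t_pkg), acc_of(t_ref))
  }
})

test_that("trained PSSM separates a separable toy problem", {
  sets <- toy_pssm_sets()
  ts <- curate_prenylation_sets(sets$positives, character(), sets$negatives,
                                curation_config())
  model <- train_pssm(ts, uniform_background())
  expect_true(all(call_pssm(model, sets$positives)))
  expect_false(any(call_pssm(model, sets$negatives)))
  expect_error(call_pssm(fit_pssm("CVIA"), "CVIA"), "calibrated")
})

test_that("Freq scoring matches hand-computed log2 ratios", {
  pos <- c("CVIA", "CVIS", "CVLA")
  neg <- c("CDDD", "CDDS", "CEDD")
  model <- fit_freq(pos, neg, pseudocount = 0.05, task = "prenylation")
  n <- 3 + 20 * 0.05
  hand <- function(cp, cn) log2(((cp + 0.05) / n) / ((cn + 0.05) / n))
  # CVDD: x1 V = 3 pos / 0 neg; x2 D = 0 pos / 3 neg; x3 D = 0 pos / 2 neg
  s <- score_freq(model, "CVDD")
  expect_equal(unname(s), hand(3, 0) + hand(0, 3) + hand(0, 2))
  # identical sets give zero scores and negative calls at threshold 0
  same <- fit_freq(pos, pos, task = "cleavage")
  expect_true(all(score_freq(same, c("CVIA", "CWWW")) == 0))
  expect_false(any(call_freq(same, c("CVIA", "CWWW"))))
  # residues seen only in positives score positive
  expect_gt(score_freq(model, "CVVV"), 0)
})

test_that("task thresholds follow the printed cutoffs strictly", {
  th <- method_thresholds()
  expect_equal(th$preps_cutoff, -2)
  expect_equal(th$fpb_cutoff, -1.1)
  expect_equal(th$freq_prenylation_cutoff, -1)
  expect_equal(th$freq_cleavage_cutoff, 0)
  # strict '>' at every boundary
  expect_true(apply_external_threshold(-1.9, th$preps_cutoff))
  expect_false(apply_external_threshold(-2, th$preps_cutoff))
  expect_false(apply_external_threshold(-1.1, th$fpb_cutoff))
  scores <- c(CVIA = 0.5, CASQ = -1.9, CDDD = -3, CKQQ = -2, CTLM = -1.5)
  calls <- apply_external_threshold(scores, th$preps_cutoff)
  expect_equal(unname(calls), c(TRUE, TRUE, FALSE, FALSE, TRUE))
  pren <- fit_freq("CVIA", "CDDD", task = "prenylation")
  clv <- fit_freq("CVIA", "CDDD", task = "cleavage")
  expect_equal(pren$threshold, -1)
  expect_equal(clv$threshold, 0)
})

test_that("PSSM and Freq models round-trip through JSON", {
  sets <- cached_sets()
  pssm <- train_pssm(sets$prenylation)
  freq <- train_freq(sets$cleavage)
  p1 <- tempfile(fileext = ".json"); p2 <- tempfile(fileext = ".json")
  write_model_json(pssm, p1)
  write_model_json(freq, p2)
  pssm2 <- read_model_json(p1)
  freq2 <- read_model_json(p2)
  motifs <- sample(enumerate_cxxx_space(), 50)
  expect_equal(score_pssm(pssm2, motifs), score_pssm(pssm, motifs))
  expect_equal(pssm2$cutoff, pssm$cutoff)
  expect_equal(score_freq(freq2, motifs), score_freq(freq, motifs))
})
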