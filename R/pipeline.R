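pipeline_error <- function(class, ...) {
  stop(structure(class = c(class, "caaxpred_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Pipeline run configuration
#'
#' Flat key/value configuration for [run_pipeline()]; every default mirrors
#' the package's modelling constants (10 folds, 0.99 PCA variance target,
#' pseudocount 0.05, Freq cutoffs -1/0, PrePS -2, FlexPepBind -1.1).
#' Unknown keys are rejected so typos fail loudly. A configuration can be
#' read from a YAML file of the same keys.
#'
#' @param task `"prenylation"` or `"cleavage"`.
#' @param feature_scheme `"sequence"`, `"aaindex"` or `"embedding"`.
#' @param model One of pssm, freq, svm, naive_bayes, knn, gbdt.
#' @param pca_variance_target Retained variance fraction (default 0.99).
#' @param cv_folds Cross-validation folds (default 10).
#' @param seed Integer seed recorded in every artifact.
#' @param pseudocount PSSM/Freq pseudocount (default 0.05).
#' @param out_dir Output directory.
#' @param paths Named list of input paths (training_set, screen table,
#'   ydj1_hits, exclusion lists, aaindex, fasta, models, validation_table).
#' @param adapter Embedding adapter function (resolved lazily; never read
#'   from file).
#' @return List of class `run_config`.
#' @export
run_config <- function(task = "prenylation", feature_scheme = "sequence",
                       model = "pssm", pca_variance_target = 0.99,
                       cv_folds = 10L, seed = 1L, pseudocount = 0.05,
                       out_dir = ".", paths = list(), adapter = NULL) {
  if (!task %in% c("prenylation", "cleavage")) {
    pipeline_error("caaxpred_config_error", "unknown task: ", task)
  }
  if (!feature_scheme %in% c("sequence", "aaindex", "embedding")) {
    pipeline_error("caaxpred_config_error", "unknown feature scheme: ",
                   feature_scheme)
  }
  if (!model %in% c("pssm", "freq", "svm", "naive_bayes", "knn", "gbdt")) {
    pipeline_error("caaxpred_config_error", "unknown model: ", model)
  }
  structure(list(task = task, feature_scheme = feature_scheme, model = model,
                 pca_variance_target = pca_variance_target,
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed),
                 pseudocount = pseudocount, out_dir = out_dir,
                 thresholds = method_thresholds(), paths = paths,
                 adapter = adapter),
            class = "run_config")
}

#' Read a [run_config()] from a flat YAML file
#' @param path YAML file path.
#' @param ... Overrides passed on to [run_config()].
#' @export
read_run_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  known <- setdiff(names(formals(run_config)), "adapter")
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    pipeline_error("caaxpred_config_error",
                   "unknown config key(s): ", paste(bad, collapse = ", "))
  }
  do.call(run_config, utils::modifyList(raw, list(...)))
}

need_path <- function(config, key) {
  p <- config$paths[[key]]
  if (is.null(p)) {
    pipeline_error("caaxpred_input_error", "config paths$", key,
                   " is required for this command")
  }
  if (!file.exists(p)) {
    pipeline_error("caaxpred_input_error", "input not found: ", p)
  }
  p
}

provenance <- function(config, artifacts) {
  list(package = "caaxpred",
       version = as.character(utils::packageVersion("caaxpred")),
       seed = config$seed,
       model = config$model,
       feature_scheme = config$feature_scheme,
       task = config$task,
       config = config[setdiff(names(config), "adapter")],
       artifacts = artifacts)
}

# Encode motifs under the configured scheme; PCA reducer optional.
encode_for_config <- function(config, motifs, reducer = NULL) {
  m <- switch(config$feature_scheme,
    sequence = encode_onehot(motifs),
    aaindex = {
      entries <- parse_aaindex(need_path(config, "aaindex"))
      encode_aaindex(motifs, entries)
    },
    embedding = {
      if (is.null(config$adapter)) {
        pipeline_error("caaxpred_input_error",
                       "feature scheme 'embedding' needs an adapter; ",
                       "pass one to run_config(adapter = ...)")
      }
      encode_embedding(motifs, config$adapter)
    }
  )
  if (!is.null(reducer)) m <- pca_transform(reducer, m)
  m
}

train_model_for_config <- function(config, ts) {
  if (config$model == "pssm") {
    return(train_pssm(ts, pseudocount = config$pseudocount))
  }
  if (config$model == "freq") {
    return(train_freq(ts, pseudocount = config$pseudocount))
  }
  tm <- training_matrix(ts)
  feats <- encode_for_config(config, tm$motifs)
  reducer <- fit_pca(feats, config$pca_variance_target)
  spec <- classifier_spec(config$model, seed = config$seed)
  fitted <- grid_search_fit(spec, pca_transform(reducer, feats), tm$labels)
  classifier_predictor(
    fitted,
    encoder = function(motifs) encode_for_config(config, motifs, reducer),
    model_id = paste(config$model, config$feature_scheme, sep = "-")
  )
}

#' Run an end-to-end pipeline command
#'
#' Commands: `synth` (write synthetic screen and fixture files), `curate`
#' (threshold selection + exclusion curation from a screen table),
#' `train` (fit and serialize the configured model), `evaluate` (k-fold CV
#' and optional validation tally), `predict-all` (score the full 8000-motif
#' space with a trained model pair), `scan` (proteome FASTA scan). Every
#' command writes its artifacts under `config$out_dir` together with a
#' `*_provenance.json` naming the package version, seed and configuration.
#'
#' @param config A [run_config()] (or YAML path understood by
#'   [read_run_config()]).
#' @param command One of synth, curate, train, evaluate, predict-all, scan.
#' @return Invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(config, command = c("synth", "curate", "train",
                                             "evaluate", "predict-all",
                                             "scan")) {
  command <- match.arg(command)
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(config$out_dir, name)
  artifacts <- list()

  if (command == "synth") {
    archive <- synthetic_screen_archive(seed = config$seed)
    utils::write.csv(archive$ras61_screen, out("ras61_screen.csv"),
                     row.names = FALSE, quote = FALSE)
    writeLines(archive$ras61_top, out("ras61_top.txt"))
    writeLines(archive$ydj1_hits, out("ydj1_hits.txt"))
    writeLines(archive$config$proteome_exclusions, out("proteome_native.txt"))
    writeLines(archive$config$reporter_exclusions, out("reporter_motifs.txt"))
    writeLines(archive$config$confirmed_cleaved_exclusions,
               out("confirmed_cleaved.txt"))
    writeLines(generate_aaindex_fixture(25L, seed = config$seed),
               out("aaindex_fixture.txt"))
    artifacts <- list(screen = out("ras61_screen.csv"),
                      ras61_top = out("ras61_top.txt"),
                      ydj1_hits = out("ydj1_hits.txt"),
                      proteome = out("proteome_native.txt"),
                      reporter = out("reporter_motifs.txt"),
                      confirmed_cleaved = out("confirmed_cleaved.txt"),
                      aaindex = out("aaindex_fixture.txt"))
  } else if (command == "curate") {
    screen <- utils::read.csv(need_path(config, "screen"),
                              stringsAsFactors = FALSE)
    cfg <- curation_config(
      proteome_exclusions = read_motif_list(need_path(config, "proteome")),
      reporter_exclusions = read_motif_list(need_path(config, "reporter")),
      confirmed_cleaved_exclusions =
        read_motif_list(need_path(config, "confirmed_cleaved"))
    )
    ydj1 <- read_motif_list(need_path(config, "ydj1_hits"))
    pren <- curate_prenylation_sets(select_ras61_positives(screen, cfg),
                                    ydj1,
                                    select_ras61_negatives(screen, cfg), cfg)
    clv <- curate_cleavage_sets(read_motif_list(need_path(config,
                                                          "ras61_top")),
                                ydj1, cfg)
    write_training_set(pren, out("prenylation_training_set.csv"))
    write_training_set(clv, out("cleavage_training_set.csv"))
    artifacts <- list(prenylation = out("prenylation_training_set.csv"),
                      cleavage = out("cleavage_training_set.csv"))
  } else if (command == "train") {
    ts <- read_training_set(need_path(config, "training_set"), config$task)
    model <- train_model_for_config(config, ts)
    if (inherits(model, "motif_predictor")) {
      path <- out(paste0(config$model, "_", config$task, "_model.rds"))
      saveRDS(model, path)
    } else {
      path <- out(paste0(config$model, "_", config$task, "_model.json"))
      write_model_json(model, path)
    }
    artifacts <- list(model = path)
  } else if (command == "evaluate") {
    ts <- read_training_set(need_path(config, "training_set"), config$task)
    tm <- training_matrix(ts)
    if (config$model %in% c("pssm", "freq")) {
      trainer <- if (config$model == "pssm") {
        pssm_trainer(pseudocount = config$pseudocount)
      } else {
        freq_trainer(pseudocount = config$pseudocount, task = config$task)
      }
      cv <- cross_validate(trainer, tm$motifs, tm$labels,
                           k = config$cv_folds, seed = config$seed)
    } else {
      feats <- encode_for_config(config, tm$motifs)
      spec <- classifier_spec(config$model, seed = config$seed)
      trainer <- function(x, y) {
        reducer <- fit_pca(feature_matrix(x, config$feature_scheme),
                           config$pca_variance_target)
        inner <- classifier_trainer(spec)(
          pca_transform(reducer, feature_matrix(x, config$feature_scheme)), y)
        function(x_new) {
          inner(pca_transform(reducer,
                              feature_matrix(x_new, config$feature_scheme)))
        }
      }
      cv <- cross_validate(trainer, unclass(feats), tm$labels,
                           k = config$cv_folds, seed = config$seed)
    }
    report <- list(model = config$model, task = config$task,
                   feature_scheme = config$feature_scheme, k = cv$k,
                   seed = cv$seed, mean = as.list(cv$mean),
                   sd = as.list(cv$sd))
    if (!is.null(config$paths$validation_table)) {
      vt <- read_validation_table(need_path(config, "validation_table"))
      method <- if (config$model %in% c("pssm", "freq")) "freq" else "svm"
      report$validation <- tally_validation(vt, method, config$task)
    }
    jsonlite::write_json(report, out("cv_report.json"), auto_unbox = TRUE,
                         digits = NA)
    utils::write.table(cv$per_fold, out("cv_per_fold.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    artifacts <- list(report = out("cv_report.json"),
                      per_fold = out("cv_per_fold.tsv"))
  } else if (command %in% c("predict-all", "scan")) {
    read_any_model <- function(path) {
      if (grepl("\\.rds$", path)) readRDS(path) else read_model_json(path)
    }
    pren <- read_any_model(need_path(config, "prenylation_model"))
    clv <- read_any_model(need_path(config, "cleavage_model"))
    if (command == "predict-all") {
      sp <- predict_space(pren, clv)
      write_prediction_tsv(sp, out("cxxx_space_predictions.tsv"))
      jsonlite::write_json(
        list(counts = as.list(sp$partition$counts),
             fractions = as.list(sp$partition$fractions),
             seed = config$seed),
        out("space_partition.json"), auto_unbox = TRUE, digits = NA)
      artifacts <- list(predictions = out("cxxx_space_predictions.tsv"),
                        partition = out("space_partition.json"))
    } else {
      res <- scan_proteome(need_path(config, "fasta"), pren, clv)
      utils::write.table(res, out("proteome_scan.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      artifacts <- list(scan = out("proteome_scan.tsv"))
    }
  }

  prov_path <- out(paste0(gsub("-", "_", command), "_provenance.json"))
  jsonlite::write_json(provenance(config, artifacts), prov_path,
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  artifacts$provenance <- prov_path
  invisible(artifacts)
}
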