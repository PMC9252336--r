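#' Default experiment configuration
#'
#' Assembles the full configuration for one classification experiment:
#' which task, where the cohort comes from, and the preprocessing, loss,
#' network and training sub-configurations. Defaults reproduce the study
#' protocol (SMOTE k = 5, balance-before-split, 70/30 split, 117 -> 112
#' image chain, batch size 23, RMSprop at 1e-3 with 1/5 decay every 10
#' epochs, improved focal loss with tau = 0.05).
#'
#' @param task one of `"pd_vs_hc"`, `"early_vs_modadv"`, `"early_pd_vs_hc"`.
#'   The positive class is PD, moderate-to-advanced PD, and early PD
#'   respectively.
#' @param seed master seed for the whole run.
#' @return a nested configuration list.
#' @export
experimentConfig <- function(task = c("pd_vs_hc", "early_vs_modadv",
                                      "early_pd_vs_hc"),
                             seed = 1L) {
  list(
    task = match.arg(task),
    seed = as.integer(seed),
    output_dir = NULL,
    cohort = list(
      source = "synthetic", csv_path = NULL,
      n_pd = 296, n_hc = 161, n_early = 230, n_modadv = 66,
      effect_size = 1.0, subgroup_effect = 0.5, shift_fraction = 0.3,
      correlation = 0.3, noise_sd = 1.0
    ),
    preprocessing = list(
      smote_k = 5, split_first = FALSE, test_fraction = 0.3,
      target_side = 117, resize_to = 112,
      erase_probability = 0.5
    ),
    loss = list(type = "improved_focal", gamma = 2, tau = 0.05),
    network = list(
      input_side = 112, stem_channels = 64,
      layer_channels = c(128, 256, 512), units_per_layer = 2, kernel = 3
    ),
    training = list(
      initial_lr = 1e-3, decay_factor = 0.2, decay_every = 10,
      batch_size = 23, max_epochs = 100, patience = 5, monitor = "loss",
      rho = 0.99, eps = 1e-8,
      validation_fraction = 0.15, paper_faithful = FALSE
    )
  )
}

# recursive merge that refuses unknown keys, collecting every offender
mergeConfig <- function(defaults, user, path = "") {
  errs <- character()
  for (nm in names(user)) {
    here <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(defaults)) {
      errs <- c(errs, paste0("unknown configuration key: ", here))
      next
    }
    if (is.list(defaults[[nm]]) && !is.null(user[[nm]])) {
      if (!is.list(user[[nm]])) {
        errs <- c(errs, paste0(here, " must be a mapping"))
        next
      }
      r <- mergeConfig(defaults[[nm]], user[[nm]], here)
      defaults[[nm]] <- r$config
      errs <- c(errs, r$errors)
    } else if (!is.null(user[[nm]])) {
      v <- user[[nm]]
      # yaml reads whole numbers as integers; keep the default's numeric type
      if (is.double(defaults[[nm]]) && is.integer(v)) v <- as.double(v)
      if (is.integer(defaults[[nm]]) && is.double(v) &&
          all(v == round(v))) v <- as.integer(v)
      defaults[[nm]] <- v
    }
  }
  list(config = defaults, errors = errs)
}

#' Load and validate an experiment configuration
#'
#' `loadConfig` reads a YAML file, overlays it on [experimentConfig()]
#' defaults (rejecting unknown keys rather than silently accepting typos)
#' and validates. `validateConfig` checks every invariant and reports all
#' violations at once.
#'
#' @param path YAML configuration file.
#' @return the validated, fully populated configuration list.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user$task)) stop("config must set 'task'")
  base <- experimentConfig(user$task,
                           seed = user$seed %||% 1L)
  merged <- mergeConfig(base, user)
  if (length(merged$errors))
    stop("invalid configuration:\n  ",
         paste(merged$errors, collapse = "\n  "))
  validateConfig(merged$config)
}

#' @rdname loadConfig
#' @param config a configuration list.
#' @export
validateConfig <- function(config) {
  errs <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  chk(config$task %in% c("pd_vs_hc", "early_vs_modadv", "early_pd_vs_hc"),
      "task must be pd_vs_hc, early_vs_modadv or early_pd_vs_hc")
  chk(config$cohort$source %in% c("synthetic", "csv"),
      "cohort.source must be 'synthetic' or 'csv'")
  if (identical(config$cohort$source, "csv"))
    chk(is.character(config$cohort$csv_path),
        "cohort.csv_path required when cohort.source is 'csv'")
  p <- config$preprocessing
  chk(p$smote_k >= 1, "preprocessing.smote_k must be >= 1")
  chk(p$test_fraction > 0 && p$test_fraction < 1,
      "preprocessing.test_fraction must lie in (0, 1)")
  chk(p$target_side >= 2, "preprocessing.target_side must be >= 2")
  chk(p$resize_to >= 2, "preprocessing.resize_to must be >= 2")
  chk(p$erase_probability >= 0 && p$erase_probability <= 1,
      "preprocessing.erase_probability must lie in [0, 1]")
  chk(config$loss$type %in% c("improved_focal", "focal", "cross_entropy"),
      "loss.type must be improved_focal, focal or cross_entropy")
  chk(config$loss$tau >= 0 && config$loss$tau < 0.5,
      "loss.tau must lie in [0, 0.5)")
  chk(config$loss$gamma >= 0, "loss.gamma must be >= 0")
  chk(config$network$input_side == config$preprocessing$resize_to,
      "network.input_side must equal preprocessing.resize_to")
  chk(length(config$network$layer_channels) == 3,
      "network.layer_channels must list exactly three layers")
  t <- config$training
  chk(t$initial_lr > 0, "training.initial_lr must be > 0")
  chk(t$decay_factor > 0 && t$decay_factor < 1,
      "training.decay_factor must lie in (0, 1)")
  chk(t$decay_every >= 1, "training.decay_every must be >= 1")
  chk(t$batch_size >= 1, "training.batch_size must be >= 1")
  chk(t$max_epochs >= 1, "training.max_epochs must be >= 1")
  chk(t$patience >= 1, "training.patience must be >= 1")
  chk(t$monitor %in% c("loss", "accuracy"),
      "training.monitor must be 'loss' or 'accuracy'")
  chk(t$validation_fraction >= 0 && t$validation_fraction < 0.5,
      "training.validation_fraction must lie in [0, 0.5)")
  if (length(errs))
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "))
  config
}

# task -> rows kept and binary labels (1 = positive class)
taskSubset <- function(cohort, task) {
  dg <- diagnosis(cohort)
  sv <- severity(cohort)
  switch(task,
    pd_vs_hc = list(
      keep = seq_len(ncol(cohort)),
      labels = as.integer(dg == "PD"),
      smoteOn = "diagnosis", positive = "PD", negative = "HC"),
    early_vs_modadv = list(
      keep = which(dg == "PD"),
      labels = as.integer(sv[dg == "PD"] == "moderate_advanced"),
      smoteOn = "severity", positive = "moderate_advanced",
      negative = "early"),
    early_pd_vs_hc = list(
      keep = which(dg == "HC" | sv == "early"),
      labels = as.integer(sv[dg == "HC" | sv == "early"] == "early"),
      smoteOn = "severity_hc", positive = "early_PD", negative = "HC")
  )
}

imagesFromFeatures <- function(X, targetSide, resizeTo) {
  elevated <- polynomialElevate(X, targetSide = targetSide)
  out <- array(0, c(resizeTo, resizeTo, 1, nrow(X)))
  for (i in seq_len(nrow(X)))
    out[, , 1, i] <- resizeImage(toImage(elevated[i, ], targetSide), resizeTo)
  out
}

#' Run a full classification experiment
#'
#' Executes the whole pipeline for one task: generate or load the cohort,
#' subset it to the task's two classes, SMOTE-balance (before splitting by
#' default, reproducing the study's ordering; set
#' `preprocessing$split_first = TRUE` for a leakage-free variant), fit the
#' min-max normalizer on the training partition, elevate features to the
#' polynomial image, resize, train the residual network, and evaluate on
#' the held-out test partition.
#'
#' When `output_dir` is set the run writes `metrics.json`, `history.csv`,
#' `roc.csv`, `config_echo.yaml` and `run.log` (seed + package version), so
#' the run is exactly reproducible from the directory contents.
#'
#' @param config configuration from [experimentConfig()] or [loadConfig()].
#' @return list with `metrics`, `confusion` ([ConfusionMatrix-class]),
#'   `roc`, `history`, `nTest`, and the trained `net`.
#' @export
runExperiment <- function(config = experimentConfig()) {
  config <- validateConfig(config)
  setGlobalSeed(config$seed)
  logLines <- c(
    paste0("gaitPD ", as.character(packageVersion("gaitPD"))),
    paste0("task: ", config$task),
    paste0("seed: ", config$seed)
  )

  cohort <- if (identical(config$cohort$source, "csv")) {
    csvToCohort(config$cohort$csv_path)
  } else {
    cc <- config$cohort
    generateCohort(cohortConfig(
      nPD = cc$n_pd, nHC = cc$n_hc, nEarly = cc$n_early,
      nModAdv = cc$n_modadv, effectSize = cc$effect_size,
      subgroupEffect = cc$subgroup_effect, shiftFraction = cc$shift_fraction,
      correlation = cc$correlation, noiseSD = cc$noise_sd,
      seed = config$seed))
  }

  ts <- taskSubset(cohort, config$task)
  sub <- cohort[, ts$keep]
  labels <- ts$labels
  logLines <- c(logLines, paste0("task dataset: ", length(labels),
                                 " samples before balancing"))

  p <- config$preprocessing
  balanceLabels <- function(ch) {
    if (config$task == "pd_vs_hc") diagnosis(ch)
    else if (config$task == "early_vs_modadv") severity(ch)
    else ifelse(diagnosis(ch) == "HC", "HC", "early_PD")
  }

  if (isTRUE(p$split_first)) {
    split <- splitTrainTest(labels, p$test_fraction, stratified = TRUE)
    trainCohort <- smoteBalance(sub[, split$train], k = p$smote_k,
                                labels = balanceLabels(sub[, split$train]))
    Xtrain <- featureMatrix(trainCohort)
    yTrain <- labelsFor(trainCohort, config$task)
    Xtest <- featureMatrix(sub[, split$test])
    yTest <- labels[split$test]
  } else {
    balanced <- smoteBalance(sub, k = p$smote_k,
                             labels = balanceLabels(sub))
    yAll <- labelsFor(balanced, config$task)
    split <- splitTrainTest(yAll, p$test_fraction, stratified = TRUE)
    X <- featureMatrix(balanced)
    Xtrain <- X[split$train, , drop = FALSE]
    yTrain <- yAll[split$train]
    Xtest <- X[split$test, , drop = FALSE]
    yTest <- yAll[split$test]
  }
  logLines <- c(logLines,
                paste0("train/test: ", length(yTrain), "/", length(yTest)))

  nz <- fitNormalizer(Xtrain)
  Xtrain <- applyNormalizer(nz, Xtrain)
  Xtest <- applyNormalizer(nz, Xtest)

  xTrainImg <- imagesFromFeatures(Xtrain, p$target_side, p$resize_to)
  xTestImg <- imagesFromFeatures(Xtest, p$target_side, p$resize_to)

  t <- config$training
  vf <- t$validation_fraction
  if (isTRUE(t$paper_faithful) || vf == 0) {
    xMon <- xTestImg; yMon <- yTest
    xFit <- xTrainImg; yFit <- yTrain
  } else {
    vs <- splitTrainTest(yTrain, vf, stratified = TRUE)
    xFit <- xTrainImg[, , , vs$train, drop = FALSE]; yFit <- yTrain[vs$train]
    xMon <- xTrainImg[, , , vs$test, drop = FALSE]; yMon <- yTrain[vs$test]
  }

  nw <- config$network
  net <- buildNetwork(networkSpec(
    inputSide = nw$input_side, stemChannels = nw$stem_channels,
    layerChannels = nw$layer_channels, unitsPerLayer = nw$units_per_layer,
    kernel = nw$kernel), seed = config$seed)

  tc <- trainConfig(initialLR = t$initial_lr, decayFactor = t$decay_factor,
                    decayEvery = t$decay_every, batchSize = t$batch_size,
                    maxEpochs = t$max_epochs, patience = t$patience,
                    monitor = t$monitor, loss = config$loss$type,
                    gamma = config$loss$gamma, tau = config$loss$tau,
                    rho = t$rho, eps = t$eps,
                    eraseProbability = p$erase_probability,
                    seed = config$seed)
  fit <- trainNetwork(net, xFit, yFit, xMon, yMon, tc)

  probs <- netForward(fit$net, xTestImg)
  pred <- classify(probs)
  cm <- confusionCounts(pred, yTest, positive = ts$positive,
                        negative = ts$negative)
  metrics <- classificationMetrics(cm)
  roc <- rocAuc(probs[, 1], yTest)
  metrics$auc <- roc$auc
  logLines <- c(logLines,
                paste0("test accuracy: ", round(metrics$accuracy, 2), "%"))

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$output_dir
    jsonlite::write_json(metrics, file.path(od, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    write.csv(fit$history, file.path(od, "history.csv"), row.names = FALSE)
    write.csv(roc$curve, file.path(od, "roc.csv"), row.names = FALSE)
    yaml::write_yaml(config, file.path(od, "config_echo.yaml"))
    writeLines(logLines, file.path(od, "run.log"))
  }

  list(metrics = metrics, confusion = cm, roc = roc,
       history = fit$history, nTest = length(yTest), net = fit$net,
       log = logLines)
}

# binary labels (1 = positive) for a possibly SMOTE-augmented cohort
labelsFor <- function(cohort, task) {
  switch(task,
    pd_vs_hc = as.integer(diagnosis(cohort) == "PD"),
    early_vs_modadv = as.integer(severity(cohort) == "moderate_advanced"),
    early_pd_vs_hc = as.integer(severity(cohort) == "early")
  )
}
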