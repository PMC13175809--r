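## Optimization loop: AdamW with cosine annealing + linear warmup, per-epoch
## validation, best-validation checkpoint selection, and the multi-seed
## protocol runner with seed-paired significance tests.

#' Training configuration
#'
#' Defaults reproduce the benchmark protocol: 50 epochs, batch size 16, AdamW
#' with initial learning rate 1e-4 and weight decay 1e-2, linear warmup over
#' the first 5 epochs, cosine annealing to a minimum learning rate of 1e-6,
#' and the five fixed seeds {42, 123, 2024, 3407, 9999}.
#'
#' @param epochs,batch_size,base_lr,weight_decay,warmup_epochs,min_lr see
#'   description.
#' @param seeds integer seeds for the repeated-runs protocol.
#' @param deterministic keep every random draw tied to the run seed.
#' @param augment apply geometric augmentation to training batches.
#' @return validated config list of class `TrainConfig`.
#' @export
trainConfig <- function(epochs = 50L, batch_size = 16L, base_lr = 1e-4,
                        weight_decay = 1e-2, warmup_epochs = 5L,
                        min_lr = 1e-6, seeds = c(42L, 123L, 2024L, 3407L, 9999L),
                        deterministic = TRUE, augment = FALSE) {
  cfg <- list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
              base_lr = base_lr, weight_decay = weight_decay,
              warmup_epochs = as.integer(warmup_epochs), min_lr = min_lr,
              seeds = as.integer(seeds), deterministic = isTRUE(deterministic),
              augment = isTRUE(augment))
  if (cfg$warmup_epochs >= cfg$epochs)
    stop("trainConfig: warmup_epochs must be < epochs")
  if (cfg$min_lr >= cfg$base_lr)
    stop("trainConfig: min_lr must be < base_lr")
  if (cfg$epochs < 1L || cfg$batch_size < 1L)
    stop("trainConfig: epochs and batch_size must be >= 1")
  class(cfg) <- "TrainConfig"
  cfg
}

#' Learning rate at a step
#'
#' Linear ramp from 0 to `base_lr` over the warmup steps, then cosine
#' annealing from `base_lr` down to exactly `min_lr` at the final step.
#' Applied per optimization step, not per epoch.
#'
#' @param step 0-based step index, `0 <= step < total_steps`.
#' @param total_steps total optimization steps of the run.
#' @param config a [trainConfig()].
#' @return the learning rate.
#' @export
lrAt <- function(step, total_steps, config) {
  if (any(step < 0) || any(step >= total_steps))
    stop("lrAt: step must satisfy 0 <= step < total_steps")
  warm <- round(total_steps * config$warmup_epochs / config$epochs)
  ifelse(step <= warm & warm > 0,
         config$base_lr * step / max(warm, 1),
         {
           tfrac <- (step - warm) / max(total_steps - 1 - warm, 1)
           config$min_lr + 0.5 * (config$base_lr - config$min_lr) *
             (1 + cos(pi * tfrac))
         })
}

adamwInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adamwStep <- function(params, grads, state, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * ((state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)) -
      lr * weight_decay * params[[nm]]
  }
  list(params = params, state = state)
}

assertDisjointSplits <- function(splits) {
  ids <- lapply(splits, function(s) vapply(s, examId, ""))
  for (i in seq_along(ids))
    for (j in seq_along(ids))
      if (i < j && length(intersect(ids[[i]], ids[[j]])))
        stop("trainOne: exam-id leakage across splits '",
             names(ids)[i], "' and '", names(ids)[j], "': ",
             paste(utils::head(intersect(ids[[i]], ids[[j]]), 3L), collapse = ", "))
  invisible(TRUE)
}

examLabelMatrix <- function(exams)
  t(vapply(exams, function(e) e@labels, integer(3L)))

#' Train one model
#'
#' Runs the full optimization protocol on exam-level splits: AdamW updates
#' with the warmup + cosine schedule, validation macro AUROC after every
#' epoch, retention of the best-validation checkpoint (earliest epoch on
#' ties), and a single final evaluation of that checkpoint on the test split.
#' No early stopping. The test split never influences checkpoint choice; it
#' is only touched after the last epoch.
#'
#' @param splits named list `train` / `valid` / `test` of labeled
#'   [ExamTensor-class] lists with disjoint exam ids (`test` may be empty).
#' @param modelCfg a [modelConfig()].
#' @param trainCfg a [trainConfig()].
#' @param seed run seed (initialization, batch order, dropout, augmentation).
#' @return `RunResult` list: `seed`, `trainLoss` and `valMacroAuroc` per
#'   epoch, `selectedEpoch`, `model` (best checkpoint as [MILModel-class]),
#'   `testReport` ([MetricReport-class] or `NULL`).
#' @export
trainOne <- function(splits, modelCfg, trainCfg, seed) {
  stopifnot(all(c("train", "valid") %in% names(splits)))
  assertDisjointSplits(splits[intersect(c("train", "valid", "test"), names(splits))])
  seed <- as.integer(seed)
  model <- buildModel(modelCfg, seed = seed)
  config <- model@config
  params <- model@params
  state <- adamwInit(params)
  train <- splits$train
  nb <- ceiling(length(train) / trainCfg$batch_size)
  totalSteps <- trainCfg$epochs * nb
  yAll <- examLabelMatrix(train)
  set.seed(seed)
  trainLoss <- numeric(trainCfg$epochs)
  valAuroc <- numeric(trainCfg$epochs)
  best <- list(auroc = -Inf, epoch = NA_integer_, params = NULL)
  step <- 0L
  for (epoch in seq_len(trainCfg$epochs)) {
    ord <- sample.int(length(train))
    losses <- numeric(nb)
    for (b in seq_len(nb)) {
      idx <- ord[seq.int((b - 1L) * trainCfg$batch_size + 1L,
                         min(b * trainCfg$batch_size, length(train)))]
      batch <- train[idx]
      if (trainCfg$augment)
        batch <- lapply(batch, augmentExam)
      lr <- lrAt(step, totalSteps, trainCfg)
      tape <- agTape()
      P <- paramNodes(tape, params, trainable = TRUE)
      fw <- forwardExams(tape, P, config, batch, train = TRUE)
      loss <- agBceWithLogits(tape, fw$logits, yAll[idx, , drop = FALSE])
      agBackward(tape, loss)
      grads <- lapply(P, function(nd) nd$grad)
      upd <- adamwStep(params, grads, state, lr, trainCfg$weight_decay)
      params <- upd$params
      state <- upd$state
      losses[b] <- loss$val
      step <- step + 1L
    }
    trainLoss[epoch] <- mean(losses)
    mdl <- methods::initialize(model, params = params)
    rep <- evaluateModel(mdl, splits$valid, naOnDegenerate = TRUE)
    va <- macroMetrics(rep)[["auroc"]]
    ## tiny validation splits can lack a class for one label; select on the
    ## mean of the defined per-label AUROCs then
    if (is.na(va)) va <- mean(perLabelMetrics(rep)["auroc", ], na.rm = TRUE)
    valAuroc[epoch] <- va
    if (valAuroc[epoch] > best$auroc) {             # strict: earliest on ties
      best <- list(auroc = valAuroc[epoch], epoch = epoch, params = params)
    }
  }
  bestModel <- methods::initialize(model, params = best$params)
  testReport <- if (!is.null(splits$test) && length(splits$test))
    evaluateModel(bestModel, splits$test) else NULL
  list(seed = seed, trainLoss = trainLoss, valMacroAuroc = valAuroc,
       selectedEpoch = best$epoch, model = bestModel, testReport = testReport)
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores the parameter set, the full model configuration and
#' an arbitrary provenance record (e.g. the preprocessing config hash).
#'
#' @param model a [MILModel-class].
#' @param path file path.
#' @param provenance optional list stored alongside.
#' @return `path` invisibly; `loadCheckpoint` returns the [MILModel-class]
#'   with the provenance attached as attribute `"provenance"`.
#' @export
saveCheckpoint <- function(model, path, provenance = list()) {
  saveRDS(list(format = "TriViewMIL-checkpoint", params = model@params,
               config = model@config, provenance = provenance), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) NULL)
  if (is.null(obj) || !identical(obj$format, "TriViewMIL-checkpoint") ||
      !is.list(obj$params) || !is.list(obj$config))
    stop("loadCheckpoint: corrupt or unrecognized checkpoint: ", path)
  mdl <- methods::new("MILModel", params = obj$params, config = obj$config)
  attr(mdl, "provenance") <- obj$provenance
  mdl
}

#' Multi-seed comparison protocol
#'
#' Trains every method (a named list of model configurations) once per seed
#' on identical splits, collects the test-split metrics, reports
#' mean +/- sample standard deviation per method, and runs seed-paired
#' two-sided t tests of every method against the designated reference.
#' Optionally re-evaluates each selected checkpoint under test-time
#' perturbations (Table-style robustness rows).
#'
#' @param splits as in [trainOne()] (test split required).
#' @param methods named list of [modelConfig()]s.
#' @param trainCfg a [trainConfig()] (its `seeds`, at least two, drive the
#'   protocol).
#' @param reference name of the reference method (default: first).
#' @param perturbations character vector from
#'   `c("none", "intensity_shift", "view_dropout")`.
#' @return list of class `ProtocolReport`: `perSeed` (long data.frame),
#'   `summary` (method x metric "mean +/- sd"), `tests` (paired-test rows vs
#'   the reference), `runs` (nested RunResults).
#' @export
runProtocol <- function(splits, methods, trainCfg, reference = names(methods)[1],
                        perturbations = "none") {
  if (is.null(names(methods)) || any(!nzchar(names(methods))))
    stop("runProtocol: methods must be a named list of model configs")
  seeds <- trainCfg$seeds
  if (length(seeds) < 2L) stop("runProtocol: need at least 2 seeds")
  if (!reference %in% names(methods))
    stop("runProtocol: unknown reference method '", reference, "'")
  metricNames <- c("auroc", "auprc", "f1", "brier")
  runs <- list()
  perSeed <- list()
  for (m in names(methods)) {
    runs[[m]] <- list()
    for (s in seeds) {
      rr <- trainOne(splits, methods[[m]], trainCfg, seed = s)
      runs[[m]][[as.character(s)]] <- rr
      reports <- list(none = rr$testReport)
      for (p in setdiff(perturbations, "none"))
        reports[[p]] <- evaluateModel(rr$model, splits$test, perturbation = p,
                                      seed = s)
      for (p in names(reports)) {
        mm <- macroMetrics(reports[[p]])
        perSeed[[length(perSeed) + 1L]] <- data.frame(
          method = m, seed = s, perturbation = p,
          metric = metricNames, value = unname(mm[metricNames]),
          stringsAsFactors = FALSE)
      }
    }
  }
  perSeed <- do.call(rbind, perSeed)
  fmt <- function(v) sprintf("%.4f ± %.4f", mean(v), stats::sd(v))
  summary <- do.call(rbind, lapply(split(perSeed,
      perSeed[c("method", "perturbation", "metric")], drop = TRUE),
    function(d) data.frame(method = d$method[1], perturbation = d$perturbation[1],
                           metric = d$metric[1], mean = mean(d$value),
                           sd = stats::sd(d$value), mean_sd = fmt(d$value),
                           stringsAsFactors = FALSE)))
  rownames(summary) <- NULL
  clean <- perSeed[perSeed$perturbation == "none", ]
  tests <- list()
  for (m in names(methods)) {
    for (met in metricNames) {
      a <- clean$value[clean$method == m & clean$metric == met][order(seeds)]
      b <- clean$value[clean$method == reference & clean$metric == met][order(seeds)]
      tt <- pairedTTest(a, b)
      tests[[length(tests) + 1L]] <- data.frame(
        method = m, reference = reference, metric = met,
        mean_diff = tt$meanDiff, t = tt$t, df = tt$df, p = tt$p,
        degenerate = tt$degenerate, stringsAsFactors = FALSE)
    }
  }
  structure(list(perSeed = perSeed, summary = summary,
                 tests = do.call(rbind, tests), runs = runs,
                 reference = reference, seeds = seeds),
            class = "ProtocolReport")
}
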