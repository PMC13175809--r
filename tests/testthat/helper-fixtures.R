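# Shared fixtures. Everything is generated in code; the expensive training
# runs are built lazily and cached for the whole test session.

tinySynthConfig <- function(n, seed = 101L, ...)
  synthConfig(n_exams = n, slice_count_range = c(8L, 16L),
              base_resolution = 40L, seed = seed, ...)

tinyPreprocessConfig <- function() preprocessConfig(S = 8L, R = 32L)

mergeArgs <- function(defaults, overrides)
  utils::modifyList(defaults, overrides)

tinyModelConfig <- function(...)
  do.call(modelConfig, mergeArgs(
    list(encoder_dim = 32L, embed_dim = 32L, heads = 4L, attn_layers = 1L,
         pool_kernels = c(1L, 3L, 5L), mlp_hidden = 64L, S = 8L), list(...)))

tinyTrainConfig <- function(...)
  do.call(trainConfig, mergeArgs(
    list(epochs = 5L, batch_size = 8L, base_lr = 5e-3, warmup_epochs = 1L,
         min_lr = 1e-5, seeds = c(42L, 123L)), list(...)))

tinyExams <- function(n, seed = 101L, idOffset = 0L, ...)
  preprocessDataset(generateDataset(tinySynthConfig(n, seed, ...),
                                    idOffset = idOffset)$exams,
                    tinyPreprocessConfig())$exams

# micro scale: fast enough for determinism/mechanics unit tests
microModelConfig <- function(...)
  do.call(modelConfig, mergeArgs(
    list(encoder_dim = 8L, embed_dim = 8L, heads = 2L, attn_layers = 1L,
         pool_kernels = c(1L, 3L), mlp_hidden = 16L, S = 4L), list(...)))

microStudy <- function() {
  pp <- preprocessConfig(S = 4L, R = 16L)
  gen <- function(n, off) preprocessDataset(
    generateDataset(synthConfig(n_exams = n, slice_count_range = c(4L, 8L),
                                base_resolution = 20L, seed = 77L),
                    idOffset = off)$exams, pp)$exams
  list(train = gen(24L, 0L), valid = gen(16L, 24L), test = gen(16L, 40L))
}

# a random non-image slice-embedding sequence
randomSeq <- function(S, D, seed = 1) {
  set.seed(seed)
  matrix(rnorm(S * D), S, D)
}

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.fixtureCache[[name]])) .fixtureCache[[name]] <- builder()
  .fixtureCache[[name]]
}

# the tiny study: 200 train / 100 valid / 60 test exams with planted signal
tinyStudy <- function() cached("tinyStudy", function() {
  list(train = tinyExams(200L, idOffset = 0L),
       valid = tinyExams(100L, idOffset = 200L),
       test = tinyExams(60L, idOffset = 300L))
})

# three full training runs of the multi-scale model on the tiny study
signalRuns <- function() cached("signalRuns", function() {
  splits <- tinyStudy()
  lapply(c(42L, 123L, 2024L), function(s)
    trainOne(splits, tinyModelConfig(), tinyTrainConfig(), seed = s))
})

permuteExamLabels <- function(exams, seed) {
  set.seed(seed)
  perm <- sample.int(length(exams))
  mapply(function(e, j) methods::initialize(e, labels = exams[[j]]@labels),
         exams, perm, SIMPLIFY = FALSE)
}

# brute-force metric oracles, independent of the implementations under test
oracleAuroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

oracleAuprc <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  npos <- sum(labels == 1)
  rec0 <- 0; ap <- 0
  for (t in th) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    prec <- tp / sum(pred)
    rec <- tp / npos
    ap <- ap + (rec - rec0) * prec
    rec0 <- rec
  }
  ap
}

oracleF1 <- function(scores, labels, threshold = 0.5) {
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1)
  prec <- if (sum(pred) == 0) 0 else tp / sum(pred)
  rec <- if (sum(labels) == 0) 0 else tp / sum(labels)
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

oracleBrier <- function(scores, labels) sum((scores - labels)^2) / length(scores)
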