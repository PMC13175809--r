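test_that("configuration invariants are enforced", {
  expect_error(modelConfig(embed_dim = 30, heads = 4), "divisible")
  expect_error(modelConfig(pool_kernels = c(1, 2)), "odd")
  expect_error(modelConfig(n_labels = 2), "n_labels")
})

test_that("slice encoding honors the per-slice contract", {
  # test-double encoder: mean pixel copied D-fold
  enc <- function(slice) rep(mean(slice), 5)
  stack <- array(0, c(4, 6, 6))
  for (s in 1:4) stack[s, , ] <- s
  emb <- encodeSlices(stack, enc)
  expect_equal(dim(emb), c(4, 5))
  expect_equal(emb, matrix(rep(1:4, 5), 4, 5))
  # per-slice independence: permuting slices permutes rows identically
  perm <- c(3, 1, 4, 2)
  expect_equal(encodeSlices(stack[perm, , ], enc), emb[perm, ])
  # identical slices give identical rows
  stack[2, , ] <- stack[1, , ]
  emb <- encodeSlices(stack, enc)
  expect_identical(emb[1, ], emb[2, ])
  # dimension mismatch is a contract error
  bad <- local({ n <- 0; function(slice) { n <<- n + 1; rep(0, n) } })
  expect_error(encodeSlices(stack, bad), "dimension mismatch")
  # the built-in conv encoder is deterministic and batchable
  mdl <- buildModel(tinyModelConfig(), seed = 1)
  st <- tinyExams(1L, seed = 55L)[[1]]@views$sagittal
  e1 <- encodeSlices(st, mdl)
  expect_equal(dim(e1), c(8, 32))
  expect_identical(e1, encodeSlices(st, mdl))
  expect_equal(encodeSlices(st[c(2, 1, 3:8), , ], mdl), e1[c(2, 1, 3:8), ],
               tolerance = 1e-12)
})

test_that("multi-scale pooling uses truncated windows", {
  seq1 <- matrix(c(1, 2, 3, 4), 4, 1)
  expect_equal(multiscalePool(seq1, 1), seq1)
  expect_equal(as.vector(multiscalePool(seq1, 3)), c(1.5, 2, 3, 3.5))
  const <- matrix(2, 5, 3)
  for (k in c(1, 3, 5))
    expect_equal(multiscalePool(const, k), const)
  expect_error(multiscalePool(seq1, 2), "odd")
})

test_that("token construction and attention readout behave as specified", {
  cfg <- tinyModelConfig()
  mdl <- buildModel(cfg, seed = 3)
  seq <- randomSeq(8, 32, seed = 10)
  tokens <- multiscaleTokens(mdl, seq)
  expect_equal(dim(tokens), c(24, 32))
  ro <- attentionAggregate(mdl, tokens)
  expect_length(ro$embedding, 32)
  expect_equal(sum(ro$weights), 1, tolerance = 1e-6)
  expect_true(all(ro$weights >= 0))
  # zeroed attention pathway: blocks become identities, readout uniform,
  # summary = token mean
  z <- zeroAttentionParams(mdl)
  roz <- attentionAggregate(z, tokens)
  expect_equal(roz$embedding, colMeans(tokens), tolerance = 1e-10)
  expect_equal(roz$weights, rep(1 / 24, 24), tolerance = 1e-12)
})

test_that("the aggregator is permutation-invariant without positional cues", {
  cfg <- tinyModelConfig(pool_kernels = 1L, positional_encoding = FALSE)
  mdl <- buildModel(cfg, seed = 6)
  seq <- randomSeq(8, 32, seed = 11)
  tokens <- multiscaleTokens(mdl, seq)
  set.seed(2)
  perm <- sample(nrow(tokens))
  a <- attentionAggregate(mdl, tokens)
  b <- attentionAggregate(mdl, tokens[perm, ])
  expect_equal(b$embedding, a$embedding, tolerance = 1e-5)
  expect_equal(b$weights, a$weights[perm], tolerance = 1e-5)
})

test_that("pooling baselines match direct arithmetic", {
  m <- matrix(c(1, 3, 2, 4), 2, 2)
  expect_equal(poolMean(m), c(2, 3))
  expect_equal(poolMax(m), c(3, 4))
  one <- matrix(c(5, 7), 1, 2)
  expect_equal(poolMean(one), c(5, 7))
  expect_equal(poolMax(one), c(5, 7))
  seq <- randomSeq(6, 4, seed = 3)
  perm <- c(4, 2, 6, 1, 3, 5)
  expect_equal(poolMean(seq[perm, ]), poolMean(seq))
  expect_equal(poolMax(seq[perm, ]), poolMax(seq))
  # projection path
  proj <- list(W = matrix(1:8 / 10, 4, 2), b = c(1, -1))
  expect_equal(poolMean(seq, proj), as.vector(colMeans(seq) %*% proj$W + proj$b))
})

test_that("gated-attention MIL pooling follows its formula", {
  # equalizing parameters: V = 0 makes all scores equal -> summary = mean
  seq <- randomSeq(5, 3, seed = 4)
  pe <- list(V = matrix(0, 3, 2), U = matrix(1, 3, 2), w = c(1, 1))
  got <- poolAttentionMIL(seq, pe)
  expect_equal(got$summary, colMeans(seq), tolerance = 1e-12)
  expect_equal(got$weights, rep(0.2, 5))
  # single instance returns itself
  one <- poolAttentionMIL(seq[1, , drop = FALSE], pe)
  expect_equal(one$summary, seq[1, ])
  # two instances, 1-dim parameters, hand-evaluated
  h <- matrix(c(0.5, -1), 2, 1)
  p1 <- list(V = matrix(2, 1, 1), U = matrix(1, 1, 1), w = 3)
  sc <- 3 * tanh(2 * h) * (1 / (1 + exp(-h)))
  a <- exp(sc) / sum(exp(sc))
  expect_equal(poolAttentionMIL(h, p1)$weights, as.vector(a), tolerance = 1e-12)
  expect_equal(poolAttentionMIL(h, p1)$summary, sum(a * h), tolerance = 1e-12)
})

test_that("fusion and classification keep the probability contract", {
  mdl <- buildModel(tinyModelConfig(), seed = 9)
  embs <- lapply(1:3, function(i) rnorm(32))
  pred <- fuseAndClassify(mdl, embs)
  expect_named(pred$probs, c("abnormal", "acl", "meniscus"))
  expect_true(all(pred$probs > 0 & pred$probs < 1))
  expect_equal(pred$probs, plogis(pred$logits), tolerance = 1e-7)
  # zero classifier -> all probabilities exactly one half
  z <- mdl
  z@params$fus_W1[] <- 0; z@params$fus_b1[] <- 0
  z@params$fus_W2[] <- 0; z@params$fus_b2[] <- 0
  expect_equal(unname(fuseAndClassify(z, embs)$probs), rep(0.5, 3))
  expect_error(fuseAndClassify(mdl, embs[1:2]), "exactly 3")
  # generic weights are view-order sensitive
  swapped <- fuseAndClassify(mdl, embs[c(3, 2, 1)])
  expect_gt(max(abs(swapped$logits - pred$logits)), 1e-6)
})

test_that("evaluation-mode prediction is bit-reproducible", {
  exams <- tinyExams(3L, seed = 21L)
  mdl <- buildModel(tinyModelConfig(), seed = 2)
  p1 <- predictExams(mdl, exams)
  p2 <- predictExams(mdl, exams)
  expect_identical(p1$probs, p2$probs)
  expect_identical(p1$attention, p2$attention)
  for (aw in p1$attention[[1]])
    expect_equal(sum(aw), 1, tolerance = 1e-6)
})

test_that("binary cross-entropy matches its closed forms", {
  expect_equal(bceLoss(0.5, 1), log(2), tolerance = 1e-12)
  expect_lt(bceLoss(c(1, 0), c(1, 0)), 1.1e-7)
  expect_equal(bceLoss(c(0.9, 0.2), c(1, 0)), (-log(0.9) - log(0.8)) / 2,
               tolerance = 1e-12)
  expect_error(bceLoss(c(0.5, 0.5), 1), "equal shape")
})

test_that("with kernels {1} and zeroed attention the model is mean pooling", {
  cfgMs <- tinyModelConfig(pool_kernels = 1L)
  ms <- zeroAttentionParams(buildModel(cfgMs, seed = 12))
  mean_ <- buildModel(tinyModelConfig(aggregator = "mean"), seed = 12)
  # share encoder, projection and fusion weights
  for (nm in names(mean_@params)) mean_@params[[nm]] <- ms@params[[nm]]
  exams <- tinyExams(4L, seed = 33L)
  pm <- predictExams(ms, exams)$logits
  pb <- predictExams(mean_, exams)$logits
  expect_equal(pm, pb, tolerance = 1e-5)
})

test_that("gradients reach every parameter of every aggregator", {
  ns <- asNamespace("TriViewMIL")
  exams <- tinyExams(4L, seed = 61L)
  y <- ns$examLabelMatrix(exams)
  for (agg in c("multiscale_attention", "mean", "max", "attention_mil")) {
    mdl <- buildModel(tinyModelConfig(aggregator = agg), seed = 5)
    tape <- ns$agTape()
    P <- ns$paramNodes(tape, mdl@params, trainable = TRUE)
    set.seed(1)
    fw <- ns$forwardExams(tape, P, mdl@config, exams, train = TRUE)
    loss <- ns$agBceWithLogits(tape, fw$logits, y)
    ns$agBackward(tape, loss)
    for (nm in names(P)) {
      expect_false(is.null(P[[nm]]$grad), label = paste(agg, nm, "grad exists"))
      expect_gt(max(abs(P[[nm]]$grad)), 0, label = paste(agg, nm, "nonzero"))
    }
  }
})

test_that("a training step against numerical gradients on the full model", {
  ns <- asNamespace("TriViewMIL")
  exams <- tinyExams(2L, seed = 71L)
  mdl <- buildModel(microModelConfig(S = 8L, pool_kernels = c(1L, 3L)), seed = 8)
  y <- ns$examLabelMatrix(exams)
  lossAt <- function(params) {
    tape <- ns$agTape()
    P <- ns$paramNodes(tape, params)
    fw <- ns$forwardExams(tape, P, mdl@config, exams, train = FALSE)
    ns$agBceWithLogits(tape, fw$logits, y)$val
  }
  tape <- ns$agTape()
  P <- ns$paramNodes(tape, mdl@params, trainable = TRUE)
  fw <- ns$forwardExams(tape, P, mdl@config, exams, train = FALSE)
  loss <- ns$agBceWithLogits(tape, fw$logits, y)
  ns$agBackward(tape, loss)
  # spot-check a handful of coordinates in diverse tensors
  for (nm in c("enc_W1", "proj_W_k1", "attn_Wq_1", "readout_w", "fus_W2")) {
    pr <- mdl@params
    i <- 1L
    h <- 1e-5
    pr[[nm]][i] <- pr[[nm]][i] + h; up <- lossAt(pr)
    pr[[nm]][i] <- pr[[nm]][i] - 2 * h; dn <- lossAt(pr)
    num <- (up - dn) / (2 * h)
    # relative agreement; ReLU kinks inside the finite-difference interval
    # bound the attainable precision for the deep conv path
    expect_equal(P[[nm]]$grad[i], num, tolerance = 2e-2,
                 label = paste("grad", nm))
  }
})
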