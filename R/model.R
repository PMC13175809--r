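## The exam-level classifier family: a shared convolutional slice encoder,
## per-view slice aggregation (multi-scale attention, or mean / max /
## gated-attention-MIL baselines), and learned three-view fusion with three
## sigmoid outputs (abnormality, ACL tear, meniscus tear).

#' Model architecture configuration
#'
#' Defaults reproduce the benchmark architecture (encoder feature dimension
#' 2048, embedding 256, 4 heads, 2 attention layers, pooling kernels {1,3,5},
#' MLP hidden 512, dropout 0.2, 32 slices per view); tests use much smaller
#' values through the same contract.
#'
#' @param encoder_dim slice-embedding dimension D produced by the encoder.
#' @param embed_dim token/view embedding dimension E (divisible by `heads`).
#' @param heads number of attention heads.
#' @param attn_layers number of pre-norm self-attention layers.
#' @param pool_kernels odd positive window sizes for the parallel slice-axis
#'   average-pooling scales.
#' @param mlp_hidden hidden width of the fusion classifier.
#' @param dropout dropout probability in the fusion classifier (train only).
#' @param S slices per view (length of the positional embedding table).
#' @param positional_encoding learn a positional embedding over slice index
#'   (shared across scales)?
#' @param aggregator one of `"multiscale_attention"`, `"mean"`, `"max"`,
#'   `"attention_mil"`.
#' @param fusion `"concat_mlp"` (learned fusion) or `"average"` (view
#'   averaging ablation).
#' @param mil_hidden hidden width of the gated-attention-MIL scorer.
#' @param n_labels number of output labels (fixed at 3 here).
#' @return validated config list of class `ModelConfig`.
#' @export
modelConfig <- function(encoder_dim = 2048L, embed_dim = 256L, heads = 4L,
                        attn_layers = 2L, pool_kernels = c(1L, 3L, 5L),
                        mlp_hidden = 512L, dropout = 0.2, S = 32L,
                        positional_encoding = TRUE,
                        aggregator = c("multiscale_attention", "mean", "max",
                                       "attention_mil"),
                        fusion = c("concat_mlp", "average"),
                        mil_hidden = 64L, n_labels = 3L) {
  aggregator <- match.arg(aggregator)
  fusion <- match.arg(fusion)
  cfg <- list(encoder_dim = as.integer(encoder_dim),
              embed_dim = as.integer(embed_dim), heads = as.integer(heads),
              attn_layers = as.integer(attn_layers),
              pool_kernels = as.integer(pool_kernels),
              mlp_hidden = as.integer(mlp_hidden), dropout = dropout,
              S = as.integer(S),
              positional_encoding = isTRUE(positional_encoding),
              aggregator = aggregator, fusion = fusion,
              mil_hidden = as.integer(mil_hidden),
              n_labels = as.integer(n_labels))
  if (cfg$embed_dim %% cfg$heads != 0L)
    stop("modelConfig: embed_dim must be divisible by heads")
  if (any(cfg$pool_kernels < 1L) || any(cfg$pool_kernels %% 2L == 0L))
    stop("modelConfig: pool_kernels must be odd positive integers")
  if (cfg$n_labels != 3L)
    stop("modelConfig: n_labels is fixed at 3 (abnormal, acl, meniscus)")
  if (cfg$dropout < 0 || cfg$dropout >= 1)
    stop("modelConfig: dropout must be in [0, 1)")
  if (cfg$attn_layers < 1L) stop("modelConfig: attn_layers must be >= 1")
  class(cfg) <- "ModelConfig"
  cfg
}

encChannels <- function(D) c(16L, 32L, 64L, D)

#' Initialize a model
#'
#' Allocates and initializes all parameter tensors for the configured
#' aggregator/fusion variant (He initialization for ReLU fan-ins, scaled
#' Gaussian elsewhere, zero biases, unit layer-norm gains).
#'
#' @param config a [modelConfig()].
#' @param seed integer seed for the initialization draw.
#' @return a [MILModel-class].
#' @export
buildModel <- function(config, seed = 42L) {
  if (!inherits(config, "ModelConfig")) config <- do.call(modelConfig, config)
  set.seed(as.integer(seed))
  D <- config$encoder_dim; E <- config$embed_dim
  P <- list()
  he <- function(nin, nout) matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
  xa <- function(nin, nout) matrix(stats::rnorm(nin * nout, 0, sqrt(1 / nin)), nin, nout)
  zb <- function(k) matrix(0, 1L, k)
  ch <- encChannels(D)
  cin <- 1L
  for (i in seq_along(ch)) {
    P[[paste0("enc_W", i)]] <- he(cin * 9L, ch[i])
    P[[paste0("enc_b", i)]] <- zb(ch[i])
    cin <- ch[i]
  }
  if (config$aggregator == "multiscale_attention") {
    for (k in config$pool_kernels) {
      P[[paste0("proj_W_k", k)]] <- xa(D, E)
      P[[paste0("proj_b_k", k)]] <- zb(E)
      P[[paste0("scale_emb_k", k)]] <- matrix(stats::rnorm(E, 0, 0.02), 1L)
    }
    if (config$positional_encoding)
      P$pos_emb <- matrix(stats::rnorm(config$S * E, 0, 0.02), config$S, E)
    for (l in seq_len(config$attn_layers)) {
      P[[paste0("attn_Wq_", l)]] <- xa(E, E)
      P[[paste0("attn_Wk_", l)]] <- xa(E, E)
      P[[paste0("attn_Wv_", l)]] <- xa(E, E)
      P[[paste0("attn_Wo_", l)]] <- xa(E, E)
      P[[paste0("attn_bq_", l)]] <- zb(E)
      P[[paste0("attn_bk_", l)]] <- zb(E)
      P[[paste0("attn_bv_", l)]] <- zb(E)
      P[[paste0("attn_bo_", l)]] <- zb(E)
      P[[paste0("ln1_g_", l)]] <- matrix(1, 1L, E)
      P[[paste0("ln1_b_", l)]] <- zb(E)
      P[[paste0("ln2_g_", l)]] <- matrix(1, 1L, E)
      P[[paste0("ln2_b_", l)]] <- zb(E)
      P[[paste0("ffn_W1_", l)]] <- he(E, 2L * E)
      P[[paste0("ffn_b1_", l)]] <- zb(2L * E)
      P[[paste0("ffn_W2_", l)]] <- xa(2L * E, E)
      P[[paste0("ffn_b2_", l)]] <- zb(E)
    }
    P$readout_w <- matrix(stats::rnorm(E, 0, 0.02), E, 1L)
    P$readout_b <- matrix(0, 1L, 1L)
  } else {
    P$proj_W_k1 <- xa(D, E)
    P$proj_b_k1 <- zb(E)
    if (config$aggregator == "attention_mil") {
      L <- config$mil_hidden
      P$mil_V <- xa(D, L)
      P$mil_U <- xa(D, L)
      P$mil_w <- matrix(stats::rnorm(L, 0, sqrt(1 / L)), L, 1L)
    }
  }
  fin <- if (config$fusion == "concat_mlp") 3L * E else E
  P$fus_W1 <- he(fin, config$mlp_hidden)
  P$fus_b1 <- zb(config$mlp_hidden)
  P$fus_W2 <- xa(config$mlp_hidden, config$n_labels)
  P$fus_b2 <- zb(config$n_labels)
  methods::new("MILModel", params = P, config = unclass(config))
}

## slice-axis average pooling matrix: stride-1 windows of width k, truncated
## (averaged over valid entries) at the stack boundaries
poolMatrix <- function(S, k) {
  half <- (k - 1L) %/% 2L
  M <- matrix(0, S, S)
  for (i in seq_len(S)) {
    j <- max(1L, i - half):min(S, i + half)
    M[i, j] <- 1 / length(j)
  }
  M
}

#' Multi-scale slice pooling (pre-projection)
#'
#' Average pooling along the slice axis with stride 1 and windows truncated
#' at the boundaries (averaging over valid entries only).
#'
#' @param seq S x D slice-embedding matrix.
#' @param kernel odd positive window size.
#' @return S x D pooled matrix.
#' @export
multiscalePool <- function(seq, kernel) {
  if (kernel %% 2L == 0L || kernel < 1L)
    stop("multiscalePool: kernel must be an odd positive integer")
  poolMatrix(nrow(seq), kernel) %*% seq
}

## wrap raw parameter matrices as tape nodes (leaves when training)
paramNodes <- function(tape, params, trainable = FALSE) {
  lapply(params, function(p)
    if (trainable) agLeaf(tape, p) else agConst(tape, p))
}

## conv encoder: (N, 1, R, R) array node -> (N, D) embedding node
encoderForward <- function(tape, P, config, x) {
  nb <- length(encChannels(config$encoder_dim))
  h <- x
  for (i in seq_len(nb)) {
    h <- agConv2d(tape, h, P[[paste0("enc_W", i)]], P[[paste0("enc_b", i)]],
                  k = 3L, stride = 2L, pad = 1L)
    h <- agRelu(tape, h)
  }
  agGlobalAvgPool(tape, h)
}

transformerLayerForward <- function(tape, P, config, x, l) {
  E <- config$embed_dim
  dh <- E %/% config$heads
  ln1 <- agLayerNorm(tape, x, P[[paste0("ln1_g_", l)]], P[[paste0("ln1_b_", l)]])
  Q <- agAddBias(tape, agMatmul(tape, ln1, P[[paste0("attn_Wq_", l)]]), P[[paste0("attn_bq_", l)]])
  K <- agAddBias(tape, agMatmul(tape, ln1, P[[paste0("attn_Wk_", l)]]), P[[paste0("attn_bk_", l)]])
  V <- agAddBias(tape, agMatmul(tape, ln1, P[[paste0("attn_Wv_", l)]]), P[[paste0("attn_bv_", l)]])
  outs <- vector("list", config$heads)
  for (h in seq_len(config$heads)) {
    idx <- seq.int((h - 1L) * dh + 1L, h * dh)
    A <- agSoftmaxRows(tape, agScale(tape,
      agMatmul(tape, agCols(tape, Q, idx), agTranspose(tape, agCols(tape, K, idx))),
      1 / sqrt(dh)))
    outs[[h]] <- agMatmul(tape, A, agCols(tape, V, idx))
  }
  O <- agHcat(tape, outs)
  x <- agAdd(tape, x, agAddBias(tape, agMatmul(tape, O, P[[paste0("attn_Wo_", l)]]),
                                P[[paste0("attn_bo_", l)]]))
  ln2 <- agLayerNorm(tape, x, P[[paste0("ln2_g_", l)]], P[[paste0("ln2_b_", l)]])
  ff <- agAddBias(tape, agMatmul(tape,
    agRelu(tape, agAddBias(tape, agMatmul(tape, ln2, P[[paste0("ffn_W1_", l)]]),
                           P[[paste0("ffn_b1_", l)]])),
    P[[paste0("ffn_W2_", l)]]), P[[paste0("ffn_b2_", l)]])
  agAdd(tape, x, ff)
}

## multi-scale tokens from one view's slice-embedding node (S x D)
multiscaleTokensForward <- function(tape, P, config, emb) {
  S <- nrow(emb$val)
  toks <- lapply(config$pool_kernels, function(k) {
    pooled <- agConstMulLeft(tape, poolMatrix(S, k), emb)
    tk <- agAddBias(tape, agMatmul(tape, pooled, P[[paste0("proj_W_k", k)]]),
                    P[[paste0("proj_b_k", k)]])
    tk <- agAddBias(tape, tk, P[[paste0("scale_emb_k", k)]])
    if (config$positional_encoding) tk <- agAdd(tape, tk, P$pos_emb)
    tk
  })
  agVcat(tape, toks)
}

readoutForward <- function(tape, P, tokens) {
  scores <- agAddBias(tape, agMatmul(tape, tokens, P$readout_w), P$readout_b)
  a <- agSoftmaxRows(tape, agTranspose(tape, scores))
  list(emb = agMatmul(tape, a, tokens), weights = as.vector(a$val))
}

## one view's slice embeddings -> (1 x E) view embedding + readout weights
aggregateForward <- function(tape, P, config, emb) {
  switch(config$aggregator,
    multiscale_attention = {
      tokens <- multiscaleTokensForward(tape, P, config, emb)
      for (l in seq_len(config$attn_layers))
        tokens <- transformerLayerForward(tape, P, config, tokens, l)
      readoutForward(tape, P, tokens)
    },
    mean = {
      m <- agMeanRows(tape, emb)
      list(emb = agAddBias(tape, agMatmul(tape, m, P$proj_W_k1), P$proj_b_k1),
           weights = rep(1 / nrow(emb$val), nrow(emb$val)))
    },
    max = {
      m <- agMaxRows(tape, emb)
      list(emb = agAddBias(tape, agMatmul(tape, m, P$proj_W_k1), P$proj_b_k1),
           weights = NULL)
    },
    attention_mil = {
      gate <- agMul(tape, agTanh(tape, agMatmul(tape, emb, P$mil_V)),
                    agSigmoid(tape, agMatmul(tape, emb, P$mil_U)))
      a <- agSoftmaxRows(tape, agTranspose(tape, agMatmul(tape, gate, P$mil_w)))
      s <- agMatmul(tape, a, emb)
      list(emb = agAddBias(tape, agMatmul(tape, s, P$proj_W_k1), P$proj_b_k1),
           weights = as.vector(a$val))
    })
}

fusionForward <- function(tape, P, config, rows, train) {
  x <- agVcat(tape, rows)                       # B x 3E (or B x E)
  h <- agRelu(tape, agAddBias(tape, agMatmul(tape, x, P$fus_W1), P$fus_b1))
  h <- agDropout(tape, h, config$dropout, train)
  agAddBias(tape, agMatmul(tape, h, P$fus_W2), P$fus_b2)
}

## stack a list of exams into the (N, 1, R, R) slice array the encoder eats;
## rows are ordered exam-major, then view (sagittal, coronal, axial), then slice
stackExamSlices <- function(exams, config) {
  d <- dim(exams[[1]]@views[[1]])
  S <- d[1]; R <- d[2]
  B <- length(exams)
  x <- array(0, c(B * 3L * S, 1L, R, R))
  for (e in seq_len(B))
    for (v in seq_len(3L)) {
      rows <- ((e - 1L) * 3L + (v - 1L)) * S + seq_len(S)
      x[rows, 1L, , ] <- exams[[e]]@views[[v]]
    }
  x
}

## full forward pass over a batch of exams; returns the logits node plus
## per-exam-per-view readout weights
forwardExams <- function(tape, P, config, exams, train = FALSE) {
  S <- dim(exams[[1]]@views[[1]])[1]
  x <- agConst(tape, stackExamSlices(exams, config))
  emb <- encoderForward(tape, P, config, x)
  B <- length(exams)
  rows <- vector("list", B)
  attn <- vector("list", B)
  for (e in seq_len(B)) {
    vembs <- vector("list", 3L)
    aw <- vector("list", 3L)
    for (v in seq_len(3L)) {
      ridx <- ((e - 1L) * 3L + (v - 1L)) * S + seq_len(S)
      agg <- aggregateForward(tape, P, config, agRows(tape, emb, ridx))
      vembs[[v]] <- agg$emb
      aw[v] <- list(agg$weights)
    }
    names(aw) <- VIEW_NAMES
    attn[[e]] <- aw
    rows[[e]] <- if (config$fusion == "concat_mlp") agHcat(tape, vembs) else
      agScale(tape, agAdd(tape, agAdd(tape, vembs[[1]], vembs[[2]]), vembs[[3]]), 1 / 3)
  }
  logits <- fusionForward(tape, P, config, rows, train)
  list(logits = logits, attention = attn)
}

#' Predict exam-level probabilities
#'
#' Runs the model in evaluation mode (dropout off, fully deterministic) over
#' a list of preprocessed exams.
#'
#' @param model a [MILModel-class].
#' @param exams list of [ExamTensor-class].
#' @param batchSize exams per forward pass.
#' @return list with `probs` and `logits` (n x 3 matrices, columns abnormal/
#'   acl/meniscus, rownames = exam ids) and `attention` (per exam, per view,
#'   the aggregator's slice/token weights where defined).
#' @export
predictExams <- function(model, exams, batchSize = 16L) {
  config <- model@config
  n <- length(exams)
  logits <- matrix(NA_real_, n, 3L,
                   dimnames = list(vapply(exams, examId, ""), LABEL_NAMES))
  attention <- vector("list", n)
  for (start in seq.int(1L, n, by = batchSize)) {
    idx <- start:min(start + batchSize - 1L, n)
    tape <- agTape()
    P <- paramNodes(tape, model@params)
    fw <- forwardExams(tape, P, config, exams[idx], train = FALSE)
    logits[idx, ] <- fw$logits$val
    attention[idx] <- fw$attention
  }
  names(attention) <- rownames(logits)
  list(probs = stats::plogis(logits), logits = logits, attention = attention)
}

## ---- standalone op surface (evaluation-mode, plain matrices) ---------------

#' Encode a view's slices into a slice-embedding sequence
#'
#' With a function encoder, applies it slice by slice (the contract: one
#' `R x R` slice in, one length-D vector out, shared across slices and views).
#' With a [MILModel-class], runs its convolutional encoder.
#'
#' @param viewStack rank-3 array (S x R x R).
#' @param encoder a function(slice matrix) -> numeric vector, or a `MILModel`.
#' @return S x D embedding matrix, row k the embedding of slice k.
#' @export
encodeSlices <- function(viewStack, encoder) {
  if (!is.array(viewStack) || length(dim(viewStack)) != 3L)
    stop("encodeSlices: viewStack must be a rank-3 array (S x R x R)")
  S <- dim(viewStack)[1]
  if (methods::is(encoder, "MILModel")) {
    tape <- agTape()
    P <- paramNodes(tape, encoder@params)
    x <- array(0, c(S, 1L, dim(viewStack)[2], dim(viewStack)[3]))
    x[, 1L, , ] <- viewStack
    return(encoderForward(tape, P, encoder@config, agConst(tape, x))$val)
  }
  first <- encoder(viewStack[1, , ])
  if (!is.numeric(first) || is.null(length(first)))
    stop("encodeSlices: encoder must return a numeric vector; got ",
         class(first)[1])
  D <- length(first)
  out <- matrix(NA_real_, S, D)
  out[1, ] <- first
  for (s in seq_len(S)[-1]) {
    v <- encoder(viewStack[s, , ])
    if (length(v) != D)
      stop("encodeSlices: encoder dimension mismatch: expected ", D,
           ", got ", length(v), " at slice ", s)
    out[s, ] <- v
  }
  out
}

#' Multi-scale token sequence for one view
#'
#' Pools the slice-embedding sequence at each configured kernel (stride 1,
#' truncated windows), applies the scale-specific D-to-E projection, adds the
#' scale embedding and (if enabled) the shared positional embedding, and
#' concatenates the per-scale token sets along the token axis in kernel order.
#'
#' @param model a [MILModel-class] with the multi-scale aggregator.
#' @param seq S x D slice-embedding matrix.
#' @return (length(kernels) * S) x E token matrix.
#' @export
multiscaleTokens <- function(model, seq) {
  if (model@config$aggregator != "multiscale_attention")
    stop("multiscaleTokens: model does not use the multi-scale aggregator")
  tape <- agTape()
  P <- paramNodes(tape, model@params)
  multiscaleTokensForward(tape, P, model@config, agConst(tape, seq))$val
}

#' Attention aggregation of a token sequence
#'
#' Applies the model's pre-norm self-attention layers and the learned-query
#' softmax readout to a token sequence.
#'
#' @param model a [MILModel-class] with the multi-scale aggregator.
#' @param tokens T x E token matrix.
#' @return list with `embedding` (length-E vector) and `weights` (length-T
#'   readout probability vector).
#' @export
attentionAggregate <- function(model, tokens) {
  config <- model@config
  tape <- agTape()
  P <- paramNodes(tape, model@params)
  tk <- agConst(tape, tokens)
  for (l in seq_len(config$attn_layers))
    tk <- transformerLayerForward(tape, P, config, tk, l)
  ro <- readoutForward(tape, P, tk)
  list(embedding = as.vector(ro$emb$val), weights = ro$weights)
}

#' Mean / max pooling over slice embeddings
#'
#' Coordinate-wise mean (or max) over slices, optionally followed by the
#' shared D-to-E projection (`proj = list(W, b)`).
#'
#' @param seq S x D slice-embedding matrix.
#' @param proj optional projection, `list(W = D x E, b = length-E)`.
#' @return pooled vector (length D, or E when projected).
#' @export
poolMean <- function(seq, proj = NULL) {
  m <- colMeans(seq)
  if (is.null(proj)) m else as.vector(m %*% proj$W + proj$b)
}

#' @rdname poolMean
#' @export
poolMax <- function(seq, proj = NULL) {
  m <- apply(seq, 2L, max)
  if (is.null(proj)) m else as.vector(m %*% proj$W + proj$b)
}

#' Gated-attention multiple-instance pooling
#'
#' Scores each instance by `w' (tanh(V' h) * sigmoid(U' h))`, softmax-
#' normalizes the scores over instances, and returns the weighted sum.
#'
#' @param seq S x D instance matrix.
#' @param params `list(V = D x L, U = D x L, w = length-L)`; taken from the
#'   model when omitted and `model` is given.
#' @param model optional [MILModel-class] built with `aggregator =
#'   "attention_mil"`.
#' @return list with `summary` (length-D vector, pre-projection) and
#'   `weights` (length-S probability vector).
#' @export
poolAttentionMIL <- function(seq, params = NULL, model = NULL) {
  if (is.null(params)) {
    if (is.null(model)) stop("poolAttentionMIL: provide params or model")
    params <- list(V = model@params$mil_V, U = model@params$mil_U,
                   w = as.vector(model@params$mil_w))
  }
  sc <- (tanh(seq %*% params$V) * stats::plogis(seq %*% params$U)) %*% params$w
  a <- exp(sc - max(sc))
  a <- as.vector(a / sum(a))
  list(summary = as.vector(crossprod(seq, a)), weights = a)
}

#' Fuse three view embeddings and classify
#'
#' Concatenates the (sagittal, coronal, axial) view embeddings in that fixed
#' order (or averages them for the view-averaging ablation) and applies the
#' two-layer MLP head; probabilities are plain logistic outputs with no
#' post-hoc temperature scaling.
#'
#' @param model a [MILModel-class].
#' @param viewEmbeddings list of exactly three length-E vectors, in order
#'   sagittal, coronal, axial (names, when present, must match).
#' @return an `ExamPrediction`: list with `probs` and `logits` (named length-3
#'   vectors).
#' @export
fuseAndClassify <- function(model, viewEmbeddings) {
  if (!is.list(viewEmbeddings) || length(viewEmbeddings) != 3L)
    stop("fuseAndClassify: expected exactly 3 view embeddings, got ",
         length(viewEmbeddings))
  if (!is.null(names(viewEmbeddings)) &&
      !identical(names(viewEmbeddings), VIEW_NAMES))
    stop("fuseAndClassify: views must be ordered sagittal, coronal, axial")
  P <- model@params
  config <- model@config
  x <- if (config$fusion == "concat_mlp")
    matrix(unlist(viewEmbeddings), 1L) else
    matrix(Reduce(`+`, viewEmbeddings) / 3, 1L)
  h <- pmax(x %*% P$fus_W1 + matrix(P$fus_b1, 1L), 0)
  logits <- as.vector(h %*% P$fus_W2 + as.vector(P$fus_b2))
  names(logits) <- LABEL_NAMES
  structure(list(probs = stats::plogis(logits), logits = logits),
            class = "ExamPrediction")
}

#' Binary cross-entropy over probabilities
#'
#' Mean over all entries of `-(y log p + (1-y) log(1-p))`, with probabilities
#' clamped to `[eps, 1-eps]`.
#'
#' @param probs,labels equally shaped numeric probability/label arrays.
#' @param eps clamp bound (default 1e-7).
#' @return scalar loss.
#' @export
bceLoss <- function(probs, labels, eps = 1e-7) {
  if (length(probs) != length(labels))
    stop("bceLoss: probs and labels must have equal shape")
  p <- pmin(pmax(probs, eps), 1 - eps)
  mean(-(labels * log(p) + (1 - labels) * log(1 - p)))
}

#' Zero the attention pathway of a multi-scale model
#'
#' Sets all self-attention projections, feed-forward weights, readout scorer,
#' scale embeddings and positional embeddings to zero. With pooling kernels
#' {1} the aggregator then reduces exactly to mean pooling through the shared
#' projection (layer-norm gains are left at 1; the residual blocks become
#' identities because their output projections are zero).
#'
#' @param model a [MILModel-class] with the multi-scale aggregator.
#' @return the modified model.
#' @export
zeroAttentionParams <- function(model) {
  P <- model@params
  pats <- c("^attn_", "^ffn_", "^readout_", "^scale_emb_", "^pos_emb$",
            "^ln[12]_b_")
  for (nm in names(P))
    if (any(vapply(pats, function(p) grepl(p, nm), TRUE)))
      P[[nm]][] <- 0
  methods::initialize(model, params = P)
}

#' Write per-token attention weights to CSV
#'
#' @param prediction result of [predictExams()].
#' @param path output CSV path (columns exam_id, view, token, weight).
#' @return `path`, invisibly.
#' @export
writeAttentionCSV <- function(prediction, path) {
  rows <- list()
  for (id in names(prediction$attention))
    for (v in VIEW_NAMES) {
      w <- prediction$attention[[id]][[v]]
      if (is.null(w)) next
      rows[[length(rows) + 1L]] <- data.frame(
        exam_id = id, view = v, token = seq_along(w) - 1L, weight = w,
        stringsAsFactors = FALSE)
    }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
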