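## Multimodal framework extensions: composable units for fusing visual,
## temporal/biomechanical and auxiliary feature vectors, the focal-style risk
## loss, the recurrent state update, and hierarchical output combination.
##
## None of these units participates in the benchmarked visual-only model:
## the default model/training configuration activates none of them (a
## configuration audit in the test suite asserts this). They are provided as
## individually tested building blocks for future multimodal instantiations.

maskedFeatures <- function(F_v, F_t, F_a, mask = NULL) {
  feats <- list(v = F_v, t = F_t, a = F_a)
  if (is.null(mask)) mask <- !vapply(feats, is.null, TRUE)
  mask <- as.logical(mask)
  avail <- feats[mask]
  if (length(avail) == 0L)
    stop("no available modality: at least one feature vector is required")
  lens <- vapply(avail, length, 1L)
  if (length(unique(lens)) != 1L)
    stop("available feature vectors must have equal length")
  if (!all(vapply(avail, function(f) all(is.finite(f)), TRUE)))
    stop("available feature vectors must be finite")
  list(feats = feats, mask = mask, avail = avail)
}

#' Adaptive weighted modality fusion
#'
#' Softmax weights over the available modalities (masked out modalities get
#' zero weight and the softmax renormalizes over the rest); the fused vector
#' is the weighted sum, so the weights always lie on the probability simplex.
#'
#' @param F_v,F_t,F_a equal-length feature vectors (`NULL` = unavailable).
#' @param logits length-3 weight logits (visual, temporal, auxiliary).
#' @param mask optional logical length-3 availability mask overriding the
#'   `NULL` convention.
#' @return list with `fused` (vector) and `weights` (length-3, zeros at
#'   unavailable slots, summing to 1).
#' @export
adaptiveWeightedFusion <- function(F_v = NULL, F_t = NULL, F_a = NULL,
                                   logits = c(0, 0, 0), mask = NULL) {
  mf <- maskedFeatures(F_v, F_t, F_a, mask)
  lg <- logits[mf$mask]
  w <- exp(lg - max(lg))
  w <- w / sum(w)
  weights <- numeric(3L)
  weights[mf$mask] <- w
  names(weights) <- c("visual", "temporal", "auxiliary")
  fused <- Reduce(`+`, Map(`*`, mf$avail, w))
  list(fused = fused, weights = weights)
}

#' Two-stage cross-modal fusion
#'
#' Stage one computes a two-way softmax gate over the concatenated
#' visual/temporal pair, `[a1, a2] = softmax(W_alpha [F_v; F_t] + b_alpha)`,
#' and blends `F_vt = a1 F_v + a2 F_t`; stage two folds in the auxiliary
#' vector, `F_joint = tanh(W_psi [F_vt; F_a] + b_psi)`, so every output entry
#' lies strictly in (-1, 1).
#'
#' @param F_v,F_t,F_a equal-length feature vectors.
#' @param params list with `W_alpha` (2 x 2d), `b_alpha` (length 2),
#'   `W_psi` (d x 2d), `b_psi` (length d).
#' @return list with `F_joint`, `F_vt` and the gate `alpha`.
#' @export
crossModalFuse <- function(F_v, F_t, F_a, params) {
  d <- length(F_v)
  if (length(F_t) != d || length(F_a) != d)
    stop("crossModalFuse: feature vectors must have equal length")
  if (!identical(dim(params$W_alpha), c(2L, 2L * d)) ||
      !identical(dim(params$W_psi), c(d, 2L * d)))
    stop("crossModalFuse: parameter dimensions do not match feature length ", d)
  z <- as.vector(params$W_alpha %*% c(F_v, F_t)) + params$b_alpha
  alpha <- exp(z - max(z))
  alpha <- alpha / sum(alpha)
  F_vt <- alpha[1] * F_v + alpha[2] * F_t
  F_joint <- tanh(as.vector(params$W_psi %*% c(F_vt, F_a)) + params$b_psi)
  list(F_joint = F_joint, F_vt = F_vt, alpha = alpha)
}

#' Cross-modal alignment loss
#'
#' Sum over ordered pairs of available modalities of the squared distance
#' between unit-L2-normalized features (each unordered pair counted twice);
#' zero iff all normalized features coincide, and invariant to positive
#' rescaling of any feature.
#'
#' @param features list of at least two equal-length feature vectors.
#' @return nonnegative scalar.
#' @export
alignmentLoss <- function(features) {
  if (length(features) < 2L)
    stop("alignmentLoss: need at least two available modalities")
  norm <- lapply(features, function(f) {
    n <- sqrt(sum(f^2))
    if (n == 0) stop("alignmentLoss: a zero vector cannot be normalized")
    f / n
  })
  total <- 0
  for (i in seq_along(norm))
    for (j in seq_along(norm))
      if (i != j) total <- total + sum((norm[[i]] - norm[[j]])^2)
  total
}

#' Feature-dimension attention reweighting
#'
#' `alpha = softmax(W_a F_joint + b_a)` over feature dimensions (summing to
#' 1), applied elementwise: `F_attn = alpha * F_joint`.
#'
#' @param F_joint finite feature vector.
#' @param params list with `W_a` (d x d) and `b_a` (length d).
#' @return list with `F_attn` and `alpha`.
#' @export
attentionReweight <- function(F_joint, params) {
  z <- as.vector(params$W_a %*% F_joint) + params$b_a
  alpha <- exp(z - max(z))
  alpha <- alpha / sum(alpha)
  list(F_attn = alpha * F_joint, alpha = alpha)
}

#' Latent risk score and injury probability
#'
#' `s = act(W_s [F_attn; H] + b_s)` with a bounded activation (tanh by
#' default, sigmoid switchable), then `P = logistic(s)`; with tanh the
#' probability is confined to (logistic(-1), logistic(1)).
#'
#' @param F_attn reweighted feature vector.
#' @param H recurrent context vector.
#' @param params list with `W_s` (1 x (d+h) or vector) and `b_s` (scalar).
#' @param activation `"tanh"` or `"sigmoid"` for the latent score.
#' @return list with `score` and `probability`.
#' @export
riskScore <- function(F_attn, H, params, activation = c("tanh", "sigmoid")) {
  activation <- match.arg(activation)
  z <- sum(as.vector(params$W_s) * c(F_attn, H)) + params$b_s
  s <- if (activation == "tanh") tanh(z) else stats::plogis(z)
  list(score = s, probability = stats::plogis(s))
}

#' Focal-style risk loss
#'
#' `-(1-P)^gamma * y * log(P) - P^gamma * (1-y) * log(1-P)`, with the
#' asymmetric modulators exactly as formulated; reduces to binary
#' cross-entropy at `gamma = 0`.
#'
#' @param P predicted probabilities in (0, 1) (clamped at 1e-7).
#' @param y binary labels.
#' @param gamma nonnegative focusing parameter.
#' @return mean loss over the inputs.
#' @export
focalRiskLoss <- function(P, y, gamma) {
  if (gamma < 0) stop("focalRiskLoss: gamma must be >= 0")
  eps <- 1e-7
  P <- pmin(pmax(P, eps), 1 - eps)
  mean(-(1 - P)^gamma * y * log(P) - P^gamma * (1 - y) * log(1 - P))
}

#' Recurrent state update
#'
#' `H_t = tanh(W_h H_prev + W_x X_t + b_h)` and output
#' `y_t = logistic(W_o H_t + b_o)`.
#'
#' @param H_prev previous hidden state (length h).
#' @param X_t input vector at time t.
#' @param params list with `W_h` (h x h), `W_x` (h x d), `b_h` (length h),
#'   `W_o` (k x h or vector), `b_o` (length k or scalar).
#' @return list with `H` (new state, entries in (-1, 1)) and `y` (output
#'   probabilities).
#' @export
recurrentStep <- function(H_prev, X_t, params) {
  H <- tanh(as.vector(params$W_h %*% H_prev) +
            as.vector(params$W_x %*% X_t) + params$b_h)
  Wo <- params$W_o
  y <- if (is.matrix(Wo)) stats::plogis(as.vector(Wo %*% H) + params$b_o)
       else stats::plogis(sum(Wo * H) + params$b_o)
  list(H = H, y = y)
}

#' Hierarchical output combination
#'
#' `O_final = alpha * O_irpm + beta * O_pom`, linear in each argument.
#'
#' @param O_irpm,O_pom equally shaped numeric outputs.
#' @param alpha,beta combination weights.
#' @return combined output.
#' @export
hierarchicalCombine <- function(O_irpm, O_pom, alpha, beta) {
  if (!identical(dim(O_irpm), dim(O_pom)) ||
      length(O_irpm) != length(O_pom))
    stop("hierarchicalCombine: outputs must have identical shape")
  alpha * O_irpm + beta * O_pom
}

#' Which extension units does a configuration activate?
#'
#' Audit helper: inspects a model + training configuration and reports every
#' framework-extension mechanism it would activate. The benchmark
#' configuration (multi-scale attention aggregator, concat-MLP fusion,
#' plain BCE loss) activates none.
#'
#' @param modelCfg a [modelConfig()].
#' @param trainCfg a [trainConfig()].
#' @return character vector of activated extension names (empty for the
#'   benchmark configuration).
#' @export
activeExtensions <- function(modelCfg, trainCfg) {
  active <- character()
  if (!is.null(modelCfg$focal_gamma)) active <- c(active, "focal_risk_loss")
  if (!is.null(modelCfg$alignment_weight)) active <- c(active, "alignment_loss")
  if (!is.null(modelCfg$constraint_weight))
    active <- c(active, "constraint_penalty")
  if (!is.null(modelCfg$modalities) &&
      length(setdiff(modelCfg$modalities, "visual")))
    active <- c(active, "cross_modal_fusion")
  if (!is.null(trainCfg$pom)) active <- c(active, "pom_optimizer")
  active
}
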