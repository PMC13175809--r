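## Reverse-mode automatic differentiation on a flat tape.
##
## Nodes are environments holding a value, an accumulated gradient, and a
## backward closure; ops append nodes to the tape in execution order, so the
## reverse sweep is a single backwards pass over the tape (already a valid
## topological order). Values are dense numeric matrices except for the
## convolution/GAP ops, which carry 4-D arrays (N, C, H, W).

agTape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

agNode <- function(tape, val, bw = NULL, const = FALSE) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$bw <- bw
  nd$const <- const
  if (tape$n == length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$n <- tape$n + 1L
  tape$nodes[[tape$n]] <- nd
  nd
}

## leaf with gradient tracking (a trainable parameter)
agLeaf <- function(tape, val) agNode(tape, val)

## leaf without gradient tracking (an input / fixed tensor)
agConst <- function(tape, val) agNode(tape, val, const = TRUE)

agAccum <- function(nd, g) {
  if (nd$const) return(invisible(NULL))
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

## seed the output node with gradient 1 and sweep the tape in reverse
agBackward <- function(tape, node) {
  node$grad <- if (is.matrix(node$val)) matrix(1, nrow(node$val), ncol(node$val)) else 1
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$bw)) nd$bw(nd$grad)
  }
  invisible(NULL)
}

agMatmul <- function(tape, a, b) {
  agNode(tape, a$val %*% b$val, bw = function(g) {
    agAccum(a, g %*% t(b$val))
    agAccum(b, crossprod(a$val, g))
  })
}

agAdd <- function(tape, a, b) {
  agNode(tape, a$val + b$val, bw = function(g) {
    agAccum(a, g)
    agAccum(b, g)
  })
}

## add a 1 x k bias row to every row of an n x k matrix
agAddBias <- function(tape, x, b) {
  agNode(tape, sweep(x$val, 2L, as.vector(b$val), "+"), bw = function(g) {
    agAccum(x, g)
    agAccum(b, matrix(colSums(g), 1L))
  })
}

agScale <- function(tape, x, s) {
  agNode(tape, x$val * s, bw = function(g) agAccum(x, g * s))
}

agMul <- function(tape, a, b) {
  agNode(tape, a$val * b$val, bw = function(g) {
    agAccum(a, g * b$val)
    agAccum(b, g * a$val)
  })
}

agRelu <- function(tape, x) {
  mask <- x$val > 0
  agNode(tape, x$val * mask, bw = function(g) agAccum(x, g * mask))
}

agTanh <- function(tape, x) {
  y <- tanh(x$val)
  agNode(tape, y, bw = function(g) agAccum(x, g * (1 - y^2)))
}

agSigmoid <- function(tape, x) {
  y <- stats::plogis(x$val)
  agNode(tape, y, bw = function(g) agAccum(x, g * y * (1 - y)))
}

agSoftmaxRows <- function(tape, x) {
  m <- x$val - apply(x$val, 1L, max)
  e <- exp(m)
  y <- e / rowSums(e)
  agNode(tape, y, bw = function(g) {
    agAccum(x, y * (g - rowSums(g * y)))
  })
}

## row-wise layer normalization with learned gain/offset (1 x k each)
agLayerNorm <- function(tape, x, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(x$val)
  xc <- x$val - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  gv <- as.vector(gamma$val)
  val <- sweep(xhat, 2L, gv, "*")
  val <- sweep(val, 2L, as.vector(beta$val), "+")
  agNode(tape, val, bw = function(g) {
    agAccum(gamma, matrix(colSums(g * xhat), 1L))
    agAccum(beta, matrix(colSums(g), 1L))
    gy <- sweep(g, 2L, gv, "*")
    agAccum(x, inv * (gy - rowMeans(gy) - xhat * rowMeans(gy * xhat)))
  })
}

## fixed-matrix left multiply (used for the slice-axis pooling operators)
agConstMulLeft <- function(tape, M, x) {
  agNode(tape, M %*% x$val, bw = function(g) agAccum(x, crossprod(M, g)))
}

agRows <- function(tape, x, idx) {
  n <- nrow(x$val)
  agNode(tape, x$val[idx, , drop = FALSE], bw = function(g) {
    gf <- matrix(0, n, ncol(g))
    if (anyDuplicated(idx)) {
      rs <- rowsum(g, idx)
      gf[as.integer(rownames(rs)), ] <- rs
    } else gf[idx, ] <- g
    agAccum(x, gf)
  })
}

agCols <- function(tape, x, idx) {
  k <- ncol(x$val)
  agNode(tape, x$val[, idx, drop = FALSE], bw = function(g) {
    gf <- matrix(0, nrow(g), k)
    gf[, idx] <- g
    agAccum(x, gf)
  })
}

agVcat <- function(tape, xs) {
  rows <- vapply(xs, function(x) nrow(x$val), 1L)
  ends <- cumsum(rows)
  agNode(tape, do.call(rbind, lapply(xs, function(x) x$val)), bw = function(g) {
    for (i in seq_along(xs))
      agAccum(xs[[i]], g[seq.int(ends[i] - rows[i] + 1L, ends[i]), , drop = FALSE])
  })
}

agHcat <- function(tape, xs) {
  cols <- vapply(xs, function(x) ncol(x$val), 1L)
  ends <- cumsum(cols)
  agNode(tape, do.call(cbind, lapply(xs, function(x) x$val)), bw = function(g) {
    for (i in seq_along(xs))
      agAccum(xs[[i]], g[, seq.int(ends[i] - cols[i] + 1L, ends[i]), drop = FALSE])
  })
}

agTranspose <- function(tape, x) {
  agNode(tape, t(x$val), bw = function(g) agAccum(x, t(g)))
}

agMeanRows <- function(tape, x) {
  n <- nrow(x$val)
  agNode(tape, matrix(colMeans(x$val), 1L), bw = function(g) {
    agAccum(x, matrix(as.vector(g), n, ncol(g), byrow = TRUE) / n)
  })
}

agMaxRows <- function(tape, x) {
  amax <- max.col(t(x$val), ties.method = "first")
  k <- ncol(x$val)
  val <- matrix(x$val[cbind(amax, seq_len(k))], 1L)
  agNode(tape, val, bw = function(g) {
    gf <- matrix(0, nrow(x$val), k)
    gf[cbind(amax, seq_len(k))] <- as.vector(g)
    agAccum(x, gf)
  })
}

## inverted dropout; draws its mask from the current RNG stream
agDropout <- function(tape, x, p, train) {
  if (!train || p <= 0) return(x)
  mask <- (matrix(stats::runif(length(x$val)), nrow(x$val)) >= p) / (1 - p)
  agNode(tape, x$val * mask, bw = function(g) agAccum(x, g * mask))
}

## numerically stable mean binary cross-entropy straight from logits
agBceWithLogits <- function(tape, z, y) {
  zv <- z$val
  n <- length(zv)
  val <- sum(pmax(zv, 0) - y * zv + log1p(exp(-abs(zv)))) / n
  agNode(tape, val, bw = function(g) {
    agAccum(z, g * (stats::plogis(zv) - y) / n)
  })
}

## ---- convolution -----------------------------------------------------------

convIdxCache <- new.env(parent = emptyenv())

## im2col gather indices into the zero-padded (N, C, Hp, Wp) array, rows
## ordered n fastest, then output row, then output column
convIndices <- function(N, C, H, W, k, stride, pad) {
  key <- paste(N, C, H, W, k, stride, pad, sep = "_")
  got <- convIdxCache[[key]]
  if (!is.null(got)) return(got)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  OH <- (Hp - k) %/% stride + 1L
  OW <- (Wp - k) %/% stride + 1L
  i0 <- (seq_len(OH) - 1L) * stride + 1L          # window top rows
  j0 <- (seq_len(OW) - 1L) * stride + 1L
  ## base linear index (n = 1) for element (c, ki, kj) of window (oh, ow):
  ## idx = 1 + (c-1)*N + (i-1)*N*C + (j-1)*N*C*Hp
  ohw <- expand.grid(i0 = i0, j0 = j0)            # oh fastest (column-major)
  ckk <- expand.grid(c = seq_len(C), ki = seq_len(k), kj = seq_len(k))
  ii <- outer(ohw$i0, ckk$ki - 1L, "+")           # (OH*OW) x (C*k*k)
  jj <- outer(ohw$j0, ckk$kj - 1L, "+")
  cc <- matrix(ckk$c, nrow(ii), ncol(ii), byrow = TRUE)
  idx1 <- 1 + (cc - 1) * N + (ii - 1) * (N * C) + (jj - 1) * (N * C * Hp)
  idx <- idx1[rep(seq_len(nrow(idx1)), each = N), , drop = FALSE] +
    rep(seq_len(N) - 1L, times = nrow(idx1))
  storage.mode(idx) <- "integer"
  out <- new.env(parent = emptyenv())
  out$idx <- idx; out$OH <- OH; out$OW <- OW; out$Hp <- Hp; out$Wp <- Wp
  convIdxCache[[key]] <- out
  out
}

## lazily built scatter-add metadata: gather indices sorted once, group sums
## recovered from a cumulative sum at the cached group boundaries
convScatterMeta <- function(ci) {
  if (!is.null(ci$ord)) return(ci)
  v <- as.vector(ci$idx)
  ci$ord <- order(v)
  sorted <- v[ci$ord]
  ci$ends <- which(sorted != c(sorted[-1L], -1L))
  ci$uidx <- sorted[ci$ends]
  ci
}

## 2-D convolution over x: 4-D array (N, C, H, W); W kernel matrix (C*k*k, F),
## b bias (1, F); stride/pad scalars. Output array (N, F, OH, OW).
agConv2d <- function(tape, x, Wk, b, k, stride = 2L, pad = 1L) {
  d <- dim(x$val)
  N <- d[1]; C <- d[2]; H <- d[3]; Wd <- d[4]
  ci <- convIndices(N, C, H, Wd, k, stride, pad)
  xp <- array(0, c(N, C, ci$Hp, ci$Wp))
  xp[, , pad + seq_len(H), pad + seq_len(Wd)] <- x$val
  colm <- matrix(xp[ci$idx], nrow(ci$idx), ncol(ci$idx))
  out <- colm %*% Wk$val
  out <- sweep(out, 2L, as.vector(b$val), "+")
  Fch <- ncol(out)
  val <- aperm(array(out, c(N, ci$OH, ci$OW, Fch)), c(1L, 4L, 2L, 3L))
  agNode(tape, val, bw = function(g) {
    G <- matrix(aperm(g, c(1L, 3L, 4L, 2L)), nrow(colm), Fch)
    agAccum(Wk, crossprod(colm, G))
    agAccum(b, matrix(colSums(G), 1L))
    if (!x$const) {
      dcol <- G %*% t(Wk$val)
      ci <- convScatterMeta(ci)
      cs <- cumsum(as.vector(dcol)[ci$ord])
      gp <- numeric(length(xp))
      gp[ci$uidx] <- diff(c(0, cs[ci$ends]))
      gp <- array(gp, dim(xp))
      agAccum(x, gp[, , pad + seq_len(H), pad + seq_len(Wd), drop = FALSE])
    }
  })
}

## global average pool: (N, F, OH, OW) array -> (N, F) matrix
agGlobalAvgPool <- function(tape, x) {
  d <- dim(x$val)
  sp <- d[3] * d[4]
  M <- matrix(x$val, d[1] * d[2], sp)
  agNode(tape, matrix(rowMeans(M), d[1], d[2]), bw = function(g) {
    agAccum(x, array(rep(as.vector(g), sp), d) / sp)
  })
}
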