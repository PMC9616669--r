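# Independent reference implementations used as oracles. All deliberately
# written as plain scalar loops / direct formula transcriptions, sharing no
# code with the package's tensor engine. Arrays use the public N x C x H x W
# layout.

oracleConv3x3 <- function(x, w, b, d = 1) {
  N <- dim(x)[1]; C <- dim(x)[2]; H <- dim(x)[3]; W <- dim(x)[4]
  Cout <- dim(w)[4]
  out <- array(0, c(N, Cout, H, W))
  for (n in 1:N) for (co in 1:Cout) for (h in 1:H) for (v in 1:W) {
    s <- b[co]
    for (i in 1:3) for (j in 1:3) for (ci in 1:C) {
      hh <- h + (i - 2) * d; vv <- v + (j - 2) * d
      if (hh >= 1 && hh <= H && vv >= 1 && vv <= W)
        s <- s + x[n, ci, hh, vv] * w[i, j, ci, co]
    }
    out[n, co, h, v] <- s
  }
  out
}

oracleConvT2 <- function(x, w, b) {
  N <- dim(x)[1]; C <- dim(x)[2]; H <- dim(x)[3]; W <- dim(x)[4]
  Cout <- dim(w)[4]
  out <- array(0, c(N, Cout, 2 * H, 2 * W))
  for (n in 1:N) for (co in 1:Cout) for (h in 1:H) for (v in 1:W)
    for (i in 1:2) for (j in 1:2) for (ci in 1:C)
      out[n, co, 2 * (h - 1) + i, 2 * (v - 1) + j] <-
        out[n, co, 2 * (h - 1) + i, 2 * (v - 1) + j] + x[n, ci, h, v] * w[i, j, ci, co]
  for (co in 1:Cout) out[, co, , ] <- out[, co, , ] + b[co]
  out
}

# batch norm in eval mode with stored running statistics
oracleBNEval <- function(x, gamma, beta, rmean = NULL, rvar = NULL, eps = 1e-5) {
  C <- dim(x)[2]
  if (is.null(rmean)) rmean <- numeric(C)
  if (is.null(rvar)) rvar <- rep(1, C)
  out <- x
  for (c in 1:C)
    out[, c, , ] <- (x[, c, , ] - rmean[c]) / sqrt(rvar[c] + eps) * gamma[c] + beta[c]
  out
}

oracleRelu <- function(x) pmax(x, 0)
oracleSigmoid <- function(x) 1 / (1 + exp(-x))

# the package's conv unit in eval mode: ReLU(BN(conv3x3))
oracleConvBNEval <- function(x, p, d = 1)
  oracleRelu(oracleBNEval(oracleConv3x3(x, p$w, p$b, d), p$gamma, p$beta))

oracleGAP <- function(x) {           # (N,C,H,W) -> (N,C)
  N <- dim(x)[1]; C <- dim(x)[2]
  g <- matrix(0, N, C)
  for (n in 1:N) for (c in 1:C) g[n, c] <- mean(x[n, c, , ])
  g
}

oracleChannelAttention <- function(x, w1, b1, w2, b2) {
  g <- oracleGAP(x)
  h <- oracleRelu(sweep(g %*% w1, 2, b1, `+`))
  oracleSigmoid(sweep(h %*% w2, 2, b2, `+`))
}

oracleSoftmaxC <- function(x) {
  out <- x
  N <- dim(x)[1]; H <- dim(x)[3]; W <- dim(x)[4]
  for (n in 1:N) for (h in 1:H) for (v in 1:W) {
    z <- exp(x[n, , h, v] - max(x[n, , h, v]))
    out[n, , h, v] <- z / sum(z)
  }
  out
}

oracleL2NormC <- function(x, eps = 1e-8) {
  out <- x
  N <- dim(x)[1]; H <- dim(x)[3]; W <- dim(x)[4]
  for (n in 1:N) for (h in 1:H) for (v in 1:W)
    out[n, , h, v] <- x[n, , h, v] / (sqrt(sum(x[n, , h, v]^2)) + eps)
  out
}

# Mann-Whitney probability that a random positive outscores a random
# negative, ties counted 1/2 -- brute force over all pairs.
oracleMannWhitney <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# small deterministic parameter arrays for fixed-kernel oracle tests
gridArray <- function(dims, scale = 0.1) {
  n <- prod(dims)
  array(scale * sin(seq_len(n)), dims)
}

# quick small synthetic samples shared by tests
tinySamples <- function(n = 3, size = 64, seed = 11, ...) {
  generateDataset(n, synthParams(imageSize = size, ...), seed = seed)
}
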