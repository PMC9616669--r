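## Reverse-mode automatic differentiation over dense R arrays.
##
## Feature maps are stored as 4-d arrays with dim = c(H, W, N, C): height,
## width, batch, channel. With this layout the im2col matrix of a 3x3
## convolution is assembled from nine contiguous block copies and fed straight
## into a BLAS matrix product, with no aperm() on the hot path. Channel
## descriptors (global-pooling outputs, attention gates) are (N, C) matrices.
##
## A node is an environment holding the forward value, its parent nodes and a
## backward closure mapping the node's upstream gradient to per-parent
## gradients. Node ids increase with creation order, so reverse creation order
## is a valid topological order for backpropagation.

.agState <- new.env(parent = emptyenv())
.agState$counter <- 0L

agNode <- function(value, parents = list(), backward = NULL, param = NULL) {
  .agState$counter <- .agState$counter + 1L
  node <- new.env(parent = emptyenv())
  node$id <- .agState$counter
  node$value <- value
  node$parents <- parents
  node$backward <- backward
  node$param <- param
  node$grad <- NULL
  class(node) <- "agNode"
  node
}

#' @noRd
agConstant <- function(value) agNode(value)

## A trainable parameter: value + gradient accumulator + Adam moments.
agParameter <- function(value, name = "") {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- value * 0          # same shape and attributes as the value
  p$m <- p$grad
  p$v <- p$grad
  p$name <- name
  class(p) <- "agParameter"
  p
}

agLeaf <- function(param) agNode(param$value, param = param)

.agDim <- function(x) if (is.null(dim(x))) length(x) else dim(x)

agZeroGrads <- function(params) {
  for (p in params) p$grad[] <- 0
  invisible(NULL)
}

## Backpropagate from a scalar root node. Accumulates into node$grad and,
## for leaves wrapping a parameter, into param$grad.
agBackward <- function(root, seed = 1) {
  stopifnot(length(root$value) == 1L)
  ## collect reachable nodes
  nodes <- list()
  stack <- list(root)
  seen <- new.env(parent = emptyenv())
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(nd$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    nodes[[length(nodes) + 1L]] <- nd
    for (p in nd$parents) stack[[length(stack) + 1L]] <- p
  }
  ord <- order(vapply(nodes, function(n) n$id, numeric(1)), decreasing = TRUE)
  nodes <- nodes[ord]
  root$grad <- seed
  for (nd in nodes) {
    if (is.null(nd$grad)) next
    if (!is.null(nd$param)) {
      nd$param$grad <- nd$param$grad + nd$grad
    }
    if (is.null(nd$backward) || !length(nd$parents)) next
    gs <- nd$backward(nd$grad)
    for (k in seq_along(nd$parents)) {
      g <- gs[[k]]
      if (is.null(g)) next
      par <- nd$parents[[k]]
      if (is.null(par$grad)) par$grad <- g else par$grad <- par$grad + g
    }
  }
  invisible(root)
}

## ---- elementwise ops --------------------------------------------------------

agAdd <- function(a, b) {
  stopifnot(identical(.agDim(a$value), .agDim(b$value)))
  agNode(a$value + b$value, list(a, b), function(g) list(g, g))
}

agMul <- function(a, b) {
  stopifnot(identical(.agDim(a$value), .agDim(b$value)))
  av <- a$value; bv <- b$value
  agNode(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

agRelu <- function(a) {
  mask <- a$value > 0
  agNode(a$value * mask, list(a), function(g) list(g * mask))
}

agSigmoid <- function(a) {
  y <- 1 / (1 + exp(-a$value))
  agNode(y, list(a), function(g) list(g * y * (1 - y)))
}

## ---- convolution family -----------------------------------------------------

## 3x3 convolution, stride 1, padding = dilation (spatial size preserved).
## x: (H,W,N,Cin) node; w: (3,3,Cin,Cout) param node; b: (Cout) param node.
agConv3x3 <- function(x, w, b, dilation = 1L) {
  d <- as.integer(dilation)
  stopifnot(d >= 1L)
  dm <- dim(x$value); H <- dm[1]; W <- dm[2]; N <- dm[3]; Cin <- dm[4]
  wd <- dim(w$value)
  stopifnot(length(wd) == 4L, wd[1] == 3L, wd[2] == 3L, wd[3] == Cin)
  Cout <- wd[4]
  M <- .im2col3x3(x$value, H, W, N, Cin, d)
  K <- matrix(0, Cin * 9L, Cout)
  t <- 0L
  for (j in 1:3) for (i in 1:3) {
    t <- t + 1L
    K[((t - 1L) * Cin + 1L):(t * Cin), ] <- matrix(w$value[i, j, , ], Cin, Cout)
  }
  out <- M %*% K
  out <- out + rep(b$value, each = H * W * N)
  dim(out) <- c(H, W, N, Cout)
  agNode(out, list(x, w, b), function(g) {
    gm <- g; dim(gm) <- c(H * W * N, Cout)
    gK <- crossprod(M, gm)                      # (Cin*9, Cout)
    gw <- array(0, wd)
    t <- 0L
    for (j in 1:3) for (i in 1:3) {
      t <- t + 1L
      gw[i, j, , ] <- gK[((t - 1L) * Cin + 1L):(t * Cin), ]
    }
    gx <- .col2im3x3(tcrossprod(gm, K), H, W, N, Cin, d)
    list(gx, gw, colSums(gm))
  })
}

## 1x1 convolution (channel projection). w: (Cin,Cout), b: (Cout).
agConv1x1 <- function(x, w, b) {
  dm <- dim(x$value); H <- dm[1]; W <- dm[2]; N <- dm[3]; Cin <- dm[4]
  stopifnot(nrow(w$value) == Cin)
  Cout <- ncol(w$value)
  Xm <- x$value; dim(Xm) <- c(H * W * N, Cin)
  out <- Xm %*% w$value
  out <- out + rep(b$value, each = H * W * N)
  dim(out) <- c(H, W, N, Cout)
  agNode(out, list(x, w, b), function(g) {
    gm <- g; dim(gm) <- c(H * W * N, Cout)
    gx <- tcrossprod(gm, w$value); dim(gx) <- c(H, W, N, Cin)
    list(gx, crossprod(Xm, gm), colSums(gm))
  })
}

## 2x2 transpose convolution, stride 2 (exact x2 upsampling, non-overlapping).
## w: (2,2,Cin,Cout), b: (Cout).
agConvTranspose2 <- function(x, w, b) {
  dm <- dim(x$value); H <- dm[1]; W <- dm[2]; N <- dm[3]; Cin <- dm[4]
  wd <- dim(w$value)
  stopifnot(wd[1] == 2L, wd[2] == 2L, wd[3] == Cin)
  Cout <- wd[4]
  Xm <- x$value; dim(Xm) <- c(H * W * N, Cin)
  out <- array(0, c(2L * H, 2L * W, N, Cout))
  for (i in 1:2) for (j in 1:2) {
    O <- Xm %*% matrix(w$value[i, j, , ], Cin, Cout)
    dim(O) <- c(H, W, N, Cout)
    out[seq(i, 2L * H, 2L), seq(j, 2L * W, 2L), , ] <- O
  }
  out <- out + rep(b$value, each = 4L * H * W * N)
  agNode(out, list(x, w, b), function(g) {
    gx <- matrix(0, H * W * N, Cin)
    gw <- array(0, wd)
    gb <- numeric(Cout)
    for (i in 1:2) for (j in 1:2) {
      G <- g[seq(i, 2L * H, 2L), seq(j, 2L * W, 2L), , , drop = FALSE]
      dim(G) <- c(H * W * N, Cout)
      gw[i, j, , ] <- crossprod(Xm, G)
      gx <- gx + tcrossprod(G, matrix(w$value[i, j, , ], Cin, Cout))
      gb <- gb + colSums(G)
    }
    dim(gx) <- c(H, W, N, Cin)
    list(gx, gw, gb)
  })
}

## ---- normalisation ----------------------------------------------------------

## Batch normalisation over (H,W,N) per channel. `state` is an environment with
## runningMean, runningVar (length C), momentum, eps; updated in training mode.
agBatchNorm <- function(x, gamma, beta, state, train = TRUE) {
  dm <- dim(x$value); H <- dm[1]; W <- dm[2]; N <- dm[3]; C <- dm[4]
  m <- H * W * N
  Xm <- x$value; dim(Xm) <- c(m, C)
  g <- gamma$value; bt <- beta$value
  if (train) {
    mu <- colMeans(Xm)
    Xc <- sweep(Xm, 2, mu)
    varb <- colMeans(Xc * Xc)
    rstd <- 1 / sqrt(varb + state$eps)
    Xhat <- sweep(Xc, 2, rstd, `*`)
    mom <- state$momentum
    state$runningMean <- (1 - mom) * state$runningMean + mom * mu
    uvar <- if (m > 1) varb * m / (m - 1) else varb
    state$runningVar <- (1 - mom) * state$runningVar + mom * uvar
    Y <- sweep(Xhat, 2, g, `*`)
    Y <- sweep(Y, 2, bt, `+`)
    dim(Y) <- dm
    agNode(Y, list(x, gamma, beta), function(gr) {
      Gm <- gr; dim(Gm) <- c(m, C)
      dgamma <- colSums(Gm * Xhat)
      dbeta <- colSums(Gm)
      dxhat <- sweep(Gm, 2, g, `*`)
      s1 <- colSums(dxhat)
      s2 <- colSums(dxhat * Xhat)
      dx <- sweep(m * dxhat, 2, s1) - sweep(Xhat, 2, s2, `*`)
      dx <- sweep(dx, 2, rstd / m, `*`)
      dim(dx) <- dm
      list(dx, dgamma, dbeta)
    })
  } else {
    rstd <- 1 / sqrt(state$runningVar + state$eps)
    Xhat <- sweep(sweep(Xm, 2, state$runningMean), 2, rstd, `*`)
    Y <- sweep(sweep(Xhat, 2, g, `*`), 2, bt, `+`)
    dim(Y) <- dm
    agNode(Y, list(x, gamma, beta), function(gr) {
      Gm <- gr; dim(Gm) <- c(m, C)
      dx <- sweep(Gm, 2, g * rstd, `*`)
      dim(dx) <- dm
      list(dx, colSums(Gm * Xhat), colSums(Gm))
    })
  }
}

## ---- pooling / resampling ---------------------------------------------------

agMaxPool2 <- function(x) {
  dm <- dim(x$value); H <- dm[1]; W <- dm[2]
  stopifnot(H %% 2 == 0, W %% 2 == 0)
  ro <- seq(1L, H, 2L); re <- seq(2L, H, 2L)
  co <- seq(1L, W, 2L); ce <- seq(2L, W, 2L)
  s <- list(
    x$value[ro, co, , , drop = FALSE], x$value[re, co, , , drop = FALSE],
    x$value[ro, ce, , , drop = FALSE], x$value[re, ce, , , drop = FALSE])
  out <- s[[1]]
  which4 <- array(1L, dim(out))
  for (k in 2:4) {
    upd <- s[[k]] > out
    out[upd] <- s[[k]][upd]
    which4[upd] <- k
  }
  agNode(out, list(x), function(g) {
    gx <- array(0, dm)
    rows <- list(ro, re, ro, re); cols <- list(co, co, ce, ce)
    for (k in 1:4) {
      gk <- g * (which4 == k)
      gx[rows[[k]], cols[[k]], , ] <- gx[rows[[k]], cols[[k]], , , drop = FALSE] + gk
    }
    list(gx)
  })
}

## Interpolation matrix for 1-d bilinear upsampling by integer factor f
## (half-pixel centre convention).
.bilinMat <- function(n, f) {
  m <- n * f
  A <- matrix(0, m, n)
  for (o in seq_len(m)) {
    src <- (o - 0.5) / f - 0.5          # 0-based source coordinate
    src <- min(max(src, 0), n - 1)
    i0 <- floor(src)
    w1 <- 1 - (src - i0)
    A[o, i0 + 1] <- A[o, i0 + 1] + w1
    if (i0 + 2 <= n) A[o, i0 + 2] <- A[o, i0 + 2] + (src - i0)
  }
  A
}

agUpsampleBilinear <- function(x, factor) {
  f <- as.integer(factor)
  if (f == 1L) return(agNode(x$value, list(x), function(g) list(g)))
  dm <- dim(x$value); H <- dm[1]; W <- dm[2]; N <- dm[3]; C <- dm[4]
  Ah <- .bilinMat(H, f); Aw <- .bilinMat(W, f)
  up <- function(v) {
    dim(v) <- c(H, W * N * C)
    y <- Ah %*% v
    dim(y) <- c(H * f, W, N, C)
    y <- aperm(y, c(2, 1, 3, 4))
    dim(y) <- c(W, H * f * N * C)
    y <- Aw %*% y
    dim(y) <- c(W * f, H * f, N, C)
    aperm(y, c(2, 1, 3, 4))
  }
  down <- function(g) {
    dim(g) <- c(H * f, W * f * N * C)
    y <- crossprod(Ah, g)
    dim(y) <- c(H, W * f, N, C)
    y <- aperm(y, c(2, 1, 3, 4))
    dim(y) <- c(W * f, H * N * C)
    y <- crossprod(Aw, y)
    dim(y) <- c(W, H, N, C)
    aperm(y, c(2, 1, 3, 4))
  }
  agNode(up(x$value), list(x), function(g) list(down(g)))
}

## ---- reductions / channel descriptors --------------------------------------

## Global average pooling: (H,W,N,C) -> (N,C) matrix.
agGAP <- function(x) {
  dm <- dim(x$value); H <- dm[1]; W <- dm[2]; N <- dm[3]; C <- dm[4]
  Xm <- x$value; dim(Xm) <- c(H * W, N * C)
  out <- matrix(colMeans(Xm), N, C)
  agNode(out, list(x), function(g) {
    gx <- array(rep(as.vector(g) / (H * W), each = H * W), dm)
    list(gx)
  })
}

## Fully connected layer on (N,C) descriptors. w: (Cin,Cout), b: (Cout).
agDense <- function(v, w, b) {
  out <- v$value %*% w$value
  out <- sweep(out, 2, b$value, `+`)
  agNode(out, list(v, w, b), function(g) {
    list(tcrossprod(g, w$value), crossprod(v$value, g), colSums(g))
  })
}

## Multiply each channel of x (H,W,N,C) by a per-(sample,channel) scalar
## gate s (N,C), broadcast over space.
agScaleChannels <- function(x, s) {
  dm <- dim(x$value); H <- dm[1]; W <- dm[2]; N <- dm[3]; C <- dm[4]
  stopifnot(identical(dim(s$value), c(N, C)))
  S <- array(rep(as.vector(s$value), each = H * W), dm)
  xv <- x$value
  agNode(xv * S, list(x, s), function(g) {
    tmp <- g * xv; dim(tmp) <- c(H * W, N * C)
    list(g * S, matrix(colSums(tmp), N, C))
  })
}

## ---- per-pixel channel transforms ------------------------------------------

## Softmax across channels, independently at each (h,w,n).
agSoftmaxC <- function(x) {
  dm <- dim(x$value); C <- dm[4]
  Xm <- x$value; dim(Xm) <- c(prod(dm[1:3]), C)
  mx <- Xm[, 1]
  if (C > 1) for (k in 2:C) mx <- pmax(mx, Xm[, k])
  E <- exp(Xm - mx)
  Y <- E / rowSums(E)
  out <- Y; dim(out) <- dm
  agNode(out, list(x), function(g) {
    Gm <- g; dim(Gm) <- c(prod(dm[1:3]), C)
    dot <- rowSums(Y * Gm)
    dx <- Y * (Gm - dot)
    dim(dx) <- dm
    list(dx)
  })
}

## L2 normalisation across channels at each (h,w,n): y = x / (||x|| + eps).
agL2NormC <- function(x, eps = 1e-8) {
  dm <- dim(x$value); C <- dm[4]
  Xm <- x$value; dim(Xm) <- c(prod(dm[1:3]), C)
  r <- sqrt(rowSums(Xm * Xm))
  denom <- r + eps
  Y <- Xm / denom
  out <- Y; dim(out) <- dm
  agNode(out, list(x), function(g) {
    Gm <- g; dim(Gm) <- c(prod(dm[1:3]), C)
    dot <- rowSums(Xm * Gm)
    dx <- Gm / denom - Xm * (dot / (pmax(r, 1e-12) * denom^2))
    dim(dx) <- dm
    list(dx)
  })
}

## ReLU on an (N,C) descriptor or any plain array node (same as agRelu).
## Concatenate along the channel axis (dim 4).
agConcatC <- function(nodes) {
  dms <- lapply(nodes, function(n) dim(n$value))
  base <- dms[[1]][1:3]
  for (d in dms) stopifnot(identical(d[1:3], base))
  Cs <- vapply(dms, function(d) d[4], numeric(1))
  out <- array(0, c(base, sum(Cs)))
  off <- 0L
  for (k in seq_along(nodes)) {
    out[, , , off + seq_len(Cs[k])] <- nodes[[k]]$value
    off <- off + Cs[k]
  }
  agNode(out, nodes, function(g) {
    gs <- vector("list", length(nodes))
    off <- 0L
    for (k in seq_along(nodes)) {
      gs[[k]] <- g[, , , off + seq_len(Cs[k]), drop = FALSE]
      off <- off + Cs[k]
    }
    gs
  })
}

## ---- losses -----------------------------------------------------------------

## Mean binary cross-entropy with epsilon clamping; target is a plain array.
agBCE <- function(pred, target, eps = 1e-7) {
  p <- pred$value
  stopifnot(identical(.agDim(p), .agDim(target)))
  pc <- pmin(pmax(p, eps), 1 - eps)
  n <- length(pc)
  loss <- -sum(target * log(pc) + (1 - target) * log(1 - pc)) / n
  inside <- (p > eps) & (p < 1 - eps)
  agNode(loss, list(pred), function(g) {
    dp <- g * inside * (pc - target) / (pc * (1 - pc)) / n
    list(dp)
  })
}

## Mean of all entries -> scalar (handy for gradient-flow checks).
agMean <- function(x) {
  n <- length(x$value)
  dm <- .agDim(x$value)
  agNode(sum(x$value) / n, list(x), function(g) {
    list(array(g / n, dm))
  })
}

## ---- optimiser --------------------------------------------------------------

## One Adam step over a list of agParameter environments. Classic L2-style
## weight decay is added to the raw gradient before the moment updates.
adamStep <- function(params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8, weightDecay = 0, t = 1L) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (p in params) {
    g <- p$grad
    if (weightDecay > 0) g <- g + weightDecay * p$value
    p$m <- beta1 * p$m + (1 - beta1) * g
    p$v <- beta2 * p$v + (1 - beta2) * g * g
    p$value <- p$value - lr * (p$m / bc1) / (sqrt(p$v / bc2) + eps)
  }
  invisible(NULL)
}
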