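## Building blocks of the network, each a tensor-to-tensor operator with an
## explicit shape contract:
##
##   conv unit          F(x) = ReLU(BN(conv3x3(x)))
##   channel attention  sigmoid(FC(ReLU(FC(GAP(x)))))           -> (0,1)^C gate
##   RASF               three parallel atrous branches (rates 1/3/5) fused by
##                      channel attention and a channel softmax, closed by a
##                      residual connection
##   AFF                skip fusion of shallow features taken before and after
##                      subsampling with transpose-conv upsampled deep features
##   MPF                multi-path head gating the finest decoder stage with a
##                      descriptor built from the two coarser decoder stages
##
## Blocks are lightweight S3 objects ("sfaBlock") holding agParameter
## environments plus a forward closure over autograd nodes; `blockForward`
## exposes them as plain-array operators.

.heConv <- function(kh, kw, cin, cout) {
  array(rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}

.newBNState <- function(C) {
  st <- new.env(parent = emptyenv())
  st$runningMean <- numeric(C)
  st$runningVar <- rep(1, C)
  st$momentum <- 0.1
  st$eps <- 1e-5
  st
}

.mkBlock <- function(type, params, states, fwd, info = list()) {
  structure(list(type = type, params = params, states = states, fwd = fwd,
                 info = info), class = "sfaBlock")
}

#' @export
print.sfaBlock <- function(x, ...) {
  cat(sprintf("<%s block: %d parameter arrays, %d values>\n", x$type,
              length(x$params), sum(vapply(x$params, function(p) length(p$value), 0))))
  invisible(x)
}

## ---- conv + BN + ReLU unit --------------------------------------------------

#' Convolution unit: ReLU(BN(conv3x3))
#'
#' The elementary convolution unit used throughout the network: a 3x3
#' convolution (stride 1, padding = dilation, spatial size preserved)
#' followed by batch normalisation and a rectified linear unit.
#'
#' @param inChannels,outChannels channel counts.
#' @param dilation atrous rate (padding equals dilation).
#' @return an `sfaBlock`; apply it with [blockForward()].
#' @export
convBNBlock <- function(inChannels, outChannels, dilation = 1L) {
  if (dilation < 1) stop("dilation must be >= 1")
  params <- list(
    w = agParameter(.heConv(3, 3, inChannels, outChannels), "w"),
    b = agParameter(numeric(outChannels), "b"),
    gamma = agParameter(rep(1, outChannels), "gamma"),
    beta = agParameter(numeric(outChannels), "beta"))
  st <- .newBNState(outChannels)
  fwd <- function(x, train = FALSE) {
    if (dim(x$value)[4] != inChannels)
      stop(sprintf("channel mismatch: got %d, block expects %d",
                   dim(x$value)[4], inChannels))
    h <- agConv3x3(x, agLeaf(params$w), agLeaf(params$b), dilation)
    agRelu(agBatchNorm(h, agLeaf(params$gamma), agLeaf(params$beta), st, train))
  }
  .mkBlock("convBN", params, list(bn = st), fwd,
           list(inChannels = inChannels, outChannels = outChannels,
                dilation = dilation))
}

## ---- squeeze-excitation channel attention ----------------------------------

#' Channel attention gate
#'
#' Global average pooling followed by a two-layer bottleneck
#' (`C -> C/r -> C`) with ReLU and sigmoid, yielding per-channel weights
#' strictly inside (0, 1).
#'
#' @param channels input channel count C.
#' @param r squeeze ratio (must not exceed C).
#' @return an `sfaBlock` mapping an (N,C,H,W) input to an (N,C) gate.
#' @export
channelAttentionBlock <- function(channels, r = 16L) {
  if (r > channels) stop("attention ratio r must not exceed the channel count")
  hidden <- max(1L, channels %/% r)
  params <- list(
    w1 = agParameter(matrix(rnorm(channels * hidden, 0, sqrt(2 / channels)),
                            channels, hidden), "w1"),
    b1 = agParameter(numeric(hidden), "b1"),
    w2 = agParameter(matrix(rnorm(hidden * channels, 0, sqrt(2 / hidden)),
                            hidden, channels), "w2"),
    b2 = agParameter(numeric(channels), "b2"))
  fwd <- function(x, train = FALSE) {
    g <- agGAP(x)
    h <- agRelu(agDense(g, agLeaf(params$w1), agLeaf(params$b1)))
    agSigmoid(agDense(h, agLeaf(params$w2), agLeaf(params$b2)))
  }
  .mkBlock("channelAttention", params, list(), fwd,
           list(channels = channels, r = r, hidden = hidden))
}

## ---- residual atrous spatial feature aggregation ---------------------------

#' Residual atrous multiscale aggregation block
#'
#' Three parallel dilated 3x3 convolution units (rates 1, 3, 5 by default)
#' produce F1, F2, F3. The sum branch F12 = F1 + F2 is fused by a 3x3
#' convolution with ReLU and channel attention, gating F1; the product branch
#' F23 = F2 * F3 passes a per-pixel channel softmax and re-multiplies F3.
#' Both paths are combined (concatenation by default), reduced back to the
#' input width by a 3x3 convolution, and added to the input through a
#' residual connection, so zeroing all learned weights leaves the input
#' unchanged.
#'
#' @param channels input (= output) channel count.
#' @param dilations the three atrous rates.
#' @param r channel-attention squeeze ratio.
#' @param combine `"concat"` (default) or `"sum"` for joining the two paths.
#' @return an `sfaBlock`.
#' @export
rasfBlock <- function(channels, dilations = c(1L, 3L, 5L), r = 16L,
                      combine = c("concat", "sum")) {
  combine <- match.arg(combine)
  if (any(dilations < 1)) stop("dilation rates must be >= 1")
  if (length(dilations) != 3L) stop("RASF uses exactly three atrous branches")
  branches <- lapply(dilations, function(d) convBNBlock(channels, channels, d))
  convA <- list(w = agParameter(.heConv(3, 3, channels, channels), "wA"),
                b = agParameter(numeric(channels), "bA"))
  att <- channelAttentionBlock(channels, r)
  redIn <- if (combine == "concat") 2L * channels else channels
  convR <- list(w = agParameter(.heConv(3, 3, redIn, channels), "wR"),
                b = agParameter(numeric(channels), "bR"))
  params <- c(setNames(unlist(lapply(branches, `[[`, "params"), recursive = FALSE),
                       paste0("dil", rep(seq_along(dilations), each = 4), "_",
                              rep(c("w", "b", "gamma", "beta"), 3))),
              list(wA = convA$w, bA = convA$b),
              setNames(att$params, paste0("att_", names(att$params))),
              list(wR = convR$w, bR = convR$b))
  fwd <- function(x, train = FALSE) {
    if (dim(x$value)[4] != channels)
      stop(sprintf("channel mismatch: got %d, RASF expects %d",
                   dim(x$value)[4], channels))
    F1 <- branches[[1]]$fwd(x, train)
    F2 <- branches[[2]]$fwd(x, train)
    F3 <- branches[[3]]$fwd(x, train)
    F12 <- agAdd(F1, F2)
    F23 <- agMul(F2, F3)
    F122 <- agRelu(agConv3x3(F12, agLeaf(convA$w), agLeaf(convA$b), 1L))
    gate <- att$fwd(F122, train)              # (N, C) in (0,1)
    F1p <- agScaleChannels(F1, gate)
    F123 <- agSoftmaxC(F23)
    F2p <- agMul(F123, F3)
    comb <- if (combine == "concat") agConcatC(list(F1p, F2p)) else agAdd(F1p, F2p)
    F12p <- agConv3x3(comb, agLeaf(convR$w), agLeaf(convR$b), 1L)
    agAdd(x, F12p)
  }
  .mkBlock("rasf", params,
           list(bn1 = branches[[1]]$states$bn, bn2 = branches[[2]]$states$bn,
                bn3 = branches[[3]]$states$bn), fwd,
           list(channels = channels, dilations = dilations, r = r,
                combine = combine))
}

## ---- attentional feature fusion skip connection ----------------------------

#' Attentional skip-fusion block
#'
#' Fuses shallow encoder features taken before (`low1`) and after (`low2`)
#' the level's convolutions with the deeper decoder feature (`high`, at half
#' of `low2`'s resolution). A 3x3 convolution unit projects `low1` to
#' `low2`'s width; its global average pooling gives per-channel weights that
#' gate `low2`, followed by per-pixel L2 normalisation across channels. The
#' gated map is concatenated with `low2` and with the transpose-convolution
#' upsampled `high`, so the output has `3 * lowChannels` channels at `low2`'s
#' resolution.
#'
#' @param low1Channels channels of the pre-subsampling shallow input.
#' @param lowChannels channels of the post-convolution shallow input.
#' @param highChannels channels of the deep input.
#' @return an `sfaBlock` taking three feature maps.
#' @export
affBlock <- function(low1Channels, lowChannels, highChannels) {
  conv1 <- convBNBlock(low1Channels, lowChannels)
  tconv <- list(
    w = agParameter(array(rnorm(2 * 2 * highChannels * lowChannels, 0,
                                sqrt(2 / (4 * highChannels))),
                          c(2, 2, highChannels, lowChannels)), "wT"),
    b = agParameter(numeric(lowChannels), "bT"),
    gamma = agParameter(rep(1, lowChannels), "gammaT"),
    beta = agParameter(numeric(lowChannels), "betaT"))
  stT <- .newBNState(lowChannels)
  params <- c(setNames(conv1$params, paste0("low1_", names(conv1$params))),
              list(wT = tconv$w, bT = tconv$b, gammaT = tconv$gamma,
                   betaT = tconv$beta))
  fwd <- function(low1, low2, high, train = FALSE) {
    if (dim(low2$value)[4] != lowChannels)
      stop("channel mismatch: low2 does not match the block's lowChannels")
    if (dim(high$value)[4] != highChannels)
      stop("channel mismatch: high does not match the block's highChannels")
    g <- agGAP(conv1$fwd(low1, train))              # (N, lowChannels)
    Fnewlow <- agL2NormC(agScaleChannels(low2, g))
    up <- agConvTranspose2(high, agLeaf(tconv$w), agLeaf(tconv$b))
    if (!identical(dim(up$value)[1:2], dim(low2$value)[1:2]))
      stop("resolution mismatch: transpose conv of `high` must match `low2`")
    up <- agRelu(agBatchNorm(up, agLeaf(tconv$gamma), agLeaf(tconv$beta), stT, train))
    agConcatC(list(low2, Fnewlow, up))
  }
  .mkBlock("aff", params, list(bnLow1 = conv1$states$bn, bnT = stT), fwd,
           list(low1Channels = low1Channels, lowChannels = lowChannels,
                highChannels = highChannels,
                outChannels = 3L * lowChannels))
}

## ---- multi-path feature fusion head ----------------------------------------

#' Multi-path decoder fusion block
#'
#' Upsamples the three finest decoder stages to full resolution and projects
#' each to a common width with a convolution unit. The two coarser paths are
#' multiplied, passed through a per-pixel channel softmax, globally pooled
#' and rectified into a per-channel gate that modulates the finest path.
#'
#' @param ch1,ch2,ch3 channel counts of the decoder stages at full, 1/2 and
#'   1/4 resolution.
#' @param common common projection width (defaults to `ch1`).
#' @param factors upsampling factors bringing each stage to full resolution.
#' @param gateActivation `"relu"` (default) or `"l2norm"` for the gate
#'   normalisation after pooling.
#' @return an `sfaBlock` taking three feature maps.
#' @export
mpfBlock <- function(ch1, ch2, ch3, common = ch1, factors = c(1L, 2L, 4L),
                     gateActivation = c("relu", "l2norm")) {
  gateActivation <- match.arg(gateActivation)
  c1 <- convBNBlock(ch1, common)
  cX1 <- convBNBlock(ch2, common)
  cX2 <- convBNBlock(ch3, common)
  params <- c(setNames(c1$params, paste0("f1_", names(c1$params))),
              setNames(cX1$params, paste0("x1_", names(cX1$params))),
              setNames(cX2$params, paste0("x2_", names(cX2$params))))
  fwd <- function(xh1, xh2, xh3, train = FALSE) {
    d1 <- dim(xh1$value); d2 <- dim(xh2$value); d3 <- dim(xh3$value)
    full <- d1[1] * factors[1]
    if (d2[1] * factors[2] != full || d3[1] * factors[3] != full)
      stop("input resolutions must be related by the configured power-of-two factors")
    F1 <- c1$fwd(agUpsampleBilinear(xh1, factors[1]), train)
    X1 <- cX1$fwd(agUpsampleBilinear(xh2, factors[2]), train)
    X2 <- cX2$fwd(agUpsampleBilinear(xh3, factors[3]), train)
    sm <- agSoftmaxC(agMul(X1, X2))
    g <- agGAP(sm)                                   # (N, common)
    F2 <- if (gateActivation == "relu") agRelu(g) else {
      r <- sqrt(rowSums(g$value^2))
      agNode(g$value / (r + 1e-8), list(g), local({
        gv <- g$value; rr <- r
        function(gr) {
          dot <- rowSums(gv * gr)
          list(gr / (rr + 1e-8) - gv * (dot / (pmax(rr, 1e-12) * (rr + 1e-8)^2)))
        }
      }))
    }
    agScaleChannels(F1, F2)
  }
  .mkBlock("mpf", params,
           list(bn1 = c1$states$bn, bnX1 = cX1$states$bn, bnX2 = cX2$states$bn),
           fwd,
           list(ch1 = ch1, ch2 = ch2, ch3 = ch3, common = common,
                factors = factors, gateActivation = gateActivation))
}

## ---- plain-array interface --------------------------------------------------

## Convert a public N x C x H x W batch to the internal (H, W, N, C) layout.
.toInternal <- function(x) {
  dm <- dim(x)
  if (length(dm) != 4L) stop("expected an N x C x H x W array")
  aperm(x, c(3, 4, 1, 2))
}

.toPublic <- function(x) aperm(x, c(3, 4, 1, 2))

#' Apply a building block to plain arrays
#'
#' Wraps the autograd forward pass of a block constructed with
#' [convBNBlock()], [channelAttentionBlock()], [rasfBlock()], [affBlock()] or
#' [mpfBlock()]. Inputs and outputs use the public N x C x H x W layout;
#' [channelAttentionBlock()] returns an N x C gate matrix instead.
#'
#' @param block an `sfaBlock`.
#' @param ... one array (convBN, channelAttention, RASF) or three arrays
#'   (AFF: low1, low2, high; MPF: xh1, xh2, xh3).
#' @param train logical; `TRUE` uses batch statistics in the BN layers and
#'   updates running statistics, `FALSE` (default) uses the stored running
#'   statistics.
#' @return the output array in N x C x H x W layout (or an N x C matrix for
#'   channel attention).
#' @export
blockForward <- function(block, ..., train = FALSE) {
  stopifnot(inherits(block, "sfaBlock"))
  ins <- lapply(list(...), function(a) agNode(.toInternal(a)))
  out <- do.call(block$fwd, c(ins, list(train = train)))
  if (block$type == "channelAttention") out$value else .toPublic(out$value)
}

#' List the trainable parameters of a block
#'
#' @param block an `sfaBlock`.
#' @return named list of parameter arrays (by value).
#' @export
blockParameters <- function(block) lapply(block$params, function(p) p$value)

#' Overwrite parameters of a block
#'
#' Replaces the stored values of the named parameter arrays; shapes must
#' match. Useful for loading checkpoints and for constructing fixed-weight
#' blocks in tests.
#'
#' @param block an `sfaBlock`.
#' @param values named list of arrays matching [blockParameters()] shapes.
#' @return the block, invisibly (parameters are environments, so the update
#'   is in place).
#' @export
setBlockParameters <- function(block, values) {
  for (nm in names(values)) {
    p <- block$params[[nm]]
    if (is.null(p)) stop("unknown parameter: ", nm)
    v <- values[[nm]]
    if (!identical(.agDim(p$value), .agDim(v)))
      stop("shape mismatch for parameter ", nm)
    p$value <- v
  }
  invisible(block)
}

#' Zero all trainable parameters of a block
#'
#' Sets every weight, bias and batch-norm scale/shift to zero; for the
#' residual RASF block this reduces the forward map to the identity.
#'
#' @param block an `sfaBlock`.
#' @return the block, invisibly.
#' @export
zeroBlockParameters <- function(block) {
  for (p in block$params) p$value[] <- 0
  invisible(block)
}
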