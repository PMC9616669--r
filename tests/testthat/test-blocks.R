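test_that("conv unit preserves spatial size, maps channels, stays non-negative", {
  set.seed(1)
  blk <- convBNBlock(3L, 5L)
  x <- array(rnorm(2 * 3 * 96 * 96), c(2, 3, 96, 96))
  y <- blockForward(blk, x)
  expect_identical(dim(y), c(2L, 5L, 96L, 96L))     # 96 x 96 patch contract
  expect_true(all(y >= 0))                          # ReLU closure
  expect_error(blockForward(blk, array(0, c(1, 4, 16, 16))), "channel mismatch")
  expect_error(convBNBlock(2, 2, dilation = 0), "dilation")
})

test_that("conv unit matches a sliding-window oracle in eval mode", {
  set.seed(2)
  for (d in c(1L, 2L)) {
    blk <- convBNBlock(2L, 3L, dilation = d)
    p <- list(w = gridArray(c(3, 3, 2, 3)), b = c(0.1, -0.2, 0.3),
              gamma = c(1, 1.5, 0.8), beta = c(0.05, 0, -0.05))
    setBlockParameters(blk, p)
    x <- array(rnorm(2 * 2 * 6 * 6), c(2, 2, 6, 6))
    expect_equal(blockForward(blk, x), oracleConvBNEval(x, p, d),
                 tolerance = 1e-6)
  }
})

test_that("channel attention yields gates strictly inside (0,1)", {
  set.seed(3)
  att <- channelAttentionBlock(8L, 4L)
  x <- array(rnorm(3 * 8 * 10 * 10), c(3, 8, 10, 10))
  g <- blockForward(att, x)
  expect_identical(dim(g), c(3L, 8L))
  expect_true(all(g > 0 & g < 1))
  expect_error(channelAttentionBlock(4L, 8L), "must not exceed")
})

test_that("channel attention equals the dense-algebra oracle", {
  set.seed(4)
  att <- channelAttentionBlock(4L, 2L)
  p <- list(w1 = gridArray(c(4, 2), 0.5), b1 = c(0.1, -0.1),
            w2 = gridArray(c(2, 4), 0.5), b2 = c(0, 0.2, -0.2, 0.1))
  setBlockParameters(att, p)
  x <- array(rnorm(2 * 4 * 8 * 8), c(2, 4, 8, 8))
  expect_equal(blockForward(att, x),
               oracleChannelAttention(x, p$w1, p$b1, p$w2, p$b2),
               tolerance = 1e-10)
  # spatially constant input: pooling must return the constant per channel
  v <- c(0.3, -1.2, 0.7, 2.5)
  xc <- aperm(array(rep(v, each = 1), c(4, 1, 6, 6)), c(2, 1, 3, 4))
  for (c in 1:4) xc[1, c, , ] <- v[c]
  st <- blockForward(att, xc)
  direct <- oracleSigmoid(sweep(oracleRelu(sweep(matrix(v, 1) %*% p$w1, 2, p$b1, `+`)) %*% p$w2, 2, p$b2, `+`))
  expect_equal(st, direct, tolerance = 1e-10)
})

test_that("RASF preserves shape and reduces to identity with zero weights", {
  set.seed(5)
  blk <- rasfBlock(4L, r = 2L)
  x <- array(rnorm(2 * 4 * 8 * 8), c(2, 4, 8, 8))
  expect_identical(dim(blockForward(blk, x)), dim(x))   # residual closure
  zeroBlockParameters(blk)
  expect_equal(blockForward(blk, x), x)                 # exact identity
  expect_error(rasfBlock(4L, dilations = c(0L, 3L, 5L)), "dilation")
  expect_error(blockForward(rasfBlock(4L, r = 2L), array(0, c(1, 3, 8, 8))),
               "channel mismatch")
})

test_that("RASF matches a step-by-step scalar oracle on fixed kernels", {
  set.seed(6)
  C <- 2L
  blk <- rasfBlock(C, dilations = c(1L, 3L, 5L), r = 2L)
  fixed <- list()
  for (i in 1:3) {
    fixed[[paste0("dil", i, "_w")]] <- gridArray(c(3, 3, C, C), 0.2 * i)
    fixed[[paste0("dil", i, "_b")]] <- c(0.1, -0.1) * i
    fixed[[paste0("dil", i, "_gamma")]] <- c(1, 1.2)
    fixed[[paste0("dil", i, "_beta")]] <- c(0, 0.1)
  }
  fixed$wA <- gridArray(c(3, 3, C, C), 0.3); fixed$bA <- c(0.2, -0.2)
  fixed$att_w1 <- gridArray(c(C, 1), 0.5); fixed$att_b1 <- 0.1
  fixed$att_w2 <- gridArray(c(1, C), 0.5); fixed$att_b2 <- c(0, 0.1)
  fixed$wR <- gridArray(c(3, 3, 2 * C, C), 0.15); fixed$bR <- c(0.05, -0.05)
  setBlockParameters(blk, fixed)
  x <- array(round(rnorm(1 * C * 4 * 4), 1), c(1, C, 4, 4))

  # independent evaluation of the whole chain
  F1 <- oracleConvBNEval(x, list(w = fixed$dil1_w, b = fixed$dil1_b,
                                 gamma = fixed$dil1_gamma, beta = fixed$dil1_beta), 1)
  F2 <- oracleConvBNEval(x, list(w = fixed$dil2_w, b = fixed$dil2_b,
                                 gamma = fixed$dil2_gamma, beta = fixed$dil2_beta), 3)
  F3 <- oracleConvBNEval(x, list(w = fixed$dil3_w, b = fixed$dil3_b,
                                 gamma = fixed$dil3_gamma, beta = fixed$dil3_beta), 5)
  F12 <- F1 + F2
  F23 <- F2 * F3
  F122 <- oracleRelu(oracleConv3x3(F12, fixed$wA, fixed$bA, 1))
  gate <- oracleChannelAttention(F122, fixed$att_w1, fixed$att_b1,
                                 fixed$att_w2, fixed$att_b2)
  F1p <- F1
  for (c in 1:C) F1p[, c, , ] <- F1[, c, , ] * gate[, c]
  F123 <- oracleSoftmaxC(F23)
  F2p <- F123 * F3
  comb <- array(0, c(1, 2 * C, 4, 4))
  comb[, 1:C, , ] <- F1p; comb[, (C + 1):(2 * C), , ] <- F2p
  expected <- x + oracleConv3x3(comb, fixed$wR, fixed$bR, 1)

  expect_equal(blockForward(blk, x), expected, tolerance = 1e-5)
})

test_that("AFF output concatenates gated shallow and upsampled deep features", {
  set.seed(7)
  blk <- affBlock(3L, 4L, 8L)
  low1 <- array(rnorm(2 * 3 * 8 * 8), c(2, 3, 8, 8))
  low2 <- array(rnorm(2 * 4 * 8 * 8), c(2, 4, 8, 8))
  high <- array(rnorm(2 * 8 * 4 * 4), c(2, 8, 4, 4))
  y <- blockForward(blk, low1, low2, high)
  expect_identical(dim(y)[3:4], dim(low2)[3:4])          # low2 resolution
  expect_identical(dim(y)[2], 3L * 4L)                   # concat arithmetic
  expect_error(blockForward(blk, low1, high, high), "channel mismatch")
  # wrong deep resolution: transpose conv cannot reach low2's size
  bad <- array(rnorm(2 * 8 * 2 * 2), c(2, 8, 2, 2))
  expect_error(blockForward(blk, low1, low2, bad), "resolution mismatch")
})

test_that("AFF's gated branch matches a scalar GAP/multiply/normalise oracle", {
  set.seed(8)
  blk <- affBlock(2L, 2L, 4L)
  p <- list(low1_w = gridArray(c(3, 3, 2, 2), 0.4), low1_b = c(0.1, -0.1),
            low1_gamma = c(1, 1.1), low1_beta = c(0, 0.05))
  setBlockParameters(blk, p)
  low1 <- array(round(rnorm(1 * 2 * 4 * 4), 1), c(1, 2, 4, 4))
  low2 <- array(round(rnorm(1 * 2 * 4 * 4), 1), c(1, 2, 4, 4))
  high <- array(rnorm(1 * 4 * 2 * 2), c(1, 4, 2, 2))
  y <- blockForward(blk, low1, low2, high)

  g <- oracleGAP(oracleConvBNEval(low1, list(w = p$low1_w, b = p$low1_b,
                                             gamma = p$low1_gamma,
                                             beta = p$low1_beta), 1))
  gated <- low2
  for (c in 1:2) gated[, c, , ] <- low2[, c, , ] * g[, c]
  Fnewlow <- oracleL2NormC(gated)
  expect_equal(y[, 3:4, , , drop = FALSE], Fnewlow, tolerance = 1e-6)
  expect_equal(y[, 1:2, , , drop = FALSE], low2, tolerance = 1e-12)
})

test_that("MPF softmax normalises channels and the gate matches its oracle", {
  set.seed(9)
  blk <- mpfBlock(2L, 3L, 4L, common = 2L)
  xh1 <- array(rnorm(2 * 2 * 8 * 8), c(2, 2, 8, 8))
  xh2 <- array(rnorm(2 * 3 * 4 * 4), c(2, 3, 4, 4))
  xh3 <- array(rnorm(2 * 4 * 2 * 2), c(2, 4, 2, 2))
  y <- blockForward(blk, xh1, xh2, xh3)
  expect_identical(dim(y), c(2L, 2L, 8L, 8L))           # full resolution out
  expect_error(blockForward(blk, xh1, xh3, xh2), "resolution")

  # channel softmax sums to one at every pixel
  z <- array(rnorm(2 * 5 * 3 * 3), c(2, 5, 3, 3))
  sm <- oracleSoftmaxC(z)
  expect_equal(apply(sm, c(1, 3, 4), sum),
               array(1, c(2, 3, 3)), tolerance = 1e-12)

  # gate oracle on the block's own intermediate maps, fixed kernels
  blk2 <- mpfBlock(2L, 2L, 2L, common = 2L, factors = c(1L, 1L, 1L))
  p2 <- list()
  for (nm in c("f1", "x1", "x2")) {
    p2[[paste0(nm, "_w")]] <- gridArray(c(3, 3, 2, 2), 0.3)
    p2[[paste0(nm, "_b")]] <- c(0.1, -0.1)
    p2[[paste0(nm, "_gamma")]] <- c(1, 1)
    p2[[paste0(nm, "_beta")]] <- c(0, 0)
  }
  setBlockParameters(blk2, p2)
  a <- array(round(rnorm(1 * 2 * 4 * 4), 1), c(1, 2, 4, 4))
  b <- array(round(rnorm(1 * 2 * 4 * 4), 1), c(1, 2, 4, 4))
  cc <- array(round(rnorm(1 * 2 * 4 * 4), 1), c(1, 2, 4, 4))
  y2 <- blockForward(blk2, a, b, cc)
  pr <- function(x, nm) oracleConvBNEval(x, list(w = p2[[paste0(nm, "_w")]],
                                                 b = p2[[paste0(nm, "_b")]],
                                                 gamma = p2[[paste0(nm, "_gamma")]],
                                                 beta = p2[[paste0(nm, "_beta")]]), 1)
  F1 <- pr(a, "f1"); X1 <- pr(b, "x1"); X2 <- pr(cc, "x2")
  gate <- oracleRelu(oracleGAP(oracleSoftmaxC(X1 * X2)))
  expected <- F1
  for (c in 1:2) expected[, c, , ] <- F1[, c, , ] * gate[, c]
  expect_equal(y2, expected, tolerance = 1e-5)
})

test_that("gradients flow from every block output to every input", {
  set.seed(10)
  toNode <- function(a) sfanet:::agNode(aperm(a, c(3, 4, 1, 2)))
  gradOf <- function(outNode, inNodes) {
    loss <- sfanet:::agMean(outNode)
    sfanet:::agBackward(loss)
    vapply(inNodes, function(n) max(abs(n$grad)), numeric(1))
  }
  x <- array(rnorm(2 * 4 * 8 * 8), c(2, 4, 8, 8))
  n1 <- toNode(x)
  g <- gradOf(rasfBlock(4L, r = 2L)$fwd(n1, train = TRUE), list(n1))
  expect_true(all(g > 0))

  l1 <- toNode(array(rnorm(2 * 3 * 8 * 8), c(2, 3, 8, 8)))
  l2 <- toNode(array(rnorm(2 * 4 * 8 * 8), c(2, 4, 8, 8)))
  hi <- toNode(array(rnorm(2 * 8 * 4 * 4), c(2, 8, 4, 4)))
  g <- gradOf(affBlock(3L, 4L, 8L)$fwd(l1, l2, hi, train = TRUE), list(l1, l2, hi))
  expect_true(all(g > 0))

  a <- toNode(array(rnorm(2 * 2 * 8 * 8), c(2, 2, 8, 8)))
  b <- toNode(array(rnorm(2 * 3 * 4 * 4), c(2, 3, 4, 4)))
  cc <- toNode(array(rnorm(2 * 4 * 2 * 2), c(2, 4, 2, 2)))
  g <- gradOf(mpfBlock(2L, 3L, 4L)$fwd(a, b, cc, train = TRUE), list(a, b, cc))
  expect_true(all(g > 0))
})

test_that("block outputs stay finite for finite inputs", {
  set.seed(11)
  x <- array(rnorm(2 * 4 * 8 * 8, sd = 10), c(2, 4, 8, 8))
  expect_true(all(is.finite(blockForward(rasfBlock(4L, r = 2L), x))))
  expect_true(all(is.finite(blockForward(convBNBlock(4L, 4L), x, train = TRUE))))
})
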