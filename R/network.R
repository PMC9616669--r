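## Assembly of the full U-shaped network:
##   encoder: 4 levels of (conv unit x2) + 2x2 max pooling
##   bottleneck: conv unit x2, optionally followed by the residual atrous block
##   decoder: 4 levels; the skip path is either the attentional fusion block
##            (AFF variants) or a vanilla transpose-conv + concatenation skip
##   head: multi-path fusion over the three finest decoder stages (full
##         variant) or the finest decoder output alone, then 1x1 conv + sigmoid
##
## Channel plan with base width w: encoder levels carry w, 2w, 4w, 8w and the
## bottleneck 16w. The attentional skip at decoder level k takes low1 = the
## tensor entering encoder level k (the raw input for k = 1, otherwise the
## pooled map, i.e. the shallow feature *before* this level's convolutions),
## low2 = encoder level k's output (*after* the convolutions), and high = the
## decoder output one level deeper.

.hasRASF <- function(variant) variant %in% c("rasf", "rasf_aff", "full")
.hasAFF <- function(variant) variant %in% c("aff", "rasf_aff", "full")
.hasMPF <- function(variant) variant == "full"

#' Build a network
#'
#' Constructs the block graph and randomly initialises all parameters
#' (He-normal convolutions, unit-scale batch norm) for the requested
#' ablation variant.
#'
#' @param config a [NetworkConfig-class].
#' @param seed integer seed for the parameter initialisation; the same
#'   (config, seed) pair builds an identical network.
#' @return an [SFANet-class].
#' @export
buildNetwork <- function(config = networkConfig(), seed = 1L) {
  stopifnot(is(config, "NetworkConfig"))
  validObject(config)
  withr::with_seed(as.integer(seed), .buildModules(config))
}

.buildModules <- function(config) {
  w <- config@baseWidth
  v <- config@variant
  ch <- w * 2L^(0:4)                     # level widths + bottleneck
  inCh <- c(config@inChannels, ch[1:3])  # channels entering each encoder level
  m <- list()
  for (k in 1:4) {
    m[[paste0("enc", k, "a")]] <- convBNBlock(inCh[k], ch[k])
    m[[paste0("enc", k, "b")]] <- convBNBlock(ch[k], ch[k])
  }
  m$botA <- convBNBlock(ch[4], ch[5])
  m$botB <- convBNBlock(ch[5], ch[5])
  if (.hasRASF(v))
    m$rasf <- rasfBlock(ch[5], dilations = config@dilations,
                        r = config@attentionRatio)
  for (k in 4:1) {
    if (.hasAFF(v)) {
      m[[paste0("aff", k)]] <- affBlock(inCh[k], ch[k], ch[k + 1])
      dIn <- 3L * ch[k]
    } else {
      m[[paste0("up", k)]] <- .tconvUnit(ch[k + 1], ch[k])
      dIn <- 2L * ch[k]
    }
    m[[paste0("dec", k, "a")]] <- convBNBlock(dIn, ch[k])
    m[[paste0("dec", k, "b")]] <- convBNBlock(ch[k], ch[k])
  }
  if (.hasMPF(v))
    m$mpf <- mpfBlock(ch[1], ch[2], ch[3], common = ch[1])
  m$head <- .headUnit(ch[1])
  new("SFANet", config = config, modules = m)
}

## transpose-conv upsampling unit (2x) with BN + ReLU, used by non-AFF skips
.tconvUnit <- function(inChannels, outChannels) {
  params <- list(
    w = agParameter(array(rnorm(4 * inChannels * outChannels, 0,
                                sqrt(2 / (4 * inChannels))),
                          c(2, 2, inChannels, outChannels)), "w"),
    b = agParameter(numeric(outChannels), "b"),
    gamma = agParameter(rep(1, outChannels), "gamma"),
    beta = agParameter(numeric(outChannels), "beta"))
  st <- .newBNState(outChannels)
  fwd <- function(x, train = FALSE) {
    h <- agConvTranspose2(x, agLeaf(params$w), agLeaf(params$b))
    agRelu(agBatchNorm(h, agLeaf(params$gamma), agLeaf(params$beta), st, train))
  }
  .mkBlock("tconv", params, list(bn = st), fwd,
           list(inChannels = inChannels, outChannels = outChannels))
}

## 1x1 conv + sigmoid head. The bias starts at the logit of a ~12% foreground
## prior (vessels are a small minority of fundus pixels), so early training
## does not spend steps learning the class base rate.
.headUnit <- function(inChannels) {
  params <- list(
    w = agParameter(matrix(rnorm(inChannels, 0, sqrt(2 / inChannels)),
                           inChannels, 1), "w"),
    b = agParameter(-2, "b"))
  fwd <- function(x, train = FALSE)
    agSigmoid(agConv1x1(x, agLeaf(params$w), agLeaf(params$b)))
  .mkBlock("head", params, list(), fwd, list(inChannels = inChannels))
}

## Forward pass over autograd nodes; returns the output node.
.netForward <- function(net, xNode, train = FALSE) {
  m <- net@modules
  v <- net@config@variant
  ins <- list(xNode)                    # tensor entering each encoder level
  encOut <- list()
  h <- xNode
  for (k in 1:4) {
    if (k > 1) {
      h <- agMaxPool2(encOut[[k - 1]])
      ins[[k]] <- h
    }
    h <- m[[paste0("enc", k, "b")]]$fwd(m[[paste0("enc", k, "a")]]$fwd(h, train), train)
    encOut[[k]] <- h
  }
  h <- agMaxPool2(encOut[[4]])
  h <- m$botB$fwd(m$botA$fwd(h, train), train)
  if (.hasRASF(v)) h <- m$rasf$fwd(h, train)
  dec <- vector("list", 4)
  for (k in 4:1) {
    high <- if (k == 4) h else dec[[k + 1]]
    fused <- if (.hasAFF(v)) {
      m[[paste0("aff", k)]]$fwd(ins[[k]], encOut[[k]], high, train)
    } else {
      agConcatC(list(encOut[[k]], m[[paste0("up", k)]]$fwd(high, train)))
    }
    dec[[k]] <- m[[paste0("dec", k, "b")]]$fwd(
      m[[paste0("dec", k, "a")]]$fwd(fused, train), train)
  }
  pre <- if (.hasMPF(v)) m$mpf$fwd(dec[[1]], dec[[2]], dec[[3]], train) else dec[[1]]
  m$head$fwd(pre, train)
}

#' Run the network on a batch of patches
#'
#' @param net an [SFANet-class].
#' @param batch numeric array N x C x P x P with C = `inChannels` and P =
#'   `patchSize` of the network's configuration.
#' @param train logical; training mode uses batch statistics in BN layers.
#' @return an N x 1 x P x P array of vessel probabilities, strictly in (0, 1).
#' @export
networkForward <- function(net, batch, train = FALSE) {
  dm <- dim(batch)
  cfg <- net@config
  if (length(dm) != 4L || dm[2] != cfg@inChannels || dm[3] != cfg@patchSize ||
      dm[4] != cfg@patchSize)
    stop(sprintf("expected an N x %d x %d x %d batch", cfg@inChannels,
                 cfg@patchSize, cfg@patchSize))
  out <- .netForward(net, agNode(.toInternal(batch)), train = train)
  .toPublic(out$value)
}

#' Collect the trainable parameters of a network
#'
#' @param net an [SFANet-class].
#' @return flat named list of `agParameter` environments (live references).
#' @export
networkParameters <- function(net) {
  out <- list()
  for (nm in names(net@modules)) {
    ps <- net@modules[[nm]]$params
    names(ps) <- paste0(nm, ".", names(ps))
    out <- c(out, ps)
  }
  out
}

#' Count trainable parameters
#'
#' @param net an [SFANet-class].
#' @return total number of trainable scalar parameters.
#' @export
countParameters <- function(net) {
  sum(vapply(networkParameters(net), function(p) length(p$value), numeric(1)))
}

#' Tally the building blocks of a network
#'
#' Walks the block graph and counts blocks by type; used to verify the
#' ablation variants' construction.
#'
#' @param net an [SFANet-class].
#' @return named integer vector of counts per block type.
#' @export
blockTally <- function(net) {
  types <- vapply(net@modules, `[[`, character(1), "type")
  tab <- table(factor(types, levels = c("convBN", "tconv", "rasf", "aff", "mpf",
                                        "head", "channelAttention")))
  stats::setNames(as.integer(tab), names(tab))
}

setMethod("show", "SFANet", function(object) {
  cat(sprintf("SFANet ('%s' variant): %d blocks, %s trainable parameters\n",
              object@config@variant, length(object@modules),
              format(countParameters(object), big.mark = ",")))
  show(object@config)
})

## ---- checkpoints ------------------------------------------------------------

#' Save / load a network checkpoint
#'
#' The checkpoint holds the configuration, every parameter array and the
#' batch-norm running statistics, so a reloaded network reproduces eval-mode
#' outputs exactly.
#'
#' @param net an [SFANet-class].
#' @param path checkpoint file path.
#' @return `saveNetwork` returns `path` invisibly; `loadNetwork` returns the
#'   restored [SFANet-class].
#' @export
saveNetwork <- function(net, path) {
  cfg <- net@config
  ck <- list(
    config = list(variant = cfg@variant, inChannels = cfg@inChannels,
                  baseWidth = cfg@baseWidth, patchSize = cfg@patchSize,
                  dilations = cfg@dilations, attentionRatio = cfg@attentionRatio),
    params = lapply(networkParameters(net), function(p) p$value),
    bn = lapply(net@modules, function(mod)
      lapply(mod$states, function(st)
        if (is.environment(st)) list(mean = st$runningMean, var = st$runningVar))))
  saveRDS(ck, path)
  invisible(path)
}

#' @rdname saveNetwork
#' @export
loadNetwork <- function(path) {
  ck <- readRDS(path)
  cfg <- do.call(networkConfig, ck$config)
  net <- buildNetwork(cfg, seed = 0L)
  ps <- networkParameters(net)
  for (nm in names(ck$params)) {
    if (is.null(ps[[nm]])) stop("checkpoint parameter not in network: ", nm)
    ps[[nm]]$value <- ck$params[[nm]]
    ps[[nm]]$grad[] <- 0
  }
  for (nm in names(ck$bn)) {
    sts <- net@modules[[nm]]$states
    for (snm in names(ck$bn[[nm]])) {
      saved <- ck$bn[[nm]][[snm]]
      if (!is.null(saved) && is.environment(sts[[snm]])) {
        sts[[snm]]$runningMean <- saved$mean
        sts[[snm]]$runningVar <- saved$var
      }
    }
  }
  net
}
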