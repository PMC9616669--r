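#' @import methods
#' @importFrom stats rnorm runif sd
#' @importFrom utils read.delim write.table head tail
#' @useDynLib sfanet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.VARIANTS <- c("baseline", "rasf", "aff", "rasf_aff", "full")

#' Parameters of the synthetic fundus generator
#'
#' Controls the procedural generator of fundus-like images with pixel-exact
#' vessel ground truth: a branching tree of curvilinear vessels of decreasing
#' calibre inside a dark circular field of view (FOV), rendered over a
#' textured background with Gaussian blur and additive noise.
#'
#' @slot imageSize image side length in pixels (square images).
#' @slot nRoots number of root vessels entering the FOV.
#' @slot branchProb probability of spawning a side branch at each growth step.
#' @slot widthRange range (min, max) of root vessel widths in pixels.
#' @slot tortuosity standard deviation (radians) of the per-step heading change.
#' @slot contrast signed vessel-minus-background intensity difference in
#'   \eqn{[-1, 1]}; negative values give the dark vessels of real fundus images.
#' @slot noiseSd standard deviation of additive Gaussian pixel noise; the
#'   low-frequency background texture amplitude is tied to this value, so
#'   `noiseSd = 0` yields a perfectly flat background.
#' @slot blurSigma Gaussian blur sigma in pixels applied to the rendered image.
#' @slot fovRadiusFrac FOV disk radius as a fraction of the image side.
#' @slot channels 1 for grayscale output, 3 to replicate into RGB.
#' @export
setClass("SynthParams", representation(
  imageSize = "integer", nRoots = "integer", branchProb = "numeric",
  widthRange = "numeric", tortuosity = "numeric", contrast = "numeric",
  noiseSd = "numeric", blurSigma = "numeric", fovRadiusFrac = "numeric",
  channels = "integer"))

setValidity("SynthParams", function(object) {
  msg <- character()
  if (object@imageSize < 1L) msg <- c(msg, "imageSize must be positive")
  if (object@nRoots < 1L) msg <- c(msg, "nRoots must be >= 1")
  if (object@branchProb < 0 || object@branchProb > 1)
    msg <- c(msg, "branchProb must be in [0, 1]")
  if (length(object@widthRange) != 2L || object@widthRange[1] > object@widthRange[2] ||
      any(object@widthRange <= 0))
    msg <- c(msg, "widthRange must be positive with min <= max")
  if (object@tortuosity < 0) msg <- c(msg, "tortuosity must be >= 0")
  if (abs(object@contrast) > 1) msg <- c(msg, "contrast must be in [-1, 1]")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@blurSigma < 0) msg <- c(msg, "blurSigma must be >= 0")
  if (object@fovRadiusFrac <= 0 || object@fovRadiusFrac > 0.5)
    msg <- c(msg, "fovRadiusFrac must be in (0, 0.5]")
  if (!object@channels %in% c(1L, 3L)) msg <- c(msg, "channels must be 1 or 3")
  if (length(msg)) msg else TRUE
})

#' Construct synthetic-generator parameters
#'
#' Defaults describe a 128-pixel fundus-like image with three vessel trees,
#' dark vessels of width 1.5-4 px, moderate tortuosity and noise.
#'
#' @param imageSize,nRoots,branchProb,widthRange,tortuosity,contrast,noiseSd,blurSigma,fovRadiusFrac,channels
#'   see the class documentation for [SynthParams-class].
#' @return a validated [SynthParams-class] object.
#' @export
synthParams <- function(imageSize = 128L, nRoots = 3L, branchProb = 0.03,
                        widthRange = c(1.5, 4), tortuosity = 0.12,
                        contrast = -0.35, noiseSd = 0.05, blurSigma = 0.8,
                        fovRadiusFrac = 0.48, channels = 1L) {
  new("SynthParams", imageSize = as.integer(imageSize), nRoots = as.integer(nRoots),
      branchProb = branchProb, widthRange = as.numeric(widthRange),
      tortuosity = tortuosity, contrast = contrast, noiseSd = noiseSd,
      blurSigma = blurSigma, fovRadiusFrac = fovRadiusFrac,
      channels = as.integer(channels))
}

#' A branching vessel tree in image coordinates
#'
#' Segments are straight sub-pixel steps of the growth walk; consecutive
#' steps of a branch are chained through the `parent` column, so the tree can
#' be walked exhaustively. Column-coordinates are `x`, row-coordinates `y`,
#' origin top-left.
#'
#' @slot segments data.frame with columns id, parent (0 for roots), x0, y0,
#'   x1, y1, width (px), depth (branching depth, 0 for the trunk).
#' @slot roots matrix of root starting positions (x, y).
#' @slot imageSize side length of the target image.
#' @export
setClass("VesselTree", representation(
  segments = "data.frame", roots = "matrix", imageSize = "integer"))

setValidity("VesselTree", function(object) {
  s <- object@segments
  need <- c("id", "parent", "x0", "y0", "x1", "y1", "width", "depth")
  if (!all(need %in% names(s))) return("segments missing required columns")
  if (nrow(s)) {
    if (any(s$width <= 0)) return("segment widths must be strictly positive")
    if (!all(is.finite(as.matrix(s[, c("x0", "y0", "x1", "y1", "width")]))))
      return("segment coordinates must be finite")
    par <- match(s$parent, s$id)
    has <- !is.na(par)
    if (any(s$width[has] > s$width[par[has]] + 1e-9))
      return("child segment width must not exceed its parent's")
  }
  TRUE
})

#' One fundus image with ground truth
#'
#' The atomic dataset unit: an intensity image in \eqn{[0,1]}, a binary vessel
#' mask, a binary field-of-view mask, and provenance metadata.
#'
#' @slot image numeric array, H x W (grayscale) or H x W x 3 (RGB), in [0, 1].
#' @slot vesselMask binary H x W matrix; 1 marks vessel pixels.
#' @slot fovMask binary H x W matrix; 1 marks pixels inside the field of view.
#' @slot sampleId character identifier.
#' @slot source one of "synthetic", "drive", "chase", "stare", "user".
#' @export
setClass("FundusSample", representation(
  image = "array", vesselMask = "matrix", fovMask = "matrix",
  sampleId = "character", source = "character"))

setValidity("FundusSample", function(object) {
  dm <- dim(object@image)
  if (!length(dm) %in% c(2L, 3L)) return("image must be H x W or H x W x 3")
  hw <- dm[1:2]
  if (!identical(dim(object@vesselMask), hw) || !identical(dim(object@fovMask), hw))
    return("image and masks must share H x W")
  if (!all(object@vesselMask %in% c(0, 1))) return("vesselMask must be exactly {0,1}")
  if (!all(object@fovMask %in% c(0, 1))) return("fovMask must be exactly {0,1}")
  if (any(object@vesselMask == 1 & object@fovMask == 0))
    return("vessel pixels must lie inside the FOV mask")
  if (!object@source %in% c("synthetic", "drive", "chase", "stare", "user"))
    return("unknown source")
  TRUE
})

#' Architecture configuration
#'
#' Describes a U-shaped segmentation network with four encoder/decoder levels
#' and the three optional feature-aggregation blocks. `variant` selects the
#' ablation row: `"baseline"` (plain U-shape), `"rasf"` (+ residual atrous
#' bottleneck), `"aff"` (+ attentional skip fusion), `"rasf_aff"`, and
#' `"full"` (+ multi-path decoder fusion head).
#'
#' @slot inChannels 1 (grayscale) or 3 (RGB).
#' @slot baseWidth channel count of the first encoder level; doubled per level.
#' @slot depth number of down/upsampling stages (fixed at 4).
#' @slot dilations dilation rates of the three parallel atrous branches.
#' @slot attentionRatio squeeze ratio r of the channel-attention bottleneck.
#' @slot variant one of baseline, rasf, aff, rasf_aff, full.
#' @slot patchSize input patch side; must be divisible by 2^depth = 16.
#' @export
setClass("NetworkConfig", representation(
  inChannels = "integer", baseWidth = "integer", depth = "integer",
  dilations = "integer", attentionRatio = "integer", variant = "character",
  patchSize = "integer"))

setValidity("NetworkConfig", function(object) {
  msg <- character()
  if (!object@inChannels %in% c(1L, 3L)) msg <- c(msg, "inChannels must be 1 or 3")
  if (object@baseWidth < 4L) msg <- c(msg, "baseWidth must be >= 4")
  if (object@depth != 4L) msg <- c(msg, "depth is fixed at 4")
  if (any(object@dilations < 1L)) msg <- c(msg, "dilations must be >= 1")
  if (object@attentionRatio < 1L) msg <- c(msg, "attentionRatio must be >= 1")
  if (!object@variant %in% .VARIANTS)
    msg <- c(msg, sprintf("variant must be one of: %s", paste(.VARIANTS, collapse = ", ")))
  if (object@patchSize %% 2L^object@depth != 0L)
    msg <- c(msg, "patchSize must be divisible by 2^depth = 16")
  if (length(msg)) msg else TRUE
})

#' Construct a network configuration
#'
#' @param variant ablation variant; see [NetworkConfig-class].
#' @param inChannels input channel count (1 or 3).
#' @param baseWidth first-level channel width (default 32, doubled per level).
#' @param patchSize training/inference patch side (default 96, divisible by 16).
#' @param dilations atrous rates of the bottleneck block (default 1, 3, 5).
#' @param attentionRatio channel-attention squeeze ratio (default 16).
#' @return a validated [NetworkConfig-class].
#' @export
networkConfig <- function(variant = "full", inChannels = 1L, baseWidth = 32L,
                          patchSize = 96L, dilations = c(1L, 3L, 5L),
                          attentionRatio = 16L) {
  new("NetworkConfig", inChannels = as.integer(inChannels),
      baseWidth = as.integer(baseWidth), depth = 4L,
      dilations = as.integer(dilations), attentionRatio = as.integer(attentionRatio),
      variant = variant, patchSize = as.integer(patchSize))
}

#' A built segmentation network
#'
#' Holds the block graph and the trainable parameter store. Parameters live in
#' environments, so the object has reference semantics under training.
#'
#' @slot config the [NetworkConfig-class] the network was built from.
#' @slot modules named list of building blocks (encoder/decoder conv units,
#'   bottleneck, skip-fusion and head blocks).
#' @export
setClass("SFANet", representation(config = "NetworkConfig", modules = "list"))

#' A set of image/label patches
#'
#' @slot patches numeric array N x C x P x P.
#' @slot labels binary numeric array N x 1 x P x P.
#' @slot coords data.frame with sampleId, top, left (1-based window origins).
#' @slot patchSize patch side P.
#' @export
setClass("PatchSet", representation(
  patches = "array", labels = "array", coords = "data.frame",
  patchSize = "integer"))

setValidity("PatchSet", function(object) {
  dp <- dim(object@patches); dl <- dim(object@labels)
  if (length(dp) != 4L || length(dl) != 4L) return("patches and labels must be 4-d")
  if (dp[1] != dl[1] || dp[1] < 1L) return("need N >= 1 matching patches and labels")
  if (dl[2] != 1L) return("labels must have one channel")
  if (!all(object@labels %in% c(0, 1))) return("labels must be binary")
  if (nrow(object@coords) != dp[1]) return("coords must have one row per patch")
  TRUE
})

#' Pixel-level confusion counts
#'
#' @slot tp,fp,tn,fn non-negative counts over evaluated (FOV) pixels.
#' @export
setClass("ConfusionCounts", representation(
  tp = "numeric", fp = "numeric", tn = "numeric", fn = "numeric"))

setValidity("ConfusionCounts", function(object) {
  v <- c(object@tp, object@fp, object@tn, object@fn)
  if (any(v < 0) || any(v != round(v))) return("counts must be non-negative integers")
  TRUE
})

#' Segmentation metrics report
#'
#' Sensitivity, specificity and accuracy at a fixed threshold, plus the
#' threshold-free ROC curve and its area, pooled over all evaluated FOV
#' pixels, with a per-sample breakdown.
#'
#' @slot counts pooled [ConfusionCounts-class].
#' @slot se,sp,acc,auc pooled metrics in [0, 1].
#' @slot threshold binarisation threshold used for SE/SP/ACC.
#' @slot roc data.frame with columns threshold, fpr, tpr.
#' @slot perSample data.frame with per-image se, sp, acc, auc.
#' @export
setClass("MetricsReport", representation(
  counts = "ConfusionCounts", se = "numeric", sp = "numeric", acc = "numeric",
  auc = "numeric", threshold = "numeric", roc = "data.frame",
  perSample = "data.frame"))

#' Training configuration
#'
#' Defaults follow the published schedule: Adam with learning rate 1e-4,
#' weight decay 1e-4, batch size 16.
#'
#' @slot lr,weightDecay,batchSize,epochs,seed training hyper-parameters.
#' @slot checkpoint optional path where the best-validation model is saved.
#' @export
setClass("TrainConfig", representation(
  lr = "numeric", weightDecay = "numeric", batchSize = "integer",
  epochs = "integer", seed = "integer", checkpoint = "character"))

setValidity("TrainConfig", function(object) {
  if (object@lr < 0 || object@weightDecay < 0) return("lr and weightDecay must be >= 0")
  if (object@batchSize < 1L || object@epochs < 1L) return("batchSize and epochs must be >= 1")
  TRUE
})

#' Construct a training configuration
#' @param lr Adam learning rate (default 1e-4).
#' @param weightDecay L2 weight decay added to gradients (default 1e-4).
#' @param batchSize minibatch size (default 16).
#' @param epochs number of passes over the training patches.
#' @param seed RNG seed controlling initial shuffling and batch order.
#' @param checkpoint optional file path for the best-validation checkpoint.
#' @return a validated [TrainConfig-class].
#' @export
trainConfig <- function(lr = 1e-4, weightDecay = 1e-4, batchSize = 16L,
                        epochs = 5L, seed = 1L, checkpoint = character()) {
  new("TrainConfig", lr = lr, weightDecay = weightDecay,
      batchSize = as.integer(batchSize), epochs = as.integer(epochs),
      seed = as.integer(seed), checkpoint = checkpoint)
}

## ---- show methods -----------------------------------------------------------

setMethod("show", "FundusSample", function(object) {
  dm <- dim(object@image)
  cat(sprintf("FundusSample '%s' (%s): %d x %d%s, vessel %.1f%% of FOV\n",
              object@sampleId, object@source, dm[1], dm[2],
              if (length(dm) == 3) " x 3" else "",
              100 * sum(object@vesselMask) / max(1, sum(object@fovMask))))
})

setMethod("show", "VesselTree", function(object) {
  cat(sprintf("VesselTree: %d segments, %d roots, max depth %d, image %d px\n",
              nrow(object@segments), nrow(object@roots),
              if (nrow(object@segments)) max(object@segments$depth) else 0L,
              object@imageSize))
})

setMethod("show", "NetworkConfig", function(object) {
  cat(sprintf("NetworkConfig: variant '%s', %d -> %d channels base, depth %d, patch %d, dilations %s, r = %d\n",
              object@variant, object@inChannels, object@baseWidth, object@depth,
              object@patchSize, paste(object@dilations, collapse = "/"),
              object@attentionRatio))
})

setMethod("show", "PatchSet", function(object) {
  dp <- dim(object@patches)
  cat(sprintf("PatchSet: %d patches of %d x %d x %d from %d source image(s)\n",
              dp[1], dp[2], dp[3], dp[4], length(unique(object@coords$sampleId))))
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP %d FP %d TN %d FN %d (n = %d)\n",
              as.integer(object@tp), as.integer(object@fp),
              as.integer(object@tn), as.integer(object@fn),
              as.integer(object@tp + object@fp + object@tn + object@fn)))
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport @ threshold %.2f: SE %.4f SP %.4f ACC %.4f AUC %.4f (%d samples)\n",
              object@threshold, object@se, object@sp, object@acc, object@auc,
              nrow(object@perSample)))
})

## ---- accessors --------------------------------------------------------------

#' Accessors for fundus samples and patch sets
#'
#' @param x a [FundusSample-class] or [PatchSet-class].
#' @return the requested component (image array, binary mask, id, patch
#'   array, label array, or coordinate table).
#' @name accessors
NULL

#' @rdname accessors
#' @export
sampleImage <- function(x) x@image

#' @rdname accessors
#' @export
vesselMask <- function(x) x@vesselMask

#' @rdname accessors
#' @export
fovMask <- function(x) x@fovMask

#' @rdname accessors
#' @export
sampleId <- function(x) x@sampleId

#' @rdname accessors
#' @export
patchArray <- function(x) x@patches

#' @rdname accessors
#' @export
labelArray <- function(x) x@labels

#' @rdname accessors
#' @export
patchCoords <- function(x) x@coords

#' @rdname accessors
#' @export
netConfig <- function(x) x@config
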