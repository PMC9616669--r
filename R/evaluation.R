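## Pixel-level segmentation scoring: confusion counts, sensitivity /
## specificity / accuracy at a threshold, ROC sweep and AUC, restricted to
## field-of-view pixels, over stitched whole-image predictions.

#' Pixel confusion counts inside the FOV
#'
#' Binarises the probability map at `threshold` (probabilities >= threshold
#' count as positive) and tallies TP/FP/TN/FN over pixels with `fov == 1`.
#'
#' @param prob numeric H x W probability map.
#' @param gt binary H x W ground-truth mask.
#' @param fov binary H x W field-of-view mask; `NULL` evaluates all pixels.
#' @param threshold binarisation threshold (default 0.5).
#' @return a [ConfusionCounts-class].
#' @export
confusionCounts <- function(prob, gt, fov = NULL, threshold = 0.5) {
  if (is.null(fov)) fov <- matrix(1, nrow(gt), ncol(gt))
  if (!identical(dim(prob), dim(gt)) || !identical(dim(gt), dim(fov)))
    stop("prob, gt and fov must share dimensions")
  if (!all(gt %in% c(0, 1))) stop("gt must be a binary mask")
  if (!all(fov %in% c(0, 1))) stop("fov must be a binary mask")
  keep <- fov == 1
  p <- prob[keep] >= threshold
  y <- gt[keep] == 1
  new("ConfusionCounts",
      tp = sum(p & y), fp = sum(p & !y), tn = sum(!p & !y), fn = sum(!p & y))
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' SE = TP/(TP+FN), SP = TN/(FP+TN), ACC = (TP+TN)/(TP+TN+FP+FN). A zero
#' denominator yields `NA` with a warning, never a silent zero.
#'
#' @param counts a [ConfusionCounts-class].
#' @return named numeric vector `c(se, sp, acc)`.
#' @export
seSpAcc <- function(counts) {
  stopifnot(is(counts, "ConfusionCounts"))
  tp <- counts@tp; fp <- counts@fp; tn <- counts@tn; fn <- counts@fn
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined: zero denominator")
      return(NA_real_)
    }
    num / den
  }
  c(se = ratio(tp, tp + fn, "sensitivity"),
    sp = ratio(tn, fp + tn, "specificity"),
    acc = ratio(tp + tn, tp + tn + fp + fn, "accuracy"))
}

#' ROC curve and AUC over pooled pixel scores
#'
#' Sweeps the distinct score values as thresholds, producing an ROC curve
#' from (0,0) to (1,1), and integrates it with the trapezoidal rule. With
#' ties handled as diagonal segments this equals the Mann-Whitney
#' probability that a random positive outscores a random negative (ties
#' counted 1/2).
#'
#' @param scores numeric vector of pixel scores.
#' @param labels binary vector of pixel labels (same length).
#' @return list with `auc` (scalar) and `curve` (data.frame threshold, fpr,
#'   tpr, starting at (0,0) and ending at (1,1)).
#' @export
rocAuc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (!all(labels %in% c(0, 1))) stop("labels must be binary")
  nPos <- sum(labels == 1); nNeg <- sum(labels == 0)
  if (nPos == 0 || nNeg == 0)
    stop("ROC needs at least one positive and one negative pixel")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  ## index of the last element of each distinct-score group
  lastOfGroup <- which(c(s[-1] != s[-length(s)], TRUE))
  tpr <- c(0, cumsum(y)[lastOfGroup] / nPos)
  fpr <- c(0, cumsum(1 - y)[lastOfGroup] / nNeg)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(auc = auc,
       curve = data.frame(threshold = c(Inf, s[lastOfGroup]), fpr = fpr, tpr = tpr))
}

#' Evaluate a network on whole images
#'
#' For every sample: normalise (optionally), tile with the given stride, run
#' the network in eval mode, stitch the tile predictions back by averaging,
#' and pool the FOV pixels. Reports pooled SE/SP/ACC at the threshold, the
#' pooled ROC/AUC, and a per-sample breakdown.
#'
#' @param net an [SFANet-class].
#' @param samples list of [FundusSample-class] with ground truth and FOV.
#' @param threshold binarisation threshold for SE/SP/ACC (default 0.5).
#' @param stride tiling stride; defaults to half the patch size.
#' @param normalize z-score each image inside its FOV before tiling (must
#'   match the setting used for training patches).
#' @param batchSize tiles per forward pass.
#' @param fovRestrict if `FALSE`, metrics are computed over all pixels
#'   (an all-ones FOV) instead of inside the FOV mask.
#' @return a [MetricsReport-class].
#' @export
evaluateNetwork <- function(net, samples, threshold = 0.5, stride = NULL,
                            normalize = TRUE, batchSize = 16L,
                            fovRestrict = TRUE) {
  P <- net@config@patchSize
  if (is.null(stride)) stride <- P %/% 2L
  allScores <- list(); allLabels <- list()
  per <- vector("list", length(samples))
  pooled <- new("ConfusionCounts", tp = 0, fp = 0, tn = 0, fn = 0)
  for (k in seq_along(samples)) {
    s <- samples[[k]]
    prob <- predictImage(net, s, stride = stride, normalize = normalize,
                         batchSize = batchSize)
    fov <- if (fovRestrict) s@fovMask else matrix(1, nrow(s@fovMask), ncol(s@fovMask))
    cc <- confusionCounts(prob, s@vesselMask, fov, threshold)
    pooled@tp <- pooled@tp + cc@tp; pooled@fp <- pooled@fp + cc@fp
    pooled@tn <- pooled@tn + cc@tn; pooled@fn <- pooled@fn + cc@fn
    keep <- fov == 1
    sc <- prob[keep]; lb <- s@vesselMask[keep]
    allScores[[k]] <- sc; allLabels[[k]] <- lb
    m <- suppressWarnings(seSpAcc(cc))
    sampleAuc <- if (length(unique(lb)) == 2L) rocAuc(sc, lb)$auc else NA_real_
    per[[k]] <- data.frame(sampleId = s@sampleId, se = m["se"], sp = m["sp"],
                           acc = m["acc"], auc = sampleAuc,
                           stringsAsFactors = FALSE, row.names = NULL)
  }
  m <- seSpAcc(pooled)
  roc <- rocAuc(unlist(allScores), unlist(allLabels))
  new("MetricsReport", counts = pooled, se = m[["se"]], sp = m[["sp"]],
      acc = m[["acc"]], auc = roc$auc, threshold = threshold,
      roc = roc$curve, perSample = do.call(rbind, per))
}

#' Segment one whole image
#'
#' Tiles the image, runs the network in eval mode and stitches the tile
#' probabilities back by per-pixel averaging.
#'
#' @param net an [SFANet-class].
#' @param sample a [FundusSample-class] (only its image and FOV are used).
#' @param stride tiling stride; defaults to half the patch size.
#' @param normalize z-score the image inside its FOV first.
#' @param batchSize tiles per forward pass.
#' @return H x W matrix of vessel probabilities.
#' @export
predictImage <- function(net, sample, stride = NULL, normalize = TRUE,
                         batchSize = 16L) {
  P <- net@config@patchSize
  if (is.null(stride)) stride <- P %/% 2L
  img <- if (normalize) .normalizeFov(sample@image, sample@fovMask) else sample@image
  tl <- tileImage(img, P, stride)
  n <- dim(tl$patches)[1]
  preds <- array(0, c(n, 1, P, P))
  for (from in seq(1L, n, by = batchSize)) {
    to <- min(from + batchSize - 1L, n)
    preds[from:to, , , ] <- networkForward(net, tl$patches[from:to, , , , drop = FALSE])
  }
  dm <- dim(sample@image)
  reconstructFromPatches(preds, tl$coords, dm[1], dm[2])
}
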