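## Binary cross-entropy training of any network variant with Adam, epoch-end
## validation, best-checkpoint selection and fully seeded reproducibility.

#' Mean binary cross-entropy loss
#'
#' \eqn{-\mathrm{mean}[y \log p + (1-y)\log(1-p)]}, with predictions clamped
#' to \eqn{[\epsilon, 1-\epsilon]} so the loss stays finite at the extremes.
#'
#' @param pred array of predicted probabilities.
#' @param target binary array of the same shape.
#' @param eps clamping constant (default 1e-7).
#' @return scalar loss, non-negative and finite.
#' @export
bceLoss <- function(pred, target, eps = 1e-7) {
  if (!identical(.agDim(pred), .agDim(target)))
    stop("pred and target must share dimensions")
  if (!all(target %in% c(0, 1))) stop("target must be binary")
  p <- pmin(pmax(pred, eps), 1 - eps)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}

#' Train a network on a patch set
#'
#' Minimises the mean binary cross-entropy with Adam, using the learning
#' rate, weight decay and batch size of the training configuration. Shuffle
#' order and all other randomness derive from `config@seed`, so identical
#' (network, data, config) runs reproduce identical losses. At the end of
#' every epoch the validation loss and pixel-AUC are computed in eval mode;
#' the parameters of the best-validation-loss epoch are restored into the
#' returned network (and written to `config@checkpoint` when set).
#'
#' @param net an [SFANet-class]; updated in place (parameters are
#'   environments) and also returned.
#' @param trainSet a [PatchSet-class] of training patches.
#' @param valSet optional [PatchSet-class] of validation patches.
#' @param config a [TrainConfig-class].
#' @param verbose print one line per epoch.
#' @return list with `net` (trained network) and `history` (data.frame with
#'   epoch, trainLoss, valLoss, valAUC, and attribute `bestEpoch`).
#' @export
trainNetwork <- function(net, trainSet, valSet = NULL, config = trainConfig(),
                         verbose = FALSE) {
  stopifnot(is(net, "SFANet"), is(trainSet, "PatchSet"))
  validObject(config)
  nTrain <- dim(trainSet@patches)[1]
  if (config@batchSize > nTrain)
    stop("batch size exceeds the number of training patches")
  params <- networkParameters(net)
  history <- data.frame(epoch = integer(), trainLoss = numeric(),
                        valLoss = numeric(), valAUC = numeric())
  bestVal <- Inf
  bestParams <- NULL
  step <- 0L
  withr::with_seed(config@seed, {
    for (epoch in seq_len(config@epochs)) {
      ord <- sample.int(nTrain)
      batchLosses <- numeric()
      for (from in seq(1L, nTrain, by = config@batchSize)) {
        to <- min(from + config@batchSize - 1L, nTrain)
        idx <- ord[from:to]
        xb <- .toInternal(trainSet@patches[idx, , , , drop = FALSE])
        yb <- .toInternal(trainSet@labels[idx, , , , drop = FALSE])
        out <- .netForward(net, agNode(xb), train = TRUE)
        loss <- agBCE(out, yb)
        if (!is.finite(loss$value))
          stop(sprintf("non-finite training loss (%g) at epoch %d, step %d; ",
                       loss$value, epoch, step + 1L),
               "check the learning rate and input scaling")
        agZeroGrads(params)
        agBackward(loss)
        step <- step + 1L
        adamStep(params, lr = config@lr, weightDecay = config@weightDecay,
                 t = step)
        batchLosses <- c(batchLosses, loss$value)
      }
      valLoss <- NA_real_; valAUC <- NA_real_
      if (!is.null(valSet)) {
        v <- .validationMetrics(net, valSet, config@batchSize)
        valLoss <- v$loss; valAUC <- v$auc
        if (is.finite(valLoss) && valLoss < bestVal) {
          bestVal <- valLoss
          bestParams <- lapply(params, function(p) p$value)
          attr(bestParams, "epoch") <- epoch
        }
      }
      history <- rbind(history, data.frame(
        epoch = epoch, trainLoss = mean(batchLosses), valLoss = valLoss,
        valAUC = valAUC))
      if (verbose)
        message(sprintf("epoch %d: train %.4f val %.4f auc %.4f", epoch,
                        mean(batchLosses), valLoss, valAUC))
    }
  })
  if (!is.null(bestParams)) {
    for (nm in names(bestParams)) params[[nm]]$value <- bestParams[[nm]]
    attr(history, "bestEpoch") <- attr(bestParams, "epoch")
  }
  if (length(config@checkpoint) && nzchar(config@checkpoint))
    saveNetwork(net, config@checkpoint)
  list(net = net, history = history)
}

## validation loss + pooled pixel AUC in eval mode
.validationMetrics <- function(net, valSet, batchSize) {
  n <- dim(valSet@patches)[1]
  losses <- numeric(); ns <- numeric()
  scores <- list(); labels <- list()
  for (from in seq(1L, n, by = batchSize)) {
    to <- min(from + batchSize - 1L, n)
    xb <- valSet@patches[from:to, , , , drop = FALSE]
    yb <- valSet@labels[from:to, , , , drop = FALSE]
    pb <- networkForward(net, xb)
    losses <- c(losses, bceLoss(pb, yb)); ns <- c(ns, to - from + 1L)
    scores[[length(scores) + 1L]] <- as.vector(pb)
    labels[[length(labels) + 1L]] <- as.vector(yb)
  }
  y <- unlist(labels)
  auc <- if (length(unique(y)) == 2L) rocAuc(unlist(scores), y)$auc else NA_real_
  list(loss = sum(losses * ns) / sum(ns), auc = auc)
}

#' Leave-one-out cross-validation folds
#'
#' The protocol used for small datasets: fold i tests sample i and trains on
#' all the others.
#'
#' @param samples list of at least two [FundusSample-class] objects.
#' @return list of `length(samples)` folds, each a list with `train` (the
#'   remaining samples) and `test` (a single-sample list).
#' @export
leaveOneOutSplits <- function(samples) {
  n <- length(samples)
  if (n < 2L) stop("leave-one-out needs at least 2 samples")
  lapply(seq_len(n), function(i)
    list(train = samples[-i], test = samples[i]))
}
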