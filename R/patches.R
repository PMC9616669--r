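## Patch extraction for training and deterministic tiling + stitched
## reconstruction for whole-image inference.

## z-score an image inside the FOV (per channel); pixels outside the FOV are
## set to zero. Stabilises training across images of different brightness.
.normalizeFov <- function(image, fov) {
  norm1 <- function(ch) {
    v <- ch[fov == 1]
    s <- max(sd(v), 1e-8)
    out <- (ch - mean(v)) / s
    out[fov == 0] <- 0
    out
  }
  if (length(dim(image)) == 3L) {
    for (c in seq_len(dim(image)[3])) image[, , c] <- norm1(image[, , c])
    image
  } else norm1(image)
}

.imageChannels <- function(image) if (length(dim(image)) == 3L) dim(image)[3] else 1L

.cutWindow <- function(image, top, left, P) {
  if (length(dim(image)) == 3L) image[top:(top + P - 1), left:(left + P - 1), , drop = FALSE]
  else image[top:(top + P - 1), left:(left + P - 1), drop = FALSE]
}

#' Extract random training patches
#'
#' Draws `n` windows of size P x P uniformly over the samples and over all
#' valid top-left positions; image and label are cut from identical windows.
#'
#' @param samples list of [FundusSample-class].
#' @param n number of patches.
#' @param patchSize window side P; every image must be at least P x P.
#' @param seed RNG seed; draws are deterministic for a fixed seed.
#' @param normalize z-score each image inside its FOV before cutting.
#' @param fovOnly restrict patch centres to the FOV (rejection sampling).
#' @return a [PatchSet-class].
#' @export
extractRandomPatches <- function(samples, n, patchSize = 96L, seed = 1L,
                                 normalize = TRUE, fovOnly = FALSE) {
  stopifnot(n >= 1)
  P <- as.integer(patchSize)
  for (s in samples) {
    dm <- dim(s@image)
    if (dm[1] < P || dm[2] < P)
      stop(sprintf("sample '%s' (%d x %d) is smaller than the patch size %d",
                   s@sampleId, dm[1], dm[2], P))
  }
  imgs <- lapply(samples, function(s)
    if (normalize) .normalizeFov(s@image, s@fovMask) else s@image)
  C <- .imageChannels(samples[[1]]@image)
  patches <- array(0, c(n, C, P, P))
  labels <- array(0, c(n, 1, P, P))
  ids <- character(n); tops <- integer(n); lefts <- integer(n)
  withr::with_seed(as.integer(seed), {
    for (i in seq_len(n)) {
      repeat {
        si <- sample.int(length(samples), 1L)
        dm <- dim(samples[[si]]@image)
        top <- sample.int(dm[1] - P + 1L, 1L)
        left <- sample.int(dm[2] - P + 1L, 1L)
        if (!fovOnly) break
        cy <- top + P %/% 2L; cx <- left + P %/% 2L
        if (samples[[si]]@fovMask[cy, cx] == 1) break
      }
      win <- .cutWindow(imgs[[si]], top, left, P)
      patches[i, , , ] <- aperm(array(win, c(P, P, C)), c(3, 1, 2))
      labels[i, 1, , ] <- samples[[si]]@vesselMask[top:(top + P - 1), left:(left + P - 1)]
      ids[i] <- samples[[si]]@sampleId; tops[i] <- top; lefts[i] <- left
    }
  })
  new("PatchSet", patches = patches, labels = labels,
      coords = data.frame(sampleId = ids, top = tops, left = lefts,
                          stringsAsFactors = FALSE),
      patchSize = P)
}

#' Split indices into train / validation parts
#'
#' @param n number of items.
#' @param fraction train fraction in (0, 1); train size is `round(n * fraction)`.
#' @param seed shuffle seed.
#' @return list with integer vectors `train` and `val` forming a disjoint
#'   partition of `1:n`.
#' @export
splitIndices <- function(n, fraction = 0.8, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1, n >= 2)
  ntr <- round(n * fraction)
  if (ntr < 1 || ntr >= n)
    stop("split would leave one side empty")
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  list(train = sort(perm[seq_len(ntr)]), val = sort(perm[(ntr + 1L):n]))
}

#' Split a patch set into train and validation subsets
#'
#' @param ps a [PatchSet-class].
#' @param fraction train fraction (default 0.8, the published 152,000/38,000
#'   protocol applied to 190,000 patches).
#' @param seed shuffle seed.
#' @return list of two [PatchSet-class] objects, `train` and `val`.
#' @export
splitPatches <- function(ps, fraction = 0.8, seed = 1L) {
  idx <- splitIndices(dim(ps@patches)[1], fraction, seed)
  take <- function(k) new("PatchSet",
    patches = ps@patches[k, , , , drop = FALSE],
    labels = ps@labels[k, , , , drop = FALSE],
    coords = ps@coords[k, , drop = FALSE],
    patchSize = ps@patchSize)
  list(train = take(idx$train), val = take(idx$val))
}

#' Tile an image into overlapping windows
#'
#' Produces an ordered grid of P x P windows with the given stride; the last
#' row/column of windows is clamped to the image border so every pixel is
#' covered.
#'
#' @param image H x W (or H x W x C) array, both sides at least P.
#' @param patchSize window side P.
#' @param stride step between window origins; `0 < stride <= P`.
#' @return list with `patches` (N x C x P x P) and `coords`
#'   (data.frame top, left).
#' @export
tileImage <- function(image, patchSize, stride = patchSize %/% 2L) {
  P <- as.integer(patchSize); stride <- as.integer(stride)
  if (stride <= 0) stop("stride must be positive")
  if (stride > P) stop("stride must not exceed the patch size")
  dm <- dim(image)
  if (dm[1] < P || dm[2] < P) stop("image is smaller than the patch size")
  starts <- function(total) {
    s <- seq(1L, total - P + 1L, by = stride)
    if (s[length(s)] != total - P + 1L) s <- c(s, total - P + 1L)
    s
  }
  tops <- starts(dm[1]); lefts <- starts(dm[2])
  C <- .imageChannels(image)
  grid <- expand.grid(left = lefts, top = tops)[, c("top", "left")]
  n <- nrow(grid)
  patches <- array(0, c(n, C, P, P))
  for (i in seq_len(n)) {
    win <- .cutWindow(image, grid$top[i], grid$left[i], P)
    patches[i, , , ] <- aperm(array(win, c(P, P, C)), c(3, 1, 2))
  }
  list(patches = patches, coords = grid)
}

#' Stitch tiled predictions back into an image
#'
#' Each pixel of the output is the mean of all window predictions covering
#' it.
#'
#' @param preds N x P x P (or N x 1 x P x P) array of per-window predictions.
#' @param coords the `coords` data.frame returned by [tileImage()].
#' @param H,W output image size.
#' @return H x W matrix of averaged predictions.
#' @export
reconstructFromPatches <- function(preds, coords, H, W) {
  dm <- dim(preds)
  if (length(dm) == 4L) {
    P <- dm[3]
    getw <- function(i) preds[i, 1, , ]
  } else {
    P <- dm[2]
    getw <- function(i) preds[i, , ]
  }
  acc <- matrix(0, H, W)
  cnt <- matrix(0, H, W)
  for (i in seq_len(nrow(coords))) {
    rs <- coords$top[i]:(coords$top[i] + P - 1L)
    cs <- coords$left[i]:(coords$left[i] + P - 1L)
    acc[rs, cs] <- acc[rs, cs] + getw(i)
    cnt[rs, cs] <- cnt[rs, cs] + 1
  }
  if (any(cnt == 0)) stop("uncovered pixels: coords do not tile the image")
  acc / cnt
}
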