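## Procedural generator of fundus-like images with pixel-exact vessel masks.
##
## Vessels grow as seeded random walks from root points near the FOV rim:
## each step advances a fixed length with a Gaussian heading perturbation and
## a slight calibre taper; side branches spawn with a per-step probability,
## inherit a fraction (0.6-0.9) of the parent calibre, and the walk stops when
## the calibre falls below one pixel or the tip reaches the FOV boundary.

.SEG_STEP <- 1.5        # growth step length, px
.TAPER <- 0.995         # per-step calibre taper
.MIN_WIDTH <- 1.0       # terminal calibre, px
.MAX_DEPTH <- 6L
.MAX_SEGMENTS <- 5000L
.STAMP_STEP <- 0.25     # disk-stamping interval along segments, px

#' Grow a synthetic vessel tree
#'
#' Deterministically (for a fixed seed) grows one branching tree per root
#' inside the field-of-view disk.
#'
#' @param params a [SynthParams-class].
#' @param seed integer seed; the same (params, seed) pair always returns the
#'   identical tree.
#' @return a [VesselTree-class].
#' @export
generateVesselTree <- function(params, seed = 1L) {
  stopifnot(is(params, "SynthParams"))
  validObject(params)
  if (params@imageSize < 32L)
    stop("imageSize must be at least 32 px for a meaningful vessel tree")
  withr::with_seed(as.integer(seed), .growTree(params))
}

.growTree <- function(params) {
  size <- params@imageSize
  ctr <- (size + 1) / 2
  R <- params@fovRadiusFrac * size
  segs <- vector("list", 512L)
  nseg <- 0L
  roots <- matrix(0, params@nRoots, 2, dimnames = list(NULL, c("x", "y")))

  pushSeg <- function(parent, x0, y0, x1, y1, width, depth) {
    nseg <<- nseg + 1L
    segs[[nseg]] <<- c(id = nseg, parent = parent, x0 = x0, y0 = y0,
                       x1 = x1, y1 = y1, width = width, depth = depth)
    nseg
  }

  ## active branches: list of c(x, y, heading, width, depth, parent)
  active <- list()
  for (r in seq_len(params@nRoots)) {
    theta <- runif(1, 0, 2 * pi)
    x <- ctr + 0.85 * R * cos(theta)
    y <- ctr + 0.85 * R * sin(theta)
    roots[r, ] <- c(x, y)
    heading <- theta + pi + rnorm(1, 0, 0.3)   # point roughly inward
    w0 <- runif(1, params@widthRange[1], params@widthRange[2])
    active[[length(active) + 1L]] <- c(x, y, heading, w0, 0, 0)
  }

  while (length(active) && nseg < .MAX_SEGMENTS) {
    br <- active[[length(active)]]
    active[[length(active)]] <- NULL
    x <- br[1]; y <- br[2]; heading <- br[3]; w <- br[4]
    depth <- as.integer(br[5]); parent <- as.integer(br[6])
    repeat {
      if (w < .MIN_WIDTH || nseg >= .MAX_SEGMENTS) break
      heading <- heading + rnorm(1, 0, params@tortuosity)
      nx <- x + .SEG_STEP * cos(heading)
      ny <- y + .SEG_STEP * sin(heading)
      if (sqrt((nx - ctr)^2 + (ny - ctr)^2) > R - w / 2 - 1) break
      nw <- w * .TAPER
      parent <- pushSeg(parent, x, y, nx, ny, nw, depth)
      x <- nx; y <- ny; w <- nw
      if (depth < .MAX_DEPTH && runif(1) < params@branchProb) {
        side <- sample(c(-1, 1), 1) * runif(1, 0.3, 0.8)
        cw <- w * runif(1, 0.6, 0.9)
        active[[length(active) + 1L]] <- c(x, y, heading + side, cw, depth + 1, parent)
      }
    }
  }

  df <- if (nseg) as.data.frame(do.call(rbind, segs[seq_len(nseg)]))
        else data.frame(id = numeric(), parent = numeric(), x0 = numeric(),
                        y0 = numeric(), x1 = numeric(), y1 = numeric(),
                        width = numeric(), depth = numeric())
  new("VesselTree", segments = df, roots = roots, imageSize = size)
}

## Exact rasterisation: a pixel is vessel iff its centre lies inside any of
## the disks of radius width/2 stamped at sub-pixel intervals along segments.
.rasterizeTree <- function(tree) {
  size <- tree@imageSize
  mask <- matrix(0, size, size)
  s <- tree@segments
  for (k in seq_len(nrow(s))) {
    x0 <- s$x0[k]; y0 <- s$y0[k]; x1 <- s$x1[k]; y1 <- s$y1[k]
    r <- s$width[k] / 2
    len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
    ts <- seq(0, 1, length.out = max(2L, ceiling(len / .STAMP_STEP) + 1L))
    for (t in ts) {
      cx <- x0 + t * (x1 - x0); cy <- y0 + t * (y1 - y0)
      rlo <- max(1L, ceiling(cy - r)); rhi <- min(size, floor(cy + r))
      clo <- max(1L, ceiling(cx - r)); chi <- min(size, floor(cx + r))
      if (rlo > rhi || clo > chi) next
      rows <- rlo:rhi; cols <- clo:chi
      d2 <- outer((rows - cy)^2, (cols - cx)^2, `+`)
      mask[rows, cols][d2 <= r^2] <- 1
    }
  }
  mask
}

.fovDisk <- function(size, frac) {
  ctr <- (size + 1) / 2
  R <- frac * size
  d2 <- outer((seq_len(size) - ctr)^2, (seq_len(size) - ctr)^2, `+`)
  (d2 <= R^2) * 1
}

## Separable Gaussian blur with replicate padding.
.gaussBlur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  rad <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-rad):rad)^2 / (2 * sigma^2))
  k <- k / sum(k)
  n <- length(k)
  blur1 <- function(x) {        # along rows of a matrix
    H <- nrow(x)
    idx <- outer(seq_len(H), (-rad):rad, `+`)
    idx[idx < 1L] <- 1L; idx[idx > H] <- H
    out <- matrix(0, H, ncol(x))
    for (j in seq_len(n)) out <- out + k[j] * x[idx[, j], , drop = FALSE]
    out
  }
  t(blur1(t(blur1(m))))
}

#' Render a vessel tree into a fundus-like sample
#'
#' The vessel mask is the exact rasterisation of the tree (before blur and
#' noise). The image is a textured background plus the signed vessel
#' contrast, Gaussian-blurred, noise-added, clipped to \eqn{[0,1]} and zeroed
#' outside the FOV disk.
#'
#' @param tree a [VesselTree-class] from [generateVesselTree()].
#' @param params the same [SynthParams-class] used to grow the tree.
#' @param seed integer seed for texture and noise.
#' @param sampleId identifier stored in the returned sample.
#' @return a [FundusSample-class].
#' @export
renderSample <- function(tree, params, seed = 1L, sampleId = "synthetic") {
  stopifnot(is(tree, "VesselTree"), is(params, "SynthParams"))
  if (tree@imageSize != params@imageSize)
    stop("tree and params disagree on imageSize")
  size <- params@imageSize
  fov <- .fovDisk(size, params@fovRadiusFrac)
  mask <- .rasterizeTree(tree)
  mask <- mask * fov                     # containment: vessels inside FOV
  img <- withr::with_seed(as.integer(seed), {
    bg <- matrix(0.55, size, size)
    if (params@noiseSd > 0) {            # low-frequency texture tied to noise
      tex <- .gaussBlur(matrix(rnorm(size * size), size, size), 8)
      tex <- tex / max(sd(tex), 1e-12) * 2 * params@noiseSd
      bg <- bg + tex
    }
    im <- bg + params@contrast * mask
    im <- .gaussBlur(im, params@blurSigma)
    if (params@noiseSd > 0) im <- im + matrix(rnorm(size * size, 0, params@noiseSd), size, size)
    im
  })
  img[img < 0] <- 0; img[img > 1] <- 1
  img <- img * fov
  if (params@channels == 3L) img <- array(rep(img, 3L), c(size, size, 3L))
  else img <- array(img, c(size, size))
  new("FundusSample", image = img, vesselMask = mask, fovMask = fov,
      sampleId = sampleId, source = "synthetic")
}

#' Generate a synthetic dataset
#'
#' Draws `n` samples with per-sample sub-seeds derived deterministically from
#' `seed`. When `outDir` is given, images and masks are written as PNG and a
#' tab-separated manifest is created; an existing manifest is never
#' overwritten unless `force = TRUE`.
#'
#' @param n number of samples (>= 1).
#' @param params a [SynthParams-class].
#' @param seed master seed; sample i uses sub-seed `seed + 9973 * i`.
#' @param outDir optional output directory.
#' @param force overwrite an existing manifest.
#' @return invisibly, a list of [FundusSample-class]; when writing to disk the
#'   manifest data.frame is attached as attribute `"manifest"`.
#' @export
generateDataset <- function(n, params = synthParams(), seed = 1L,
                            outDir = NULL, force = FALSE) {
  stopifnot(n >= 1)
  seed <- as.integer(seed)
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    si <- (seed + 9973L * i) %% .Machine$integer.max
    id <- sprintf("synth_%03d", i)
    tree <- generateVesselTree(params, si)
    samples[[i]] <- renderSample(tree, params, si + 1L, sampleId = id)
  }
  if (!is.null(outDir)) {
    manifestPath <- file.path(outDir, "manifest.tsv")
    if (file.exists(manifestPath) && !force)
      stop("manifest already exists at ", manifestPath, "; use force = TRUE to overwrite")
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    rows <- lapply(seq_len(n), function(i) {
      s <- samples[[i]]
      ip <- file.path(outDir, paste0(s@sampleId, "_image.png"))
      gp <- file.path(outDir, paste0(s@sampleId, "_gt.png"))
      fp <- file.path(outDir, paste0(s@sampleId, "_fov.png"))
      png::writePNG(s@image, ip)
      png::writePNG(s@vesselMask, gp)
      png::writePNG(s@fovMask, fp)
      data.frame(sampleId = s@sampleId, image = basename(ip), gt = basename(gp),
                 fov = basename(fp), split = "train", source = "synthetic",
                 seed = (seed + 9973L * i) %% .Machine$integer.max,
                 stringsAsFactors = FALSE)
    })
    manifest <- do.call(rbind, rows)
    utils::write.table(manifest, manifestPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    attr(samples, "manifest") <- manifest
  }
  invisible(samples)
}
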