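## Dataset ingestion: PNG / TIFF / PPM / JPEG readers, manifest handling and
## YAML run configuration. Orientation convention everywhere: row-major,
## origin top-left, (H, W) ordering.

## Minimal binary/ASCII PPM-PGM reader (P2/P3/P5/P6), returning [0,1].
.readPNM <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (!magic %in% c("P2", "P3", "P5", "P6"))
    stop("unsupported PNM magic '", magic, "' in ", path)
  vals <- integer(0)
  nums <- integer(3)      # width, height, maxval
  got <- 0L
  ## header tokens, skipping comments
  buf <- character(0)
  readToken <- function() {
    tok <- ""
    repeat {
      ch <- rawToChar(readBin(con, "raw", 1L))
      if (!length(ch) || !nzchar(ch)) stop("truncated PNM header in ", path)
      if (ch == "#") {
        repeat {
          ch <- rawToChar(readBin(con, "raw", 1L))
          if (ch == "\n") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (nzchar(tok)) return(tok) else next
      }
      tok <- paste0(tok, ch)
    }
  }
  while (got < 3L) {
    nums[got + 1L] <- as.integer(readToken())
    got <- got + 1L
  }
  w <- nums[1]; h <- nums[2]; maxval <- nums[3]
  channels <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- w * h * channels
  v <- if (magic %in% c("P5", "P6")) {
    if (maxval < 256) as.integer(readBin(con, "raw", n))
    else readBin(con, "integer", n, size = 2L, signed = FALSE, endian = "big")
  } else {
    rest <- rawToChar(readBin(con, "raw", file.size(path)))
    as.integer(strsplit(trimws(rest), "[[:space:]]+")[[1]])[seq_len(n)]
  }
  v <- v / maxval
  if (channels == 3L) {
    a <- array(0, c(h, w, 3L))
    for (c in 1:3) a[, , c] <- matrix(v[seq(c, n, by = 3L)], h, w, byrow = TRUE)
    a
  } else matrix(v, h, w, byrow = TRUE)
}

#' Read an image file to a [0,1] array
#'
#' Dispatches on the file extension: PNG and TIFF through the png and tiff
#' packages, PPM/PGM through a built-in reader, JPEG through EBImage when
#' available. The result is an H x W matrix or H x W x 3 array in
#' \eqn{[0,1]}, row-major with origin top-left.
#'
#' @param path image file path.
#' @return numeric array in [0, 1].
#' @export
readImageFile <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    ppm = , pgm = .readPNM(path),
    jpg = , jpeg = {
      if (!requireNamespace("EBImage", quietly = TRUE))
        stop("JPEG support needs the EBImage package")
      a <- EBImage::imageData(EBImage::readImage(path))
      ## EBImage stores (x, y[, c]); transpose to (row, col[, c])
      if (length(dim(a)) == 3L) aperm(a, c(2, 1, 3)) else t(a)
    },
    gif = stop("GIF is not supported by the installed readers; ",
               "convert to PNG first (e.g. with ImageMagick)"),
    stop("unsupported image format: .", ext))
  if (length(dim(img)) == 3L && dim(img)[3] == 4L) img <- img[, , 1:3]  # drop alpha
  if (length(dim(img)) == 3L && dim(img)[3] == 2L) img <- img[, , 1L]   # gray+alpha
  img
}

#' Load one fundus sample from image / ground-truth / FOV files
#'
#' The image is scaled to \eqn{[0,1]}; the ground truth is binarised at
#' mid-gray; a missing FOV yields an all-ones mask with a warning.
#'
#' @param imagePath path to the fundus image.
#' @param gtPath path to the manual vessel annotation.
#' @param fovPath optional path to the FOV mask.
#' @param sampleId identifier for the sample (default: image file name).
#' @param source provenance tag (one of synthetic, drive, chase, stare, user).
#' @return a [FundusSample-class].
#' @export
loadSample <- function(imagePath, gtPath, fovPath = NULL,
                       sampleId = basename(imagePath), source = "user") {
  img <- readImageFile(imagePath)
  gt <- readImageFile(gtPath)
  if (length(dim(gt)) == 3L) gt <- gt[, , 1]
  hw <- dim(img)[1:2]
  if (!identical(dim(gt), hw))
    stop(sprintf("ground truth size (%d x %d) does not match image (%d x %d)",
                 nrow(gt), ncol(gt), hw[1], hw[2]))
  gt <- (gt > 0.5) * 1
  if (is.null(fovPath)) {
    warning("no FOV mask for sample '", sampleId, "'; using an all-ones mask")
    fov <- matrix(1, hw[1], hw[2])
  } else {
    fov <- readImageFile(fovPath)
    if (length(dim(fov)) == 3L) fov <- fov[, , 1]
    if (!identical(dim(fov), hw)) stop("FOV mask size does not match image")
    fov <- (fov > 0.5) * 1
  }
  gt <- gt * fov                         # enforce vessel-in-FOV containment
  new("FundusSample", image = if (length(dim(img)) == 2L) array(img, hw) else img,
      vesselMask = gt, fovMask = fov, sampleId = sampleId, source = source)
}

#' Estimate a field-of-view mask from image intensities
#'
#' For datasets that ship no FOV masks: thresholds the intensity against the
#' dark border region and keeps the central connected structure (a simple
#' flood from the image centre over above-threshold pixels).
#'
#' @param image H x W (or H x W x 3) intensity array in [0,1].
#' @param quantileCut quantile of the corner intensity used as threshold.
#' @return binary H x W matrix, flagged with attribute `derived = TRUE`.
#' @export
estimateFov <- function(image, quantileCut = 0.95) {
  gray <- if (length(dim(image)) == 3L) apply(image, c(1, 2), mean) else image
  ## the four corner patches always lie outside the circular FOV
  b <- max(2L, min(nrow(gray), ncol(gray)) %/% 12L)
  rs <- nrow(gray); cs <- ncol(gray)
  corners <- c(gray[1:b, 1:b], gray[1:b, (cs - b + 1):cs],
               gray[(rs - b + 1):rs, 1:b], gray[(rs - b + 1):rs, (cs - b + 1):cs])
  thr <- stats::quantile(corners, quantileCut) + 0.02
  fov <- (gray > thr) * 1
  fov <- .gaussBlur(fov, 2) > 0.5
  structure(fov * 1, derived = TRUE)
}

## ---- manifests --------------------------------------------------------------

#' Read / write a dataset manifest
#'
#' A manifest is a tab-separated table with columns sampleId, image, gt,
#' fov (may be empty), split, source; paths are relative to the manifest's
#' directory.
#'
#' @param path manifest file path.
#' @return `readManifest` returns the manifest data.frame with unique sample
#'   ids; `loadManifestSamples` returns a list of [FundusSample-class].
#' @export
readManifest <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sampleId", "image", "gt")
  if (!all(need %in% names(m)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(m$sampleId)) stop("manifest sample ids must be unique")
  m
}

#' @rdname readManifest
#' @param manifest a manifest data.frame from [readManifest()].
#' @param baseDir directory paths are relative to.
#' @export
loadManifestSamples <- function(manifest, baseDir = ".") {
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    fov <- if (!is.null(row$fov) && !is.na(row$fov) && nzchar(row$fov))
      file.path(baseDir, row$fov) else NULL
    src <- if (!is.null(row$source) && row$source %in%
               c("synthetic", "drive", "chase", "stare", "user")) row$source else "user"
    loadSample(file.path(baseDir, row$image), file.path(baseDir, row$gt),
               fov, sampleId = row$sampleId, source = src)
  })
}

## ---- run configuration ------------------------------------------------------

.RUNCFG_KEYS <- list(
  network = c("variant", "inChannels", "baseWidth", "patchSize", "dilations",
              "attentionRatio"),
  train = c("lr", "weightDecay", "batchSize", "epochs", "seed", "checkpoint"),
  synth = c("imageSize", "nRoots", "branchProb", "widthRange", "tortuosity",
            "contrast", "noiseSd", "blurSigma", "fovRadiusFrac", "channels"),
  evaluate = c("threshold", "stride", "normalize", "fovRestrict"))

#' Load / save a YAML run configuration
#'
#' The configuration nests `network`, `train`, `synth` and `evaluate`
#' sections; unknown sections or keys are rejected so typos cannot silently
#' fall back to defaults. `saveRunConfig(loadRunConfig(p))` round-trips.
#'
#' @param path YAML file path.
#' @return named list of configuration sections.
#' @export
loadRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  bad <- setdiff(names(cfg), names(.RUNCFG_KEYS))
  if (length(bad)) stop("unknown config section(s): ", paste(bad, collapse = ", "))
  for (sec in names(cfg)) {
    badKey <- setdiff(names(cfg[[sec]]), .RUNCFG_KEYS[[sec]])
    if (length(badKey))
      stop("unknown key(s) in section '", sec, "': ", paste(badKey, collapse = ", "))
  }
  cfg
}

#' @rdname loadRunConfig
#' @param cfg configuration list as returned by [loadRunConfig()].
#' @export
saveRunConfig <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
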