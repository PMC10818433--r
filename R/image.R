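# Conversion of time-frequency matrices to viridis-mapped RGB rasters, the
# input format of the Vision Transformer classifier.

# Standard published 256-entry viridis lookup table (low -> high).
.viridis_hex <- c(
  "#440154", "#440256", "#450457", "#450559", "#46075A", "#46085C", "#460A5D", "#460B5E",
  "#470D60", "#470E61", "#471063", "#471164", "#471365", "#481467", "#481668", "#481769",
  "#48186A", "#481A6C", "#481B6D", "#481C6E", "#481D6F", "#481F70", "#482071", "#482173",
  "#482374", "#482475", "#482576", "#482677", "#482878", "#482979", "#472A7A", "#472C7A",
  "#472D7B", "#472E7C", "#472F7D", "#46307E", "#46327E", "#46337F", "#463480", "#453581",
  "#453781", "#453882", "#443983", "#443A83", "#443B84", "#433D84", "#433E85", "#423F85",
  "#424086", "#424186", "#414287", "#414487", "#404588", "#404688", "#3F4788", "#3F4889",
  "#3E4989", "#3E4A89", "#3E4C8A", "#3D4D8A", "#3D4E8A", "#3C4F8A", "#3C508B", "#3B518B",
  "#3B528B", "#3A538B", "#3A548C", "#39558C", "#39568C", "#38588C", "#38598C", "#375A8C",
  "#375B8D", "#365C8D", "#365D8D", "#355E8D", "#355F8D", "#34608D", "#34618D", "#33628D",
  "#33638D", "#32648E", "#32658E", "#31668E", "#31678E", "#31688E", "#30698E", "#306A8E",
  "#2F6B8E", "#2F6C8E", "#2E6D8E", "#2E6E8E", "#2E6F8E", "#2D708E", "#2D718E", "#2C718E",
  "#2C728E", "#2C738E", "#2B748E", "#2B758E", "#2A768E", "#2A778E", "#2A788E", "#29798E",
  "#297A8E", "#297B8E", "#287C8E", "#287D8E", "#277E8E", "#277F8E", "#27808E", "#26818E",
  "#26828E", "#26828E", "#25838E", "#25848E", "#25858E", "#24868E", "#24878E", "#23888E",
  "#23898E", "#238A8D", "#228B8D", "#228C8D", "#228D8D", "#218E8D", "#218F8D", "#21908D",
  "#21918C", "#20928C", "#20928C", "#20938C", "#1F948C", "#1F958B", "#1F968B", "#1F978B",
  "#1F988B", "#1F998A", "#1F9A8A", "#1E9B8A", "#1E9C89", "#1E9D89", "#1F9E89", "#1F9F88",
  "#1FA088", "#1FA188", "#1FA187", "#1FA287", "#20A386", "#20A486", "#21A585", "#21A685",
  "#22A785", "#22A884", "#23A983", "#24AA83", "#25AB82", "#25AC82", "#26AD81", "#27AD81",
  "#28AE80", "#29AF7F", "#2AB07F", "#2CB17E", "#2DB27D", "#2EB37C", "#2FB47C", "#31B57B",
  "#32B67A", "#34B679", "#35B779", "#37B878", "#38B977", "#3ABA76", "#3BBB75", "#3DBC74",
  "#3FBC73", "#40BD72", "#42BE71", "#44BF70", "#46C06F", "#48C16E", "#4AC16D", "#4CC26C",
  "#4EC36B", "#50C46A", "#52C569", "#54C568", "#56C667", "#58C765", "#5AC864", "#5CC863",
  "#5EC962", "#60CA60", "#63CB5F", "#65CB5E", "#67CC5C", "#69CD5B", "#6CCD5A", "#6ECE58",
  "#70CF57", "#73D056", "#75D054", "#77D153", "#7AD151", "#7CD250", "#7FD34E", "#81D34D",
  "#84D44B", "#86D549", "#89D548", "#8BD646", "#8ED645", "#90D743", "#93D741", "#95D840",
  "#98D83E", "#9BD93C", "#9DD93B", "#A0DA39", "#A2DA37", "#A5DB36", "#A8DB34", "#AADC32",
  "#ADDC30", "#B0DD2F", "#B2DD2D", "#B5DE2B", "#B8DE29", "#BADE28", "#BDDF26", "#C0DF25",
  "#C2DF23", "#C5E021", "#C8E020", "#CAE11F", "#CDE11D", "#D0E11C", "#D2E21B", "#D5E21A",
  "#D8E219", "#DAE319", "#DDE318", "#DFE318", "#E2E418", "#E5E419", "#E7E419", "#EAE51A",
  "#ECE51B", "#EFE51C", "#F1E51D", "#F4E61E", "#F6E620", "#F8E621", "#FBE723", "#FDE725"
)

#' Viridis colour gradient
#'
#' The published 256-entry viridis lookup table (blue -> green -> yellow),
#' optionally interpolated to `n` colours.
#'
#' @param n Number of colours (default 256).
#' @return Character vector of hex colours.
#' @export
viridis_colors <- function(n = 256) {
  if (n == 256) return(.viridis_hex)
  grDevices::colorRampPalette(.viridis_hex)(n)
}

#' Convert a time-frequency representation to a viridis RGB image
#'
#' Magnitude/energy matrices are mapped to decibels relative to the matrix
#' maximum with a floor at -80 dB; cepstral (already signed) matrices are
#' used as-is. The matrix is then resized to `height` x `width` (bilinear),
#' min-max normalized to \[0, 1\], and mapped through the viridis gradient,
#' with low frequencies at the bottom row of the image. An all-constant
#' matrix collapses to a uniform image at the colormap's lowest colour.
#'
#' The per-image dB + min-max normalization makes the output invariant to
#' positive rescaling of the input matrix.
#'
#' @param rep A [tfrep].
#' @param height,width Output raster size in pixels (default 224 x 224).
#' @return An object of class `feature_image`: list with `pixels`
#'   (`height` x `width` x 3 integer array, 0-255) and `source_scale`.
#' @export
to_image <- function(rep, height = 224, width = 224) {
  stopifnot(inherits(rep, "tfrep"))
  V <- rep$values
  if (length(V) == 0L) stop("empty time-frequency representation")
  if (rep$scale == "cepstral" || any(V < 0)) {
    D <- V
  } else {
    mx <- max(V)
    if (mx <= 0) {
      D <- matrix(-80, nrow(V), ncol(V))
    } else {
      D <- 10 * log10(V / mx)
      D[!is.finite(D) | D < -80] <- -80
    }
  }
  if (nrow(D) != height || ncol(D) != width)
    D <- EBImage::resize(D, w = height, h = width)
  rng <- range(D)
  N <- if (rng[2] > rng[1]) (D - rng[1]) / (rng[2] - rng[1]) else
    matrix(0, height, width)
  N[N < 0] <- 0; N[N > 1] <- 1
  idx <- as.integer(round(N * 255)) + 1L
  rgb <- t(grDevices::col2rgb(.viridis_hex))  # 256 x 3
  px <- array(0L, dim = c(height, width, 3L))
  flip <- height:1                            # low frequencies at the bottom
  for (ch in 1:3)
    px[, , ch] <- matrix(rgb[idx, ch], height, width)[flip, ]
  structure(list(pixels = px, source_scale = rep$scale),
            class = "feature_image")
}

#' @export
print.feature_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<feature_image> %d x %d x %d (%s source)\n",
              d[1], d[2], d[3], x$source_scale))
  invisible(x)
}

#' @export
plot.feature_image <- function(x, ...) {
  graphics::plot.new()
  graphics::rasterImage(x$pixels / 255, 0, 0, 1, 1, ...)
  invisible(x)
}

#' Write a feature image as 8-bit RGB PNG
#'
#' @param img A `feature_image`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_feature_image <- function(img, path) {
  stopifnot(inherits(img, "feature_image"))
  png::writePNG(img$pixels / 255, path)
  invisible(path)
}

#' Featurize respiratory cycles into classifier-ready images
#'
#' Applies one of the four time-frequency front-ends to each cycle and
#' converts the result to a viridis image. A manifest records cycle index,
#' patient and labels; with `dir` set, images are written as PNGs and the
#' manifest as `manifest.csv`.
#'
#' @param cycles List of [respiratory_cycle] objects.
#' @param tf Front-end: `"cochleogram"`, `"stft"`, `"mfcc"` or `"cqt"`.
#' @param height,width Image size in pixels (default 64, the desk-scale
#'   classifier profile).
#' @param dir Optional output directory for PNG export.
#' @param ... Passed to the front-end function.
#' @return List with `images` (list of `feature_image`) and `manifest`
#'   (data frame).
#' @export
featurize_cycles <- function(cycles,
                             tf = c("cochleogram", "stft", "mfcc", "cqt"),
                             height = 64, width = 64, dir = NULL, ...) {
  tf <- match.arg(tf)
  fs <- cycles[[1]]$rate
  bank <- if (tf == "cochleogram") gammatone_bank(fs) else NULL
  fe <- switch(tf,
    cochleogram = function(x) cochleogram(x, fs, bank = bank, ...),
    stft = function(x) stft(x, fs, ...),
    mfcc = function(x) mfcc(x, fs, ...),
    cqt = function(x) cqt(x, fs, ...))
  images <- vector("list", length(cycles))
  rows <- vector("list", length(cycles))
  for (i in seq_along(cycles)) {
    cy <- cycles[[i]]
    images[[i]] <- to_image(fe(cy$samples), height = height, width = width)
    path <- if (is.null(dir)) NA_character_ else
      file.path(dir, sprintf("cycle_%04d_%s.png", i, tf))
    rows[[i]] <- data.frame(cycle = i, patient_id = cy$patient_id,
                            label4 = cy$label4, crackle = cy$crackle,
                            wheeze = cy$wheeze, tf = tf, image = path)
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(images))
      write_feature_image(images[[i]], manifest$image[i])
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(images = images, manifest = manifest)
}
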