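#' Bolus image with region of interest
#'
#' Container for an RGB bolus photograph on a normalized `[0, 1]` intensity
#' scale together with a logical region-of-interest (ROI) mask. 8-bit
#' images must be divided by 255 before construction: all variance scores
#' in this package are on the normalized scale (a half-and-half binary
#' image has the maximal variance of 0.25).
#'
#' `origin` identifies the provenance of the bolus: either an in vivo
#' sample (`list(type = "in_vivo", subject = ..., group = "child"|"adult",
#' stage = 33|66|99)`) or an in vitro masticator sample
#' (`list(type = "in_vitro", n_compressions = ..., rotation_speed = ...)`).
#'
#' @param pixels H x W x 3 numeric array, intensities in `[0, 1]`.
#'   Row-major, origin top-left, channels ordered red, green, blue.
#' @param roi H x W logical matrix; defaults to the full frame.
#' @param origin Optional provenance list (see Details).
#' @param replicate Positive integer replicate index.
#' @return An object of class `bolus_image`.
#' @export
bolus_image <- function(pixels, roi = NULL, origin = NULL, replicate = 1L) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("pixels must be an H x W x 3 array", call. = FALSE)
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1)
    stop("pixel intensities must lie in [0, 1]; divide 8-bit images by 255",
         call. = FALSE)
  if (is.null(roi)) roi <- matrix(TRUE, nrow(pixels), ncol(pixels))
  if (!is.logical(roi) || !identical(dim(roi), dim(pixels)[1:2]))
    stop("roi must be an H x W logical matrix matching the image", call. = FALSE)
  if (!is.null(origin) && identical(origin$type, "in_vivo") &&
      !is.null(origin$stage) && !origin$stage %in% c(33, 66, 99))
    stop("in vivo stage must be one of 33, 66, 99", call. = FALSE)
  replicate <- as.integer(replicate)
  if (is.na(replicate) || replicate < 1L)
    stop("replicate must be a positive integer", call. = FALSE)
  structure(list(pixels = pixels, roi = roi, origin = origin,
                 replicate = replicate),
            class = "bolus_image")
}

#' @export
print.bolus_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("bolus_image: %d x %d px, ROI %d px (%.1f%%)\n",
              d[1], d[2], sum(x$roi), 100 * mean(x$roi)))
  invisible(x)
}

#' Chroma-key background specification
#'
#' Describes the coloured backdrop the boli are photographed on (green
#' paper by default). A pixel is classified as background when its HSV hue
#' lies within `hue_tol` of `hue` (circular distance, hue on `[0, 1)`) and
#' its saturation is at least `min_saturation` (the saturation floor keeps
#' near-grey sample pixels out of the key).
#'
#' @param hue Reference background hue in `[0, 1)`; 1/3 is pure green.
#' @param hue_tol Circular hue tolerance.
#' @param min_saturation Minimum saturation for a pixel to count as
#'   backdrop.
#' @return A list of class `chroma_key`.
#' @export
chroma_key <- function(hue = 1 / 3, hue_tol = 0.10, min_saturation = 0.25) {
  stopifnot(hue >= 0, hue < 1, hue_tol > 0, min_saturation >= 0)
  structure(list(hue = hue, hue_tol = hue_tol,
                 min_saturation = min_saturation),
            class = "chroma_key")
}

circular_hue_distance <- function(h, ref) {
  d <- abs(h - ref)
  pmin(d, 1 - d)
}

#' Extract the bolus region of interest from a raw photograph
#'
#' Segments the sample from its coloured backdrop in three deterministic
#' steps: (1) chroma-key classification in HSV space against the
#' `background` spec; (2) retention of the largest connected foreground
#' component (8-connectivity), which discards isolated specks; (3) optional
#' binary erosion by `erode_radius` pixels to trim the shadow fringe at the
#' sample boundary.
#'
#' @param pixels H x W x 3 array in `[0, 1]`, or a `bolus_image` whose
#'   mask is to be recomputed.
#' @param background A [chroma_key()] specification.
#' @param erode_radius Erosion radius in pixels (0 disables).
#' @param origin,replicate Passed to [bolus_image()].
#' @return A [bolus_image()] whose `roi` excludes the backdrop.
#' @export
extract_roi <- function(pixels, background = chroma_key(), erode_radius = 1L,
                        origin = NULL, replicate = 1L) {
  if (inherits(pixels, "bolus_image")) {
    if (is.null(origin)) origin <- pixels$origin
    replicate <- pixels$replicate
    pixels <- pixels$pixels
  }
  if (!inherits(background, "chroma_key"))
    stop("background must be a chroma_key() spec", call. = FALSE)
  img <- bolus_image(pixels, origin = origin, replicate = replicate)

  h <- nrow(pixels); w <- ncol(pixels)
  rgb <- rbind(as.vector(pixels[, , 1]), as.vector(pixels[, , 2]),
               as.vector(pixels[, , 3]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  is_bg <- circular_hue_distance(hsv["h", ], background$hue) <= background$hue_tol &
    hsv["s", ] >= background$min_saturation
  fg <- matrix(!is_bg, h, w)
  if (!any(fg))
    stop("empty ROI: every pixel was classified as background", call. = FALSE)

  labels <- EBImage::bwlabel(fg)
  counts <- tabulate(labels[labels > 0])
  keep <- which.max(counts)
  roi <- labels == keep

  if (erode_radius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(erode_radius) + 1L, shape = "disc")
    roi <- EBImage::erode(roi * 1, brush) > 0
    if (!any(roi))
      stop("empty ROI: erosion removed the whole foreground component",
           call. = FALSE)
  }
  img$roi <- matrix(as.logical(roi), h, w)
  img
}

channel_index <- function(channel) {
  idx <- match(match.arg(channel, c("red", "green", "blue")),
               c("red", "green", "blue"))
  idx
}

#' Bolus homogeneity score: within-ROI channel variance
#'
#' The homogeneity statistic is the population variance (divide by N, not
#' N - 1) of one channel's pixel intensities restricted to the ROI, on the
#' normalized `[0, 1]` scale. For a surface-coloured bolus the red channel
#' separates the coloured and uncoloured phases, so a higher variance means
#' a less mixed, more heterogeneous bolus; a fully mixed bolus tends to 0
#' and the theoretical maximum is 0.25.
#'
#' @param image A [bolus_image()] with a nonempty ROI.
#' @param channel One of `"red"`, `"green"`, `"blue"`.
#' @return A one-row data.frame of class `homogeneity_score` with columns
#'   `channel`, `variance`, `replicate` plus any origin fields.
#' @export
channel_variance <- function(image, channel = "red") {
  stopifnot(inherits(image, "bolus_image"))
  if (!any(image$roi))
    stop("empty ROI: cannot compute channel variance", call. = FALSE)
  idx <- channel_index(channel)
  vals <- image$pixels[, , idx][image$roi]
  v <- mean((vals - mean(vals))^2)  # population variance
  out <- data.frame(channel = c("red", "green", "blue")[idx], variance = v,
                    replicate = image$replicate, stringsAsFactors = FALSE)
  if (!is.null(image$origin)) {
    for (f in setdiff(names(image$origin), "type"))
      out[[f]] <- image$origin[[f]]
    out$origin <- image$origin$type
  }
  class(out) <- c("homogeneity_score", class(out))
  out
}

#' Select the channel that best separates groups
#'
#' Scores every image on each RGB channel and returns the channel whose
#' per-image variances give the largest one-way between-group F statistic
#' (the data-driven justification for scoring the red channel on a
#' purple-on-white coloured bolus). Ties are broken in the fixed order red,
#' green, blue. Degenerate channels with zero within-group variance but a
#' group difference score F = +Inf and win subject to the same tie-break.
#'
#' @param images List of [bolus_image()] objects.
#' @param group_labels Group factor, one label per image (>= 2 groups,
#'   >= 2 images per group).
#' @return The selected channel name, with attributes `F` (named vector of
#'   the three F statistics) and `scores` (per-image variance table).
#' @export
select_channel <- function(images, group_labels) {
  stopifnot(is.list(images), length(images) == length(group_labels))
  g <- factor(group_labels)
  if (nlevels(g) < 2L || any(table(g) < 2L))
    stop("need at least 2 groups with at least 2 images each", call. = FALSE)
  channels <- c("red", "green", "blue")
  vars <- sapply(channels, function(ch)
    vapply(images, function(im) channel_variance(im, ch)$variance, numeric(1)))
  fstat <- vapply(channels, function(ch)
    one_way_anova(vars[, ch], g)$F, numeric(1))
  sel <- channels[which.max(fstat)]  # which.max = first max: red > green > blue
  structure(sel, F = fstat,
            scores = data.frame(image = seq_along(images), group = g, vars))
}

#' Read an RGB image file as a normalized pixel array
#'
#' Reads PNG or TIFF via EBImage and returns an H x W x 3 array in
#' `[0, 1]` (greyscale images are replicated across channels; any alpha
#' channel is dropped).
#'
#' @param path Image file path.
#' @return H x W x 3 numeric array.
#' @export
read_bolus_raster <- function(path) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  # EBImage stores x (width) first; return rows = height for matrix-style use
  aperm(a, c(2, 1, 3))
}

#' Write a normalized pixel array to a PNG file
#'
#' @param pixels H x W x 3 array in `[0, 1]` or a `bolus_image`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_bolus_png <- function(pixels, path) {
  if (inherits(pixels, "bolus_image")) pixels <- pixels$pixels
  img <- EBImage::Image(aperm(pixels, c(2, 1, 3)), colormode = "Color")
  EBImage::writeImage(img, path, type = "png")
  invisible(path)
}

#' Score a set of bolus images into a tidy table
#'
#' @param images List of [bolus_image()] objects.
#' @param channel Channel to score (default red).
#' @return A tidy data.frame with one row per image: origin fields,
#'   replicate, channel and variance.
#' @export
score_images <- function(images, channel = "red") {
  rows <- lapply(images, channel_variance, channel = channel)
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    r[setdiff(all_cols, names(r))] <- NA
    r[all_cols]
  })
  do.call(rbind, rows)
}
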