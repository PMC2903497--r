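#' Morphometry configuration
#'
#' Collects every tunable of the image pipeline. Length parameters
#' (`blur_window`, `min_object_area`) are defined at the reference
#' resolution of 1280 x 1024 pixels (a 100x high-power field) and are
#' rescaled automatically when an image of another size is analyzed:
#' areas scale with the pixel-area ratio, window widths with its square
#' root.
#'
#' @param blur_window Odd width of the arithmetic mean filter, in pixels at
#'   the reference resolution (default 5).
#' @param shading_window Odd width of the illumination-estimation window for
#'   shading correction; `NULL` (default) means a quarter of the smaller
#'   image dimension, rounded to odd.
#' @param threshold_offset Signed grey-levels added to the automatic
#'   threshold; positive values admit more (brighter) pixels as fibre,
#'   mimicking the manual threshold adjustment used to compensate for
#'   staining intensity differences (default 0).
#' @param min_object_area Minimum object area in pixels at the reference
#'   resolution; smaller dark objects (cell nuclei) are discarded
#'   (default 200).
#' @param background_brightness Grey-level at or above which a pixel is
#'   treated as unstained background or vessel lumen (default 240).
#' @param connectivity Pixel connectivity for object detection, 4 or 8
#'   (default 8; collagen fibres are thin and often diagonally connected).
#' @return A `morphometry_config` object (a validated named list).
#' @examples
#' morphometry_config(threshold_offset = 10)
#' @export
morphometry_config <- function(blur_window = 5L,
                               shading_window = NULL,
                               threshold_offset = 0,
                               min_object_area = 200L,
                               background_brightness = 240,
                               connectivity = 8L) {
  check_window(blur_window, minimum = 1L, arg = "blur_window")
  if (!is.null(shading_window))
    check_window(shading_window, minimum = 3L, arg = "shading_window")
  if (!is.numeric(threshold_offset) || length(threshold_offset) != 1L)
    abort("threshold_offset must be a single number", "fibromat_bad_config")
  if (!is.numeric(min_object_area) || min_object_area < 0)
    abort("min_object_area must be >= 0", "fibromat_bad_config")
  if (!is.numeric(background_brightness) ||
      background_brightness < 0 || background_brightness > 255)
    abort("background_brightness must be in [0, 255]", "fibromat_bad_config")
  if (!connectivity %in% c(4L, 8L))
    abort("connectivity must be 4 or 8", "fibromat_bad_config")
  structure(list(blur_window = as.integer(blur_window),
                 shading_window = if (is.null(shading_window)) NULL
                                  else as.integer(shading_window),
                 threshold_offset = as.numeric(threshold_offset),
                 min_object_area = as.numeric(min_object_area),
                 background_brightness = as.numeric(background_brightness),
                 connectivity = as.integer(connectivity)),
            class = "morphometry_config")
}

#' @export
print.morphometry_config <- function(x, ...) {
  cat("<morphometry_config>\n")
  for (nm in names(x))
    cat(sprintf("  %-22s %s\n", nm,
                if (is.null(x[[nm]])) "auto (min(dim)/4)" else format(x[[nm]])))
  invisible(x)
}

check_window <- function(k, minimum, arg) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < minimum ||
      k != as.integer(k) || as.integer(k) %% 2L == 0L)
    abort(sprintf("%s must be an odd integer >= %d", arg, minimum),
          "fibromat_bad_config")
  invisible(k)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Green-channel grey transformation
#'
#' Sirius Red stains collagen fibres and nuclei red; red pigment absorbs
#' green light, so stained structures are dark in the green channel while
#' the pale yellowish hepatocellular cytoplasm stays bright. The grey image
#' is therefore the green channel alone: red and blue carry no signal for
#' this stain and are discarded.
#'
#' @param img An [rgb_image].
#' @return A numeric grey matrix in \[0, 255\].
#' @export
green_channel_grey <- function(img) {
  if (!is_rgb_image(img)) img <- rgb_image(img)
  m <- unclass(img)[, , 2]
  storage.mode(m) <- "double"
  m
}

# symmetric (edge-inclusive reflective) padding by r pixels on each side
pad_symmetric <- function(m, r) {
  if (r == 0L) return(m)
  n <- nrow(m); p <- ncol(m)
  if (r > n || r > p)
    abort("padding radius exceeds image dimensions", "fibromat_bad_config")
  m[c(r:1, 1:n, n:(n - r + 1L)), c(r:1, 1:p, p:(p - r + 1L)), drop = FALSE]
}

# k x k arithmetic-mean filter via a summed-area table; symmetric borders
box_mean <- function(m, k) {
  r <- (k - 1L) %/% 2L
  if (r == 0L) return(m)
  n <- nrow(m); p <- ncol(m)
  pd <- pad_symmetric(m, r)
  S <- matrix(0, n + 2L * r + 1L, p + 2L * r + 1L)
  S[-1L, -1L] <- apply(pd, 2L, cumsum)
  S[-1L, -1L] <- t(apply(S[-1L, -1L, drop = FALSE], 1L, cumsum))
  hi_r <- (2L * r + 2L):(n + 2L * r + 1L); lo_r <- 1:n
  hi_c <- (2L * r + 2L):(p + 2L * r + 1L); lo_c <- 1:p
  (S[hi_r, hi_c, drop = FALSE] - S[lo_r, hi_c, drop = FALSE] -
     S[hi_r, lo_c, drop = FALSE] + S[lo_r, lo_c, drop = FALSE]) / (k * k)
}

#' Shading correction
#'
#' Removes slowly varying illumination non-uniformity (vignetting, uneven
#' lamp field) by flat-field division: the illumination is estimated over a
#' large window, the image is divided by the estimate, and the result is
#' rescaled to preserve the original brightness level. Output is clamped
#' to \[0, 255\].
#'
#' Two estimators are available. `"mean"` uses the large-window arithmetic
#' mean and preserves the global mean intensity. `"median"` estimates the
#' illumination as a windowed median on a coarse grid and preserves the
#' global median; it is robust against bright structures (vessel lumina)
#' or dark structures (dense fibrosis) of a size comparable to the window,
#' which would bias an arithmetic-mean estimate and shift the corrected
#' brightness of exactly the structures the later pipeline stages must
#' classify. [analyze_field()] uses the median estimator.
#'
#' @param grey Numeric grey matrix.
#' @param shading_window Odd window width, at least 3 and at most the
#'   smaller image dimension.
#' @param method `"mean"` (default) or `"median"`, see Details.
#' @return Corrected grey matrix.
#' @export
correct_shading <- function(grey, shading_window, method = c("mean", "median")) {
  grey <- as_grey_matrix(grey)
  method <- match.arg(method)
  check_window(shading_window, minimum = 3L, arg = "shading_window")
  if (shading_window > min(dim(grey)))
    abort("shading_window exceeds the smaller image dimension",
          "fibromat_bad_config")
  if (method == "mean") {
    est <- pmax(box_mean(grey, as.integer(shading_window)), 1e-6)
    flat <- grey / est
    clamp255(flat * (mean(grey) / mean(flat)))
  } else {
    est <- pmax(median_surface(grey, as.integer(shading_window)), 1e-6)
    flat <- grey / est
    clamp255(flat * (stats::median(grey) / stats::median(flat)))
  }
}

# windowed median of the image, computed on a block-mean downsampled grid
# and upsampled by block replication; the illumination field is smooth, so
# the coarse grid loses nothing while making the median affordable
median_surface <- function(grey, window) {
  n <- nrow(grey); p <- ncol(grey)
  d <- max(1L, as.integer(round(window / 32)))
  if (d > 1L) {
    nb <- floor(n / d); pb <- floor(p / d)
    cropped <- grey[seq_len(nb * d), seq_len(pb * d), drop = FALSE]
    # block means: average d consecutive rows, then d consecutive columns
    rows <- rowsum(cropped, rep(seq_len(nb), each = d)) / d
    small <- t(rowsum(t(rows), rep(seq_len(pb), each = d))) / d
  } else {
    nb <- n; pb <- p
    small <- grey
  }
  wb <- round_odd(window / d, minimum = 3L)
  wb <- min(wb, round_odd(min(nb, pb), minimum = 1L))
  est_small <- .median_filter(small, wb)
  # replicate blocks back to full resolution
  est_small[pmin(ceiling(seq_len(n) / d), nb),
            pmin(ceiling(seq_len(p) / d), pb), drop = FALSE]
}

#' Arithmetic mean blur
#'
#' Replaces each pixel by the mean of its `blur_window` x `blur_window`
#' neighbourhood (symmetric border handling). A window of 1 is the
#' identity.
#'
#' @param grey Numeric grey matrix.
#' @param blur_window Odd positive window width in pixels.
#' @return Blurred grey matrix.
#' @export
mean_blur <- function(grey, blur_window) {
  grey <- as_grey_matrix(grey)
  check_window(blur_window, minimum = 1L, arg = "blur_window")
  box_mean(grey, as.integer(blur_window))
}

#' Background and lumen detection
#'
#' Unstained regions -- the slide background and the lumina of small
#' vessels -- transmit light freely and are near-white; they are excluded
#' from the parenchyma by a brightness cutoff on the grey image.
#'
#' @param grey Numeric grey matrix.
#' @param background_brightness Grey-level cutoff in \[0, 255\]; pixels with
#'   `grey >= cutoff` are background.
#' @return Logical mask, `TRUE` where background/lumen.
#' @export
background_mask <- function(grey, background_brightness = 240) {
  grey <- as_grey_matrix(grey)
  if (background_brightness < 0 || background_brightness > 255)
    abort("background_brightness must be in [0, 255]", "fibromat_bad_config")
  grey >= background_brightness
}

#' Automatic threshold by histogram analysis
#'
#' Computes the grey-level threshold separating stained (dark) from
#' unstained (bright) tissue by maximizing the between-class variance of
#' the grey-value histogram (Otsu's criterion), restricted to tissue
#' pixels so the bright background mode cannot dominate. The fibres are
#' the dark class: red-stained structures absorb green light. A signed
#' offset is added to reproduce manual threshold adjustment; the result is
#' clamped to \[0, 255\].
#'
#' With `refine = "midpoint"`, the Otsu cut only defines the two classes
#' and the returned threshold is placed halfway between their mean grey
#' values (the intermeans position). In a well-stained section the
#' stained and unstained modes are separated by a sparse histogram valley;
#' the raw between-class-variance argmax can sit anywhere across that
#' valley, whereas the intermeans position is stable and -- when the
#' threshold is later applied to a mean-filtered image -- cuts the blurred
#' fibre edge ramp at its half-way point, so edge smear cancels instead of
#' dilating or eroding every fibre.
#'
#' @param grey Numeric grey matrix.
#' @param tissue Logical tissue mask (non-background pixels).
#' @param threshold_offset Signed grey-levels added to the automatic value.
#' @param refine `"otsu"` (default) returns the between-class-variance
#'   argmax itself; `"midpoint"` returns the intermeans position of the
#'   Otsu classes.
#' @return A single threshold grey-level.
#' @export
histogram_threshold <- function(grey, tissue, threshold_offset = 0,
                                refine = c("otsu", "midpoint")) {
  grey <- as_grey_matrix(grey)
  refine <- match.arg(refine)
  check_mask(tissue, grey, "tissue")
  v <- round(grey[tissue])
  if (length(v) == 0L)
    abort("empty tissue mask: no pixels to threshold", "fibromat_no_tissue")
  h <- tabulate(as.integer(v) + 1L, nbins = 256L)
  if (sum(h > 0L) < 2L)
    abort("degenerate grey histogram: tissue has a single grey value",
          "fibromat_degenerate_histogram")
  t0 <- otsu_from_histogram(h)
  if (refine == "midpoint")
    t0 <- (mean(v[v <= t0]) + mean(v[v > t0])) / 2
  min(max(t0 + threshold_offset, 0), 255)
}

# between-class-variance maximization over all 255 cut points; the dark
# class is {0..t}. Empty bins between the modes make the criterion flat
# across the whole valley, so ties resolve to the middle of the
# maximizing plateau, centring the cut in the valley.
otsu_from_histogram <- function(h) {
  p <- h / sum(h)
  w1 <- cumsum(p)[1:255]
  mu <- cumsum(p * (0:255))
  sb <- (mu[256] * w1 - mu[1:255])^2 / (w1 * (1 - w1))
  sb[w1 <= 0 | w1 >= 1] <- -Inf
  plateau <- which(sb == max(sb))
  plateau[ceiling(length(plateau) / 2)] - 1L
}

#' Binarize the stained (dark) class
#'
#' @param grey Numeric grey matrix.
#' @param threshold Grey-level in \[0, 255\]; tissue pixels with
#'   `grey <= threshold` are positive.
#' @param tissue Logical tissue mask; background pixels are never positive.
#' @return Logical mask of stained pixels.
#' @export
binarize_dark <- function(grey, threshold, tissue) {
  grey <- as_grey_matrix(grey)
  check_mask(tissue, grey, "tissue")
  if (threshold < 0 || threshold > 255)
    abort("threshold must be in [0, 255]", "fibromat_bad_config")
  tissue & (grey <= threshold)
}

#' Binary object detection
#'
#' Labels every maximal connected set of positive pixels and records its
#' area and bounding box (1-based, inclusive).
#'
#' @param binary Logical mask.
#' @param connectivity 4 (edge-adjacent) or 8 (edge- or corner-adjacent).
#' @return A list with `labels` (integer matrix, 0 = unlabelled, objects
#'   numbered 1..K) and `records` (data frame: `label`, `area`, `row_min`,
#'   `row_max`, `col_min`, `col_max`).
#' @export
label_objects <- function(binary, connectivity = 8L) {
  check_mask(binary, arg = "binary")
  if (!connectivity %in% c(4L, 8L))
    abort("connectivity must be 4 or 8", "fibromat_bad_config")
  res <- .cc_label(binary, as.integer(connectivity))
  records <- data.frame(label = seq_along(res$area), area = res$area,
                        row_min = res$row_min, row_max = res$row_max,
                        col_min = res$col_min, col_max = res$col_max)
  list(labels = res$labels, records = records)
}

#' Remove small objects (nucleus filter)
#'
#' Nuclei take up the stain as strongly as collagen but are far smaller
#' than fibre structures, so objects with area strictly below
#' `min_object_area` are eliminated.
#'
#' @param labels Integer label matrix from [label_objects()].
#' @param records Object records from [label_objects()].
#' @param min_object_area Minimum area in pixels; objects with
#'   `area >= min_object_area` are kept.
#' @return Logical mask of the retained objects.
#' @export
filter_small_objects <- function(labels, records, min_object_area) {
  if (min_object_area < 0)
    abort("min_object_area must be >= 0", "fibromat_bad_config")
  keep <- records$label[records$area >= min_object_area]
  m <- matrix(labels %in% keep, nrow(labels), ncol(labels))
  m
}

#' Exclude objects or regions from a field
#'
#' Replaces the interactive click-to-exclude workflow: whole detected
#' objects (by label id) and/or arbitrary regions (by mask) are removed
#' from the fibre mask *and* from the parenchyma denominator, so excluding
#' a mistaken object never inflates the fibrosis index.
#'
#' @param fibres Logical fibre mask.
#' @param labels Integer label matrix the ids refer to.
#' @param exclude_ids Integer vector of object labels to exclude.
#' @param exclusion_mask Optional logical mask of regions to exclude.
#' @param tissue Optional tissue mask; excluded area is counted within it
#'   (excluding a background pixel removes nothing from the parenchyma).
#' @return List with `fibres` (pruned mask), `excluded_area` (pixels
#'   removed from the parenchyma) and `excluded` (the exclusion mask used).
#' @export
apply_exclusions <- function(fibres, labels, exclude_ids = integer(),
                             exclusion_mask = NULL, tissue = NULL) {
  check_mask(fibres, arg = "fibres")
  ex <- matrix(FALSE, nrow(fibres), ncol(fibres))
  if (length(exclude_ids)) {
    exclude_ids <- as.integer(exclude_ids)
    present <- unique(labels[labels > 0L])
    missing <- setdiff(exclude_ids, present)
    if (length(missing))
      abort(sprintf("unknown object id(s): %s",
                    paste(missing, collapse = ", ")),
            "fibromat_unknown_object")
    ex <- ex | matrix(labels %in% exclude_ids, nrow(fibres), ncol(fibres))
  }
  if (!is.null(exclusion_mask)) {
    check_mask(exclusion_mask, fibres, "exclusion_mask")
    ex <- ex | exclusion_mask
  }
  if (is.null(tissue)) tissue <- matrix(TRUE, nrow(fibres), ncol(fibres))
  list(fibres = fibres & !ex,
       excluded_area = sum(ex & tissue),
       excluded = ex)
}

#' Fibrosis index
#'
#' Fibre area as a fraction of the total parenchyma area (which includes
#' the fibre pixels themselves: fibres lie within the tissue section).
#'
#' @param fibre_area Fibre pixel count.
#' @param parenchyma_area Parenchyma pixel count (tissue after exclusions,
#'   fibres included).
#' @return Fraction in \[0, 1\].
#' @examples
#' fibrosis_index(4750, 100000)  # 4.75% fibrosis
#' @export
fibrosis_index <- function(fibre_area, parenchyma_area) {
  if (parenchyma_area <= 0)
    abort("no parenchyma: field is unanalyzable", "fibromat_no_tissue")
  if (fibre_area < 0 || fibre_area > parenchyma_area)
    abort("fibre_area must lie in [0, parenchyma_area]", "fibromat_bad_config")
  fibre_area / parenchyma_area
}

#' Render the classified field
#'
#' The verification display: background and excluded regions in black,
#' parenchyma in light green, fibres in intense red.
#'
#' @param tissue Logical parenchyma mask (fibres included).
#' @param fibres Logical fibre mask; must be a subset of `tissue`.
#' @return An [rgb_image] using exactly the palette black (0,0,0), light
#'   green (144,238,144), red (255,0,0).
#' @export
render_overlay <- function(tissue, fibres) {
  check_mask(tissue, arg = "tissue")
  check_mask(fibres, tissue, "fibres")
  if (any(fibres & !tissue))
    abort("fibre pixels outside the tissue mask", "fibromat_bad_image")
  pal <- rbind(black = c(0L, 0L, 0L),
               green = c(144L, 238L, 144L),
               red   = c(255L, 0L, 0L))
  cls <- matrix(1L, nrow(tissue), ncol(tissue))
  cls[tissue] <- 2L
  cls[fibres] <- 3L
  arr <- array(0L, dim = c(nrow(tissue), ncol(tissue), 3L))
  for (ch in 1:3) arr[, , ch] <- pal[cls, ch]
  rgb_image(arr)
}

new_field_result <- function(fibre_area, parenchyma_area, background_area,
                             excluded_area, threshold_used, width, height,
                             id = NULL) {
  stopifnot(fibre_area <= parenchyma_area,
            fibre_area + (parenchyma_area - fibre_area) +
              background_area + excluded_area == width * height)
  structure(list(id = id,
                 width = as.integer(width), height = as.integer(height),
                 fibre_area = as.integer(fibre_area),
                 parenchyma_area = as.integer(parenchyma_area),
                 background_area = as.integer(background_area),
                 excluded_area = as.integer(excluded_area),
                 threshold_used = as.numeric(threshold_used),
                 fibrosis_index = fibrosis_index(fibre_area, parenchyma_area)),
            class = "field_result")
}

#' @export
print.field_result <- function(x, ...) {
  cat(sprintf("<field_result%s %dx%d>\n",
              if (is.null(x$id)) "" else paste0(" ", x$id), x$width, x$height))
  cat(sprintf("  fibrosis index: %.4f (%.2f%%)\n",
              x$fibrosis_index, 100 * x$fibrosis_index))
  cat(sprintf("  fibre %d / parenchyma %d px; background %d; excluded %d; threshold %g\n",
              x$fibre_area, x$parenchyma_area, x$background_area,
              x$excluded_area, x$threshold_used))
  invisible(x)
}

#' Analyze one micrograph field
#'
#' Runs the full pipeline on a single field: green-channel grey
#' transformation, shading correction (median-based flat-fielding, see
#' [correct_shading()]), mean-filter blurring, automatic thresholding
#' (Otsu class split on the pre-filter grey-value distribution, cut placed
#' at the intermeans midpoint, see [histogram_threshold()]), binarization
#' of the dark (stained) class in the filtered image, connected-component
#' detection, elimination of nucleus-sized objects, optional exclusions,
#' and the fibrosis index. The threshold is estimated from the
#' distribution *before* the mean filter: the filter redistributes fibre
#' edge intensities into the histogram valley, which would drag an
#' automatic threshold toward the bright class and dilate every fibre by
#' about a pixel per side. Deterministic: the same image and
#' configuration always give a bit-identical result.
#'
#' @param img An [rgb_image] (or array coercible to one).
#' @param config A [morphometry_config()].
#' @param exclude_ids Object labels to exclude (ids refer to the labelling
#'   of the binarized image, as reported by `keep_masks = TRUE`).
#' @param exclusion_mask Optional logical mask of regions to exclude.
#' @param id Optional field identifier carried into results and errors.
#' @param keep_masks If `TRUE`, attach the tissue/fibre masks and label
#'   matrix to the result (for overlays and object review).
#' @return A `field_result` with pixel-area bookkeeping satisfying
#'   `fibre + (parenchyma - fibre) + background + excluded = width * height`.
#' @export
analyze_field <- function(img, config = morphometry_config(),
                          exclude_ids = integer(), exclusion_mask = NULL,
                          id = NULL, keep_masks = FALSE) {
  if (!is_rgb_image(img)) img <- rgb_image(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  if (!inherits(config, "morphometry_config"))
    abort("config must be a morphometry_config", "fibromat_bad_config")
  area_scale <- (w * h) / (1280 * 1024)

  grey <- green_channel_grey(img)
  sw <- config$shading_window %||% round_odd(min(h, w) / 4, minimum = 3L)
  greyc <- correct_shading(grey, sw, method = "median")
  bw <- round_odd(config$blur_window * sqrt(area_scale), minimum = 1L)
  blurred <- mean_blur(greyc, bw)
  bg <- background_mask(greyc, config$background_brightness)
  tissue <- !bg
  if (!any(tissue))
    abort(sprintf("field %s has no tissue (entirely background)",
                  id %||% "<unnamed>"), "fibromat_no_tissue")

  thr <- tryCatch(
    histogram_threshold(greyc, tissue, config$threshold_offset,
                        refine = "midpoint"),
    fibromat_degenerate_histogram = function(e)
      abort(sprintf("field %s: %s", id %||% "<unnamed>", conditionMessage(e)),
            "fibromat_degenerate_histogram"))
  binary <- binarize_dark(blurred, thr, tissue)
  lab <- label_objects(binary, config$connectivity)
  min_area <- config$min_object_area * area_scale
  fib <- filter_small_objects(lab$labels, lab$records, min_area)
  exc <- apply_exclusions(fib, lab$labels, exclude_ids, exclusion_mask, tissue)

  fibre_area <- sum(exc$fibres)
  excluded_area <- exc$excluded_area
  parenchyma_area <- sum(tissue) - excluded_area
  background_area <- sum(bg)
  if (parenchyma_area <= 0)
    abort(sprintf("field %s has no parenchyma after exclusions",
                  id %||% "<unnamed>"), "fibromat_no_tissue")
  res <- new_field_result(fibre_area, parenchyma_area, background_area,
                          excluded_area, thr, w, h, id = id)
  if (keep_masks) {
    res$masks <- list(tissue = tissue & !exc$excluded,
                      fibres = exc$fibres,
                      labels = lab$labels)
  }
  res
}
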