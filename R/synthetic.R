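#' Specification of a synthetic Sirius Red field
#'
#' Describes a synthetic stained micrograph with known ground truth. The
#' colour model follows the stain's appearance: collagen fibres and cell
#' nuclei red (low green intensity), hepatocellular cytoplasm pale
#' yellowish (high red and green), vessel lumina and background
#' near-white. Geometric parameters are given in pixels at the reference
#' resolution of 1280 x 1024 and scale with the square root of the pixel
#' area for other sizes, so the same specification renders the same scene
#' statistics at any resolution.
#'
#' @param collagen_fraction Target collagen fraction of the *tissue* area
#'   (lumina excluded), in \[0, 0.5\].
#' @param width,height Image size in pixels (default 1280 x 1024).
#' @param nucleus_density Nuclei per megapixel (default 150).
#' @param nucleus_radius Nucleus disc radius in reference pixels (default 5;
#'   nucleus area stays well below the default minimum object area).
#' @param lumen_count Number of bright vessel-lumen discs (default 6).
#' @param shading_amplitude Amplitude of the smooth multiplicative
#'   illumination field, in \[0, 0.5\] (default 0.15).
#' @param noise_sd Gaussian pixel noise standard deviation in grey-levels
#'   (default 3).
#' @param seed Integer seed; mandatory, so every field is reproducible.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(collagen_fraction, width = 1280L, height = 1024L,
                           nucleus_density = 150, nucleus_radius = 5,
                           lumen_count = 6L, shading_amplitude = 0.15,
                           noise_sd = 3, seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    abort("an explicit integer seed is required", "fibromat_bad_spec")
  if (!is.numeric(collagen_fraction) || collagen_fraction < 0 ||
      collagen_fraction > 0.5)
    abort("collagen_fraction must be in [0, 0.5]", "fibromat_bad_spec")
  if (shading_amplitude < 0 || shading_amplitude > 0.5)
    abort("shading_amplitude must be in [0, 0.5]", "fibromat_bad_spec")
  if (width < 32 || height < 32)
    abort("synthetic fields must be at least 32 x 32 pixels", "fibromat_bad_spec")
  if (nucleus_density < 0 || nucleus_radius <= 0 || lumen_count < 0 ||
      noise_sd < 0)
    abort("negative synthetic-field parameter", "fibromat_bad_spec")
  structure(list(width = as.integer(width), height = as.integer(height),
                 collagen_fraction = collagen_fraction,
                 nucleus_density = nucleus_density,
                 nucleus_radius = nucleus_radius,
                 lumen_count = as.integer(lumen_count),
                 shading_amplitude = shading_amplitude,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# disc pixel offsets (dr, dc) for radius r around a centre pixel
disc_offsets <- function(r) {
  ri <- ceiling(r)
  g <- expand.grid(dr = -ri:ri, dc = -ri:ri)
  g[g$dr^2 + g$dc^2 <= r^2, , drop = FALSE]
}

# mark disc pixels (clipped to the image) in linear index space
disc_indices <- function(cr, cc, offs, h, w) {
  r <- cr + offs$dr; c <- cc + offs$dc
  ok <- r >= 1 & r <= h & c >= 1 & c <= w
  (c[ok] - 1L) * h + r[ok]
}

# binary dilation by a (2m+1)-square structuring element, via box sums
dilate_box <- function(mask, m) {
  if (m <= 0) return(mask)
  box_mean(mask * 1, 2L * as.integer(m) + 1L) > 1e-12
}

# one curvilinear stroke: a smoothed random walk stamped with a disc of
# radius width/2; the walk stops at the first disallowed centre so a
# stroke is always one connected piece. Returns pixel linear indices in
# draw order (first occurrence), so a prefix is a connected partial stroke.
stroke_indices <- function(start_r, start_c, width_px, length_px, h, w,
                           allowed) {
  step <- max(1, width_px / 3)
  n_steps <- max(2L, ceiling(length_px / step))
  theta <- runif(1, 0, 2 * pi) + cumsum(rnorm(n_steps, 0, 0.12))
  r <- pmin(pmax(start_r + cumsum(c(0, step * sin(theta[-1]))), 1), h)
  c <- pmin(pmax(start_c + cumsum(c(0, step * cos(theta[-1]))), 1), w)
  ok <- allowed[cbind(round(r), round(c))]
  stop_at <- if (all(ok)) n_steps else which(!ok)[1] - 1L
  if (stop_at < 1L) return(integer())
  offs <- disc_offsets(width_px / 2)
  idx <- unlist(lapply(seq_len(stop_at), function(i)
    disc_indices(round(r[i]), round(c[i]), offs, h, w)))
  idx[!duplicated(idx)]
}

#' Generate a synthetic stained field
#'
#' Renders a field according to its [synthetic_spec()]: bright lumen
#' discs, red curvilinear fibre strokes added until the target tissue
#' collagen fraction is met (the final stroke is truncated, branching off
#' existing collagen so the truncated piece stays connected and above the
#' object-size filter), small nucleus discs kept clear of fibres and of
#' each other, Gaussian pixel noise, and an optional smooth multiplicative
#' shading field. Identical spec and seed give bit-identical output; the
#' caller's RNG state is untouched.
#'
#' @param spec A [synthetic_spec()].
#' @return A `synthetic_field`: list with `image` ([rgb_image]),
#'   disjoint truth masks `collagen_truth`, `nucleus_truth`, `lumen_truth`,
#'   `realized_fraction` (collagen pixels / tissue pixels) and `spec`.
#' @export
synthesize_field <- function(spec) {
  if (!inherits(spec, "synthetic_spec"))
    abort("spec must be a synthetic_spec", "fibromat_bad_spec")
  with_seed(spec$seed, render_field(spec))
}

render_field <- function(spec) {
  h <- spec$height; w <- spec$width
  s <- sqrt((w * h) / (1280 * 1024))

  # vessel lumina: bright discs excluded from tissue
  lumen <- matrix(FALSE, h, w)
  if (spec$lumen_count > 0) {
    for (i in seq_len(spec$lumen_count)) {
      rad <- runif(1, 30, 80) * s
      idx <- disc_indices(round(runif(1, 1, h)), round(runif(1, 1, w)),
                          disc_offsets(rad), h, w)
      lumen[idx] <- TRUE
    }
  }
  tissue <- !lumen
  tissue_px <- sum(tissue)
  target_px <- round(spec$collagen_fraction * tissue_px)

  # collagen strokes: keep clear of lumina so blur cannot mix the classes
  margin <- ceiling(6 * s)
  allowed <- tissue & !dilate_box(lumen, margin)
  allowed_idx <- which(allowed)
  if (target_px > 0 && length(allowed_idx) < 2 * target_px)
    abort("collagen target fraction unreachable in this field",
          "fibromat_bad_spec")

  collagen <- matrix(FALSE, h, w)
  collagen_idx <- integer()
  cur <- 0L
  empty_draws <- 0L
  while (cur < target_px) {
    need <- target_px - cur
    # once the deficit is smaller than a typical stroke, grow a branch off
    # the existing collagen: a truncated branch stays connected to its
    # parent object and cannot be lost to the object-size filter
    branch <- length(collagen_idx) > 0L && need < 2500 * s^2
    start <- if (branch) sample(collagen_idx, 1L) else sample(allowed_idx, 1L)
    sr <- ((start - 1L) %% h) + 1L
    sc <- ((start - 1L) %/% h) + 1L
    width_px <- runif(1, 4, 6) * s
    length_px <- runif(1, 150, 500) * s
    idx <- stroke_indices(sr, sc, width_px, length_px, h, w, allowed)
    idx <- idx[!collagen[idx]]
    overshoot_unanchored <- length(idx) > need && !branch &&
      length(collagen_idx) > 0L
    if (length(idx) == 0L || overshoot_unanchored) {
      empty_draws <- empty_draws + 1L
      if (empty_draws > 500L)
        abort("collagen target fraction unreachable in this field",
              "fibromat_bad_spec")
      next
    }
    if (length(idx) > need) idx <- idx[seq_len(need)]
    collagen[idx] <- TRUE
    collagen_idx <- c(collagen_idx, idx)
    cur <- cur + length(idx)
  }

  # nuclei: red discs below the area filter, separated from fibres,
  # lumina and each other
  nucleus <- matrix(FALSE, h, w)
  rn <- max(1, spec$nucleus_radius * s)
  n_nuc <- round(spec$nucleus_density * (w * h) / 1e6)
  if (n_nuc > 0) {
    clearance <- ceiling(rn + 3 * s + 1)
    blocked <- dilate_box(collagen | lumen, clearance)
    offs <- disc_offsets(rn)
    centres_r <- numeric(0); centres_c <- numeric(0)
    placed <- 0L; tries <- 0L
    min_gap2 <- (2 * rn + 3)^2
    while (placed < n_nuc && tries < 60L * n_nuc) {
      tries <- tries + 1L
      cr <- round(runif(1, 1 + rn, h - rn))
      cc <- round(runif(1, 1 + rn, w - rn))
      if (blocked[cr, cc]) next
      if (length(centres_r) &&
          min((centres_r - cr)^2 + (centres_c - cc)^2) < min_gap2) next
      nucleus[disc_indices(cr, cc, offs, h, w)] <- TRUE
      centres_r <- c(centres_r, cr); centres_c <- c(centres_c, cc)
      placed <- placed + 1L
    }
  }

  # render: palette + noise + multiplicative shading
  base <- list(r = matrix(230, h, w), g = matrix(200, h, w),
               b = matrix(140, h, w))
  paint <- function(ch, mask, value) { ch[mask] <- value; ch }
  base$r <- paint(paint(paint(base$r, collagen, 180), nucleus, 150), lumen, 252)
  base$g <- paint(paint(paint(base$g, collagen, 60), nucleus, 50), lumen, 252)
  base$b <- paint(paint(paint(base$b, collagen, 60), nucleus, 60), lumen, 252)

  shade <- if (spec$shading_amplitude > 0) {
    1 + spec$shading_amplitude * smooth_surface(h, w)
  } else {
    matrix(1, h, w)
  }
  arr <- array(0, dim = c(h, w, 3))
  for (i in 1:3) {
    ch <- base[[i]]
    if (spec$noise_sd > 0) ch <- ch + rnorm(h * w, 0, spec$noise_sd)
    arr[, , i] <- round(clamp255(ch * shade))
  }

  structure(list(image = rgb_image(arr),
                 collagen_truth = collagen,
                 nucleus_truth = nucleus,
                 lumen_truth = lumen,
                 realized_fraction = sum(collagen) / tissue_px,
                 spec = spec),
            class = "synthetic_field")
}

# smooth random surface: a few low-frequency cosine components, shifted
# to zero median (shading models spatial non-uniformity, not a change of
# overall exposure) and normalized to unit maximum amplitude
smooth_surface <- function(h, w) {
  u <- matrix(seq(0, 1, length.out = h), h, w)
  v <- matrix(seq(0, 1, length.out = w), h, w, byrow = TRUE)
  g <- matrix(0, h, w)
  for (i in 1:3) {
    a <- rnorm(1); fu <- runif(1, 0.3, 1.2); fv <- runif(1, 0.3, 1.2)
    ph <- runif(2, 0, 2 * pi)
    g <- g + a * cos(2 * pi * fu * u + ph[1]) * cos(2 * pi * fv * v + ph[2])
  }
  g <- g - stats::median(g)
  g / max(abs(g))
}

#' @export
print.synthetic_field <- function(x, ...) {
  cat(sprintf("<synthetic_field %dx%d planted %.4f realized %.4f seed %d>\n",
              x$spec$width, x$spec$height, x$spec$collagen_fraction,
              x$realized_fraction, x$spec$seed))
  invisible(x)
}

#' Generate a synthetic study cohort
#'
#' Emulates a grouped time-course design: each group has a target tissue
#' collagen fraction; per-animal fractions jitter multiplicatively around
#' the group target, and each animal gets several independent fields.
#' Fully deterministic under the master seed.
#'
#' @param groups Data frame with columns `label`, `n` (animals) and
#'   `collagen_fraction` (group target).
#' @param seed Master seed.
#' @param fields_per_sample Fields (micrographs) per animal (default 10,
#'   the usual sampling depth per liver).
#' @param jitter_sd Standard deviation of the per-animal log-normal
#'   jitter on the group fraction (default 0.1).
#' @param width,height,... Remaining arguments forwarded to
#'   [synthetic_spec()] for every field.
#' @return Nested list: per group, `label`, `collagen_fraction`, and
#'   `samples`, each with `sample_id`, `fraction` and a list of
#'   `synthetic_field`s.
#' @export
synthesize_cohort <- function(groups, seed, fields_per_sample = 10L,
                              jitter_sd = 0.1, width = 1280L, height = 1024L,
                              ...) {
  if (!is.data.frame(groups) ||
      !all(c("label", "n", "collagen_fraction") %in% names(groups)))
    abort("groups must have columns label, n, collagen_fraction",
          "fibromat_bad_spec")
  if (any(groups$n < 1)) abort("each group needs n >= 1", "fibromat_bad_spec")
  with_seed(seed, {
    lapply(seq_len(nrow(groups)), function(gi) {
      g <- groups[gi, ]
      samples <- lapply(seq_len(g$n), function(ai) {
        frac <- min(0.5, g$collagen_fraction * exp(rnorm(1, 0, jitter_sd)))
        fields <- lapply(seq_len(fields_per_sample), function(fi) {
          synthesize_field(synthetic_spec(
            collagen_fraction = frac, width = width, height = height,
            seed = sample.int(.Machine$integer.max, 1L), ...))
        })
        list(sample_id = sprintf("%s_a%02d", g$label, ai),
             fraction = frac, fields = fields)
      })
      list(label = as.character(g$label),
           collagen_fraction = g$collagen_fraction, samples = samples)
    })
  })
}

#' Write a synthetic field to disk
#'
#' Writes the rendered image and its three truth masks as PNG files.
#'
#' @param field A `synthetic_field`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_synthetic_field <- function(field, dir, prefix = "field") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(image = file.path(dir, paste0(prefix, ".png")),
             collagen = file.path(dir, paste0(prefix, "_collagen.png")),
             nucleus = file.path(dir, paste0(prefix, "_nucleus.png")),
             lumen = file.path(dir, paste0(prefix, "_lumen.png")))
  write_image(field$image, paths[["image"]])
  write_image(field$collagen_truth, paths[["collagen"]])
  write_image(field$nucleus_truth, paths[["nucleus"]])
  write_image(field$lumen_truth, paths[["lumen"]])
  invisible(paths)
}
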