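#' Working sessions
#'
#' A session records a batch analysis: the configuration, the list of
#' images (with content checksums, so a collaborator reopening the file
#' is warned if an image changed on disk), per-image exclusions, and the
#' results of the fields already analyzed. Sessions are versioned JSON
#' files (suggested extension `.fibromat.json`) and round-trip through
#' save/load losslessly, preserving entry order.
#'
#' @param config A [morphometry_config()].
#' @return `new_session()` returns an empty `fibromat_session`.
#' @export
new_session <- function(config = morphometry_config()) {
  if (!inherits(config, "morphometry_config"))
    abort("config must be a morphometry_config", "fibromat_bad_config")
  structure(list(version = "1.0",
                 created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                 modified = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                 config = config,
                 entries = list()),
            class = "fibromat_session")
}

#' @rdname new_session
#' @param session A `fibromat_session`.
#' @param image_path Path of the image to add.
#' @param exclude_ids Integer object ids to exclude for this image.
#' @param exclusion_mask_path Optional path of a mask image (nonzero =
#'   excluded).
#' @export
session_add <- function(session, image_path, exclude_ids = integer(),
                        exclusion_mask_path = NULL) {
  stopifnot(inherits(session, "fibromat_session"))
  if (!file.exists(image_path))
    abort(sprintf("image file not found: %s", image_path), "fibromat_io")
  session$entries[[length(session$entries) + 1L]] <-
    list(image = image_path,
         checksum = unname(tools::md5sum(image_path)),
         exclude_ids = as.integer(exclude_ids),
         exclusion_mask = exclusion_mask_path,
         result = NULL)
  session$modified <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  session
}

#' @rdname new_session
#' @details `session_analyze()` runs [analyze_field()] on every pending
#'   entry; entries whose image cannot be read or analyzed keep a `NULL`
#'   result and the error message is collected.
#' @return `session_analyze()` returns the session with results filled in
#'   and an attribute `errors` (named character vector, empty on full
#'   success).
#' @export
session_analyze <- function(session) {
  stopifnot(inherits(session, "fibromat_session"))
  errors <- character()
  for (i in seq_along(session$entries)) {
    e <- session$entries[[i]]
    if (!is.null(e$result)) next
    res <- tryCatch({
      img <- read_image(e$image)
      mask <- if (!is.null(e$exclusion_mask)) read_mask(e$exclusion_mask)
      analyze_field(img, session$config, exclude_ids = e$exclude_ids,
                    exclusion_mask = mask, id = basename(e$image))
    }, error = function(err) err)
    if (inherits(res, "error")) {
      errors[[e$image]] <- conditionMessage(res)
    } else {
      session$entries[[i]]$result <- res
    }
  }
  session$modified <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  attr(session, "errors") <- errors
  session
}

# single-channel exclusion mask: nonzero = excluded
read_mask <- function(path) {
  if (!file.exists(path))
    abort(sprintf("mask file not found: %s", path), "fibromat_io")
  x <- try_decode(png::readPNG(path), path)
  if (is.array(x) && length(dim(x)) == 3L) x <- x[, , 1]
  x > 0
}

#' Save or load a session
#'
#' @param session A `fibromat_session`.
#' @param path File path (suggested extension `.fibromat.json`).
#' @return `load_session()` returns the session; image checksums are
#'   re-verified and a mismatch (image modified since the session was
#'   saved) raises a warning naming the file.
#' @export
save_session <- function(session, path) {
  stopifnot(inherits(session, "fibromat_session"))
  ser <- unclass(session)
  ser$config <- unclass(ser$config)
  ser$entries <- lapply(ser$entries, function(e) {
    if (!is.null(e$result)) {
      r <- unclass(e$result)
      r$masks <- NULL                      # masks are derivable, not stored
      e$result <- r
    }
    e
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname save_session
#' @export
load_session <- function(path) {
  if (!file.exists(path))
    abort(sprintf("session file not found: %s", path), "fibromat_io")
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(raw$version) || !identical(raw$version, "1.0"))
    abort(sprintf("unsupported session version: %s",
                  raw$version %||% "<missing>"), "fibromat_session_version")
  cfg <- raw$config
  config <- morphometry_config(
    blur_window = cfg$blur_window,
    shading_window = cfg$shading_window,
    threshold_offset = cfg$threshold_offset,
    min_object_area = cfg$min_object_area,
    background_brightness = cfg$background_brightness,
    connectivity = cfg$connectivity)
  entries <- lapply(raw$entries, function(e) {
    out <- list(image = e$image,
                checksum = e$checksum,
                exclude_ids = as.integer(unlist(e$exclude_ids)),
                exclusion_mask = e$exclusion_mask,
                result = NULL)
    if (!is.null(e$result)) {
      r <- e$result
      out$result <- new_field_result(r$fibre_area, r$parenchyma_area,
                                     r$background_area, r$excluded_area,
                                     r$threshold_used, r$width, r$height,
                                     id = r$id)
    }
    out
  })
  for (e in entries) {
    if (file.exists(e$image)) {
      if (!identical(unname(tools::md5sum(e$image)), e$checksum))
        warn(sprintf("image changed since session was saved: %s", e$image),
             "fibromat_checksum_warning")
    } else {
      warn(sprintf("session image not found on disk: %s", e$image),
           "fibromat_checksum_warning")
    }
  }
  structure(list(version = raw$version, created = raw$created,
                 modified = raw$modified, config = config,
                 entries = entries),
            class = "fibromat_session")
}

#' @export
print.fibromat_session <- function(x, ...) {
  done <- sum(vapply(x$entries, function(e) !is.null(e$result), logical(1)))
  cat(sprintf("<fibromat_session v%s: %d entries (%d analyzed), modified %s>\n",
              x$version, length(x$entries), done, x$modified))
  invisible(x)
}

#' Export fibrosis indices to a text file
#'
#' Writes one tab-separated row per analyzed field with the index as a
#' fraction to 4 decimal places (the sham-level indices around 0.0013
#' need more than the two decimals a percentage display uses) plus the
#' pixel-area bookkeeping, ready for re-import into any statistics
#' package.
#'
#' @param results List of `field_result`s.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
export_indices <- function(results, path) {
  if (length(results) == 0L)
    abort("no results to export", "fibromat_io")
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    if (!inherits(r, "field_result"))
      abort("results must be field_result objects", "fibromat_io")
    data.frame(image = r$id %||% sprintf("field_%03d", i),
               fibrosis_index = sprintf("%.4f", r$fibrosis_index),
               fibre_px = r$fibre_area,
               parenchyma_px = r$parenchyma_area,
               background_px = r$background_area,
               excluded_px = r$excluded_area,
               stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname export_indices
#' @details `read_indices()` re-imports an exported TSV.
#' @export
read_indices <- function(path) {
  if (!file.exists(path))
    abort(sprintf("index file not found: %s", path), "fibromat_io")
  df <- read.delim(path)
  if (!"fibrosis_index" %in% names(df))
    abort("not an index export: fibrosis_index column missing", "fibromat_io")
  df$fibrosis_index <- as.numeric(df$fibrosis_index)
  df
}
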