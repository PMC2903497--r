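#' Two-tiered semi-quantitative fibrosis score
#'
#' Periportal fibrosis is staged 0--4 (no fibrosis, incomplete lamellae,
#' complete lamellae with or without beginning septa, portal--portal
#' septa, complete cirrhosis) and perisinusoidal fibrosis 0--2 (none,
#' fibres in under half of the perisinusoidal spaces, in over half), for
#' a maximum total of 6. Stages are ordinal categories: per-animal scores
#' are integers, and only group summaries may be real-valued means.
#'
#' @param periportal Integer stage 0--4.
#' @param perisinusoidal Integer stage 0--2.
#' @return A `fibrosis_score` with fields `periportal`, `perisinusoidal`
#'   and `total` (their sum).
#' @examples
#' fibrosis_score(2, 1)$total  # 3
#' @export
fibrosis_score <- function(periportal, perisinusoidal) {
  for (v in list(periportal, perisinusoidal))
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v != as.integer(v))
      abort("stages must be single integers", "fibromat_bad_score")
  if (periportal < 0 || periportal > 4)
    abort("periportal stage must be in 0..4", "fibromat_bad_score")
  if (perisinusoidal < 0 || perisinusoidal > 2)
    abort("perisinusoidal stage must be in 0..2", "fibromat_bad_score")
  structure(list(periportal = as.integer(periportal),
                 perisinusoidal = as.integer(perisinusoidal),
                 total = as.integer(periportal + perisinusoidal)),
            class = "fibrosis_score")
}

#' @export
print.fibrosis_score <- function(x, ...) {
  cat(sprintf("<fibrosis_score periportal %d + perisinusoidal %d = total %d>\n",
              x$periportal, x$perisinusoidal, x$total))
  invisible(x)
}

#' Aggregate the fields of one liver sample
#'
#' The sample's fibrosis index is the arithmetic mean of its field
#' indices. Ten random high-power fields per sample is the usual
#' sampling depth; other counts are allowed with a warning.
#'
#' @param fields List of `field_result`s (or a numeric vector of field
#'   indices).
#' @param sample_id Optional sample identifier.
#' @param score Optional [fibrosis_score()] for the same sample.
#' @return A `sample_result` with `sample_id`, `field_indices`,
#'   `sample_index`, `n_fields` and `score`.
#' @export
aggregate_sample <- function(fields, sample_id = NULL, score = NULL) {
  idx <- if (is.numeric(fields)) as.numeric(fields)
         else vapply(fields, function(f) {
           if (!inherits(f, "field_result"))
             abort("fields must be field_result objects or numeric indices",
                   "fibromat_bad_score")
           f$fibrosis_index
         }, numeric(1))
  if (length(idx) == 0L)
    abort("a sample needs at least one field", "fibromat_bad_score")
  if (length(idx) != 10L)
    warn(sprintf("sample %s has %d fields (10 expected)",
                 sample_id %||% "<unnamed>", length(idx)),
         "fibromat_field_count")
  if (!is.null(score) && !inherits(score, "fibrosis_score"))
    abort("score must be a fibrosis_score", "fibromat_bad_score")
  structure(list(sample_id = sample_id,
                 field_indices = idx,
                 sample_index = mean(idx),
                 n_fields = length(idx),
                 score = score),
            class = "sample_result")
}

#' @export
print.sample_result <- function(x, ...) {
  cat(sprintf("<sample_result%s index %.4f over %d fields%s>\n",
              if (is.null(x$sample_id)) "" else paste0(" ", x$sample_id),
              x$sample_index, x$n_fields,
              if (is.null(x$score)) "" else sprintf(", total score %d",
                                                    x$score$total)))
  invisible(x)
}

#' Group mean and standard error
#'
#' @param values Numeric vector (per-animal indices or scores).
#' @param label Group label (e.g. days after ligation).
#' @return A `group_summary` with `label`, `n`, `mean` and `sem`
#'   (standard deviation / sqrt(n); 0 with a warning for n = 1).
#' @examples
#' group_summary(c(1, 2, 3), "d7")  # mean 2, sem 0.577
#' @export
group_summary <- function(values, label = NULL) {
  if (length(values) == 0L)
    abort("group_summary needs at least one value", "fibromat_bad_score")
  sem <- if (length(values) == 1L) {
    warn("n = 1: standard error reported as 0", "fibromat_sem_n1")
    0
  } else sd(values) / sqrt(length(values))
  structure(list(label = label, n = length(values),
                 mean = mean(values), sem = sem),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary%s n=%d %.2f +/- %.2f>\n",
              if (is.null(x$label)) "" else paste0(" ", x$label),
              x$n, x$mean, x$sem))
  invisible(x)
}

#' Ordinary least-squares fit
#'
#' Simple linear regression of `y` on `x` with the coefficient of
#' determination.
#'
#' @param x,y Numeric vectors of equal length, at least 2 pairs.
#' @return A `regression_result` with `slope`, `intercept`, `r_squared`
#'   and `n`.
#' @examples
#' linear_fit(0:3, c(0, 1, 1, 2))  # slope 0.6, intercept 0.1, R^2 0.9
#' @export
linear_fit <- function(x, y) {
  if (length(x) != length(y))
    abort("x and y must have equal length", "fibromat_bad_score")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2L)
    abort("linear_fit needs at least 2 pairs", "fibromat_bad_score")
  if (sd(x) == 0)
    abort("x is constant: slope undefined", "fibromat_bad_score")
  fit <- lm(y ~ x)
  r2 <- if (sd(y) == 0) {
    warn("y is constant: R^2 reported as 0", "fibromat_constant_y")
    0
  } else {
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((y - mean(y))^2)
    1 - ss_res / ss_tot
  }
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2, n = length(x)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result y = %.4f x + %.4f, R^2 = %.3f, n = %d>\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Correlate semi-quantitative scores with the morphometric index
#'
#' Regresses the sample fibrosis index on each score dimension (total,
#' periportal, perisinusoidal), score on the x axis. Samples without a
#' score are dropped with a warning.
#'
#' @param samples List of `sample_result`s carrying scores.
#' @return List of three `regression_result`s: `total`, `periportal`,
#'   `perisinusoidal`.
#' @export
correlate_scores_with_index <- function(samples) {
  ok <- vapply(samples, function(s) !is.null(s$score), logical(1))
  if (any(!ok))
    warn(sprintf("%d sample(s) without a score dropped", sum(!ok)),
         "fibromat_missing_score")
  samples <- samples[ok]
  if (length(samples) < 2L)
    abort("fewer than 2 scored samples: correlation impossible",
          "fibromat_bad_score")
  idx <- vapply(samples, function(s) s$sample_index, numeric(1))
  dims <- c("total", "periportal", "perisinusoidal")
  setNames(lapply(dims, function(d) {
    linear_fit(vapply(samples, function(s) as.numeric(s$score[[d]]),
                      numeric(1)), idx)
  }), dims)
}

#' Read semi-quantitative scores from CSV/TSV
#'
#' Expects columns `sample_id`, `periportal`, `perisinusoidal`.
#'
#' @param path CSV (comma) or TSV (tab) file.
#' @return Data frame with validated integer stages and a `total` column.
#' @export
read_scores <- function(path) {
  if (!file.exists(path))
    abort(sprintf("scores file not found: %s", path), "fibromat_io")
  first <- readLines(path, n = 1L)
  df <- if (grepl("\t", first)) read.delim(path) else read.csv(path)
  need <- c("sample_id", "periportal", "perisinusoidal")
  if (!all(need %in% names(df)))
    abort(sprintf("scores file must have columns %s",
                  paste(need, collapse = ", ")), "fibromat_io")
  for (i in seq_len(nrow(df)))          # validates every row's ranges
    fibrosis_score(df$periportal[i], df$perisinusoidal[i])
  df$total <- df$periportal + df$perisinusoidal
  df
}

#' Group report table
#'
#' Summarizes a cohort as one row per group: n, fibrosis index (percent)
#' and the three score dimensions, each as "mean +/- SEM" to two
#' decimals.
#'
#' @param df Data frame with columns `group`, `index` (fraction per
#'   animal) and optionally `periportal`, `perisinusoidal`, `total`.
#' @return Data frame with formatted summary columns, one row per group
#'   in order of first appearance.
#' @export
group_report <- function(df) {
  if (!all(c("group", "index") %in% names(df)))
    abort("group_report needs columns group and index", "fibromat_bad_score")
  fmt <- function(v) {
    g <- suppressWarnings(group_summary(v))
    sprintf("%.2f ± %.2f", g$mean, g$sem)
  }
  groups <- unique(df$group)
  rows <- lapply(groups, function(g) {
    d <- df[df$group == g, , drop = FALSE]
    out <- data.frame(group = g, n = nrow(d),
                      fibrosis_index_pct = fmt(100 * d$index),
                      stringsAsFactors = FALSE)
    for (col in c("periportal", "perisinusoidal", "total"))
      if (col %in% names(d)) out[[col]] <- fmt(d[[col]])
    out
  })
  do.call(rbind, rows)
}
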