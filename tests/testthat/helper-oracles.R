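# Independent oracles and small fixture builders used across the suite.

# Brute-force flood-fill connected-component labelling. Scans column-major
# and fills each component completely on first encounter, so component
# numbering (order of first appearance) matches label_objects().
flood_label <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  labels <- matrix(0L, h, w); k <- 0L
  nb <- if (connectivity == 4) {
    cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  } else {
    cbind(rep(-1:1, times = 3), rep(-1:1, each = 3))[-5, , drop = FALSE]
  }
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (!mask[i, j] || labels[i, j] != 0L) next
    k <- k + 1L
    queue <- list(c(i, j)); labels[i, j] <- k
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (t in seq_len(nrow(nb))) {
        r <- p[1] + nb[t, 1]; c2 <- p[2] + nb[t, 2]
        if (r >= 1 && r <= h && c2 >= 1 && c2 <= w &&
            mask[r, c2] && labels[r, c2] == 0L) {
          labels[r, c2] <- k
          queue[[length(queue) + 1L]] <- c(r, c2)
        }
      }
    }
  }
  labels
}

# Exhaustive between-class-variance maximization; dark class = values
# <= t, ties resolved to the middle of the maximizing plateau.
otsu_brute <- function(values) {
  v <- round(values)
  sb <- rep(-Inf, 255)
  for (t in 0:254) {
    a <- v[v <= t]; b <- v[v > t]
    if (length(a) == 0L || length(b) == 0L) next
    w1 <- length(a) / length(v)
    sb[t + 1L] <- w1 * (1 - w1) * (mean(a) - mean(b))^2
  }
  plateau <- which(sb == max(sb))
  plateau[ceiling(length(plateau) / 2)] - 1L
}

# Brute-force k x k windowed mean with symmetric (edge-mirrored) borders.
box_mean_brute <- function(m, k) {
  r <- (k - 1L) %/% 2L
  n <- nrow(m); p <- ncol(m)
  ref <- function(i, n) ifelse(i < 1L, 1L - i, ifelse(i > n, 2L * n + 1L - i, i))
  out <- matrix(0, n, p)
  for (i in seq_len(n)) for (j in seq_len(p)) {
    acc <- 0
    for (di in -r:r) for (dj in -r:r)
      acc <- acc + m[ref(i + di, n), ref(j + dj, p)]
    out[i, j] <- acc / (k * k)
  }
  out
}

# Uniform-colour RGB image.
flat_rgb <- function(h, w, r, g, b) {
  arr <- array(0L, dim = c(h, w, 3))
  arr[, , 1] <- r; arr[, , 2] <- g; arr[, , 3] <- b
  rgb_image(arr)
}

# Small synthetic field used by fast unit tests (320 x 256 keeps every
# structure above the scaled object filter while running in well under a
# second).
small_field <- function(fraction, seed, ...) {
  synthesize_field(synthetic_spec(collagen_fraction = fraction,
                                  width = 320L, height = 256L,
                                  seed = seed, ...))
}

expect_no_failure <- function(status) expect_identical(as.integer(status), 0L)

withr_local_tempdir <- function(env = parent.frame()) {
  withr::local_tempdir(.local_envir = env)
}

# hand-assembled uncompressed 24-bit bottom-up BMP, independent of the
# package's reader
write_bmp_fixture <- function(path, arr) {
  h <- dim(arr)[1]; w <- dim(arr)[2]
  row_bytes <- as.integer(ceiling(3 * w / 4) * 4)
  u16 <- function(x) as.raw(c(x %% 256, x %/% 256))
  u32 <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                              (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
  px <- raw(0)
  for (r in h:1) {                      # rows stored bottom-up, BGR order
    rowb <- raw(0)
    for (c2 in seq_len(w))
      rowb <- c(rowb, as.raw(arr[r, c2, 3]), as.raw(arr[r, c2, 2]),
                as.raw(arr[r, c2, 1]))
    px <- c(px, rowb, raw(row_bytes - 3L * w))
  }
  hdr <- c(charToRaw("BM"), u32(54 + length(px)), raw(4), u32(54),
           u32(40), u32(w), u32(h), u16(1), u16(24), u32(0), u32(length(px)),
           u32(2835), u32(2835), u32(0), u32(0))
  writeBin(c(hdr, px), path)
  invisible(path)
}
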