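# Shared fixtures and independent oracles. The oracles implement the
# defining formulas directly (double loops, dense grid search, closed
# forms) and never call the code paths they check.

fixtureModels <- syntheticCalibrationModels()

# Brute-force gamma: for every reference pixel, the minimum over ALL
# measured pixels of sqrt(dist^2/DTA^2 + dDose^2/denom^2). Grids share
# shape and spacing.
gammaBrute <- function(ref, mea, spacing, ddPercent, dtaMm,
                       normalization = "global", thresholdPercent = 0) {
  d <- dim(ref)
  dmax <- max(ref)
  out <- matrix(NA_real_, d[1], d[2])
  rPos <- (seq_len(d[1]) - 1) * spacing[1]
  cPos <- (seq_len(d[2]) - 1) * spacing[2]
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    if (ref[i, j] < thresholdPercent / 100 * dmax) next
    denom <- switch(normalization,
                    global = ddPercent / 100 * dmax,
                    local = ddPercent / 100 * ref[i, j],
                    absolute = ddPercent)
    if (denom <= 0) next
    dist2 <- outer((rPos - rPos[i])^2, (cPos - cPos[j])^2, `+`)
    g2 <- dist2 / dtaMm^2 + (ref[i, j] - mea)^2 / denom^2
    out[i, j] <- sqrt(min(g2))
  }
  out
}

# Literal double-loop normalized cross-correlation (template mean global,
# window mean local).
nccBrute <- function(template, image) {
  n2 <- nrow(template); m2 <- ncol(template)
  nr <- nrow(image) - n2 + 1L; nc <- ncol(image) - m2 + 1L
  t0 <- template - mean(template)
  st2 <- sum(t0^2)
  out <- matrix(0, nr, nc)
  for (u in seq_len(nr)) for (v in seq_len(nc)) {
    w <- image[u:(u + n2 - 1L), v:(v + m2 - 1L)]
    w0 <- w - mean(w)
    den <- sqrt(st2 * sum(w0^2))
    out[u, v] <- if (den > 0) sum(t0 * w0) / den else 0
  }
  out
}

# Dense grid search of the multichannel objective for one pixel, written
# straight from the channel formulas (rational models, net transmittance).
# odf/odi: length-3 post/pre optical densities; returns the argmin of
# g(t) = sum_{i<j} (D_i - D_j)^2 over t in [0.5, 1.5].
gridSearchTmin <- function(odf, odi, models, step = 1e-4) {
  tg <- seq(0.5, 1.5, by = step)
  D <- sapply(1:3, function(k) {
    p <- models[[k]]@params
    r <- 10^(-odf[k] * tg) - 10^(-odi[k] * tg)
    p[1] * r / (1 - p[2] * r)
  })
  g <- (D[, 1] - D[, 2])^2 + (D[, 1] - D[, 3])^2 + (D[, 2] - D[, 3])^2
  tg[which.min(g)]
}

# Optical densities of one film channel, straight from the definition.
odOfChannel <- function(film, k) {
  pv <- filmPixels(film)[, , k]
  -log10(pmax(pv, 1) / (2^bitDepth(film) - 1))
}

# Deterministic RGB TIFF with resolution tags, written via Python tifffile
# (an independent writer; the R tiff library does not emit resolution tags).
# Pixel values are seq_len(n) %% 65536 reshaped row-major.
writeResolutionTiff <- function(path, rows, cols, dpi) {
  script <- sprintf(paste0(
    "import numpy as np, tifffile\n",
    "a = (np.arange(%d*%d*3, dtype=np.uint32) %% 65536).astype(np.uint16)",
    ".reshape(%d, %d, 3)\n",
    "tifffile.imwrite(r'%s', a, resolution=(%d, %d), compression=None)\n"),
    rows, cols, rows, cols, path, dpi, dpi)
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  status <- system2("python", sf, stdout = TRUE, stderr = TRUE)
  stopifnot(file.exists(path))
  invisible(path)
}

# Expected pixel values of writeResolutionTiff, in R's [row, col, channel]
# layout (tifffile writes row-major with channel fastest).
resolutionTiffPixels <- function(rows, cols) {
  v <- (seq_len(rows * cols * 3) - 1) %% 65536
  a <- array(v, c(3, cols, rows))      # channel, col, row (fastest first)
  aperm(a, c(3, 2, 1))
}
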