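# Internal numerical helpers shared across modules.

# Evaluate a function with a temporary RNG state seeded from `seed`,
# restoring the caller's state afterwards.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Bilinear sampling of matrix `m` at fractional (row, col) coordinates.
# Coordinates are 1-based; samples outside [1, nrow] x [1, ncol] return
# `fill` unless clamp = TRUE, in which case they are clamped to the edge.
bilinearSample <- function(m, rows, cols, fill = 0, clamp = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  if (clamp) {
    rows <- pmin(pmax(rows, 1), nr)
    cols <- pmin(pmax(cols, 1), nc)
  }
  inside <- rows >= 1 & rows <= nr & cols >= 1 & cols <= nc
  r <- pmin(pmax(rows, 1), nr)
  c <- pmin(pmax(cols, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); r0 <- pmax(r0, 1L)
  c0 <- pmin(floor(c), nc - 1L); c0 <- pmax(c0, 1L)
  fr <- r - r0
  fc <- c - c0
  i00 <- cbind(r0, c0)
  i10 <- cbind(r0 + 1L, c0)
  i01 <- cbind(r0, c0 + 1L)
  i11 <- cbind(r0 + 1L, c0 + 1L)
  v <- (1 - fr) * (1 - fc) * m[i00] + fr * (1 - fc) * m[i10] +
    (1 - fr) * fc * m[i01] + fr * fc * m[i11]
  if (!clamp) v[!inside] <- fill
  v
}

# Rotate a matrix by `angleDeg` about its center using bilinear
# interpolation. Output has the same shape; source samples falling outside
# the input are set to `fill`.
rotateBilinear <- function(m, angleDeg, fill = mean(edgeValues(m))) {
  if (angleDeg == 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  th <- angleDeg * pi / 180
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  ri <- matrix(seq_len(nr), nr, nc) - cr
  ci <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cc
  # inverse mapping: sample the source at the back-rotated coordinates
  sr <- cos(th) * ri - sin(th) * ci + cr
  sc <- sin(th) * ri + cos(th) * ci + cc
  matrix(bilinearSample(m, as.vector(sr), as.vector(sc), fill = fill), nr, nc)
}

edgeValues <- function(m) {
  c(m[1, ], m[nrow(m), ], m[, 1], m[, ncol(m)])
}

# Replicate-pad a matrix by `k` pixels on every side.
padReplicate <- function(m, k) {
  if (k == 0L) return(m)
  ri <- pmin(pmax(seq_len(nrow(m) + 2L * k) - k, 1L), nrow(m))
  ci <- pmin(pmax(seq_len(ncol(m) + 2L * k) - k, 1L), ncol(m))
  m[ri, ci, drop = FALSE]
}

# Local (window) sums over a size x size neighbourhood with replicate
# padding, via integral images. Exact for moderate dynamic ranges.
localSum <- function(m, size) {
  k <- (size - 1L) %/% 2L
  p <- padReplicate(m, k)
  s <- apply(apply(p, 2L, cumsum), 1L, cumsum)  # transposed integral image
  s <- t(s)
  s <- rbind(0, cbind(0, s))
  nr <- nrow(m); nc <- ncol(m)
  r1 <- seq_len(nr); c1 <- seq_len(nc)
  s[r1 + 2L * k + 1L, c1 + 2L * k + 1L, drop = FALSE] -
    s[r1, c1 + 2L * k + 1L, drop = FALSE] -
    s[r1 + 2L * k + 1L, c1, drop = FALSE] +
    s[r1, c1, drop = FALSE]
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
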