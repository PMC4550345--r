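# Independent oracles kept deliberately naive: they share no code with the
# implementation paths they check.

# 8-connected component labeling by explicit flood fill (queue-based).
floodFillLabels <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(i, j)); lab[i, j] <- nxt
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      for (di in -1:1) for (dj in -1:1) {
        ni <- p[1L] + di; nj <- p[2L] + dj
        if (ni >= 1L && ni <= h && nj >= 1L && nj <= w &&
            mask[ni, nj] && lab[ni, nj] == 0L) {
          lab[ni, nj] <- nxt
          queue[[length(queue) + 1L]] <- c(ni, nj)
        }
      }
    }
  }
  lab
}

# least squares by explicit normal equations (distinct from the qr path)
normalEquationsFit <- function(X, Y) {
  solve(t(X) %*% X, t(X) %*% Y)
}

affineOracle <- function(src, dst) {
  cf <- normalEquationsFit(cbind(src[, 1], src[, 2], 1), dst)
  c(cf[1, 1], cf[2, 1], cf[3, 1], cf[1, 2], cf[2, 2], cf[3, 2])
}

quadraticOracle <- function(src, dst) {
  x <- src[, 1]; y <- src[, 2]
  cf <- normalEquationsFit(cbind(1, x, y, x^2, x * y, y^2), dst)
  list(px = cf[, 1], py = cf[, 2])
}

# exhaustive full-grid membership scan for an ellipse on an h x w image
ellipseScanOracle <- function(center, semiAxes, h, w) {
  hits <- NULL
  for (py in 0:(h - 1)) for (px in 0:(w - 1)) {
    if (((px - center[1]) / semiAxes[1])^2 +
        ((py - center[2]) / semiAxes[2])^2 <= 1)
      hits <- rbind(hits, c(px, py))
  }
  hits
}

# sort-based median (even count: mean of the two middle values)
sortMedian <- function(v) {
  s <- sort(v); n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}
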