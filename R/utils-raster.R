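# Small raster utilities on plain numeric matrices (row = y, col = x,
# 0-based pixel centers). Kept internal and minimal so the pixel conventions
# match the morphometry contract exactly.

# separable Gaussian blur with edge renormalization
.gaussianBlur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  smooth1 <- function(n) {
    K <- matrix(0, n, n)
    for (d in -r:r) {
      i <- seq_len(n)
      j <- i + d
      ok <- j >= 1 & j <= n
      K[cbind(i[ok], j[ok])] <- k[d + r + 1]
    }
    K / rowSums(K)
  }
  smooth1(nrow(m)) %*% m %*% t(smooth1(ncol(m)))
}

# resize by sampling output pixel centers in input coordinates
.resizeMatrix <- function(m, rows, cols, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  H <- nrow(m); W <- ncol(m)
  if (H == rows && W == cols) return(m)
  sr <- (seq_len(rows) - 0.5) * H / rows - 0.5
  sc <- (seq_len(cols) - 0.5) * W / cols - 0.5
  if (method == "nearest") {
    ri <- pmin(pmax(round(sr), 0), H - 1) + 1
    ci <- pmin(pmax(round(sc), 0), W - 1) + 1
    return(m[ri, ci, drop = FALSE])
  }
  r0 <- pmin(pmax(floor(sr), 0), H - 1); r1 <- pmin(r0 + 1, H - 1)
  c0 <- pmin(pmax(floor(sc), 0), W - 1); c1 <- pmin(c0 + 1, W - 1)
  fr <- pmin(pmax(sr - r0, 0), 1); fc <- pmin(pmax(sc - c0, 0), 1)
  A <- m[r0 + 1, c0 + 1, drop = FALSE]; B <- m[r0 + 1, c1 + 1, drop = FALSE]
  C <- m[r1 + 1, c0 + 1, drop = FALSE]; D <- m[r1 + 1, c1 + 1, drop = FALSE]
  top <- A * (1 - rep(fc, each = rows)) + B * rep(fc, each = rows)
  bot <- C * (1 - rep(fc, each = rows)) + D * rep(fc, each = rows)
  top * (1 - fr) + bot * fr
}

# rotate about the image center by angleDeg (counter-clockwise in the
# row/col frame); inverse mapping with bilinear or nearest sampling
.rotateMatrix <- function(m, angleDeg, method = c("bilinear", "nearest"),
                          bg = 0) {
  method <- match.arg(method)
  H <- nrow(m); W <- ncol(m)
  th <- angleDeg * pi / 180
  cy <- (H - 1) / 2; cx <- (W - 1) / 2
  yo <- rep(seq_len(H) - 1 - cy, times = W)
  xo <- rep(seq_len(W) - 1 - cx, each = H)
  xs <- cos(th) * xo + sin(th) * yo + cx
  ys <- -sin(th) * xo + cos(th) * yo + cy
  out <- matrix(bg, H, W)
  if (method == "nearest") {
    ri <- round(ys); ci <- round(xs)
    ok <- ri >= 0 & ri <= H - 1 & ci >= 0 & ci <= W - 1
    out[ok] <- m[cbind(ri[ok] + 1, ci[ok] + 1)]
    return(out)
  }
  r0 <- floor(ys); c0 <- floor(xs)
  ok <- r0 >= 0 & r0 <= H - 2 & c0 >= 0 & c0 <= W - 2
  fr <- ys[ok] - r0[ok]; fc <- xs[ok] - c0[ok]
  i00 <- cbind(r0[ok] + 1, c0[ok] + 1); i01 <- cbind(r0[ok] + 1, c0[ok] + 2)
  i10 <- cbind(r0[ok] + 2, c0[ok] + 1); i11 <- cbind(r0[ok] + 2, c0[ok] + 2)
  out[ok] <- m[i00] * (1 - fr) * (1 - fc) + m[i01] * (1 - fr) * fc +
             m[i10] * fr * (1 - fc) + m[i11] * fr * fc
  out
}

# run expr under a fixed RNG seed, restoring the caller's RNG state after
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
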