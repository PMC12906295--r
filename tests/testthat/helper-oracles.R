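## Independent brute-force oracles used to validate the analysis paths.

## Minimax centre of a line set by exhaustive grid search.
## lines: data.frame with angleDeg (direction) and offsetMM (signed
## perpendicular offset along the left normal from the origin).
oracleChebyshev <- function(angleDeg, offsetMM, span = 3, step = 0.01,
                            center = c(0, 0)) {
  th <- angleDeg * pi / 180
  nx <- -sin(th); ny <- cos(th)
  cc <- nx * center[1] + ny * center[2] + offsetMM
  xs <- seq(center[1] - span, center[1] + span, by = step)
  ys <- seq(center[2] - span, center[2] + span, by = step)
  best <- list(r = Inf, p = c(NA, NA))
  for (y in ys) {
    # vectorised over x for speed
    d <- abs(outer(xs, nx) + matrix(y * ny + 0, length(xs), length(nx),
                                    byrow = TRUE) -
               matrix(cc, length(xs), length(nx), byrow = TRUE))
    mx <- apply(d, 1, max)
    i <- which.min(mx)
    if (mx[i] < best$r) best <- list(r = mx[i], p = c(xs[i], y))
  }
  best
}

## Max distance from a point to the same line set (shared residual form).
oracleMaxLineDist <- function(p, angleDeg, offsetMM, center = c(0, 0)) {
  th <- angleDeg * pi / 180
  nx <- -sin(th); ny <- cos(th)
  cc <- nx * center[1] + ny * center[2] + offsetMM
  max(abs(nx * p[1] + ny * p[2] - cc))
}

## Exhaustive 2-D gamma: per reference point, minimum over every node of the
## bilinearly resampled evaluation grid, no search-radius cap.
oracleGamma <- function(ref, ev, doseCritPct = 3, dtaMM = 3,
                        normalization = "global") {
  rco <- pixelCoords(ref); eco <- pixelCoords(ev)
  rv <- imageValues(ref); evv <- imageValues(ev)
  refMax <- max(rv)
  nsub <- max(1L, ceiling(pixelSpacing(ev) / (0.1 * dtaMM)))
  step <- pixelSpacing(ev) / nsub
  fx <- seq(min(eco$x), max(eco$x), by = step)
  fy <- seq(min(eco$y), max(eco$y), by = step)
  interp <- function(xq, yq) {
    ix <- findInterval(xq, eco$x, all.inside = TRUE)
    iy <- findInterval(yq, eco$y, all.inside = TRUE)
    x0 <- eco$x[ix]; x1 <- eco$x[ix + 1]
    y0 <- eco$y[iy]; y1 <- eco$y[iy + 1]
    tx <- (xq - x0) / (x1 - x0); ty <- (yq - y0) / (y1 - y0)
    evv[cbind(iy, ix)] * (1 - tx) * (1 - ty) +
      evv[cbind(iy, ix + 1)] * tx * (1 - ty) +
      evv[cbind(iy + 1, ix)] * (1 - tx) * ty +
      evv[cbind(iy + 1, ix + 1)] * tx * ty
  }
  fine <- outer(fy, fx, function(Y, X) interp(as.vector(X), as.vector(Y)))
  g <- matrix(NA_real_, nrow(rv), ncol(rv))
  for (i in seq_len(nrow(rv))) for (j in seq_len(ncol(rv))) {
    d0 <- rv[i, j]
    if (d0 < 0.1 * refMax) next
    crit <- if (normalization == "global") doseCritPct / 100 * refMax
            else doseCritPct / 100 * d0
    dd <- (fine - d0) / crit
    r2 <- outer((fy - rco$y[i])^2, (fx - rco$x[j])^2, `+`)
    g[i, j] <- sqrt(min(dd^2 + r2 / dtaMM^2))
  }
  g
}

## Exhaustive sliding-window mean maximum over all fully-contained windows.
oracleMaxWindowMean <- function(m, h, w) {
  best <- -Inf
  for (i in seq_len(nrow(m) - h + 1)) {
    for (j in seq_len(ncol(m) - w + 1)) {
      best <- max(best, mean(m[i:(i + h - 1), j:(j + w - 1)]))
    }
  }
  best
}

## Table data printed with the machine's acceptance results, used as inputs.
table4ShiftsMM <- list(
  g0   = c(0.3, 0.0, -0.5, 0.0, 0.3, -0.1, 0.2),
  g90  = c(0.2, 0.1, -0.4, 0.0, 0.3, 0.0, 0.5),
  g180 = c(0.1, 0.1, -0.5, 0.0, 0.3, -0.1, 0.3),
  g270 = c(0.3, 0.1, -0.4, 0.0, 0.2, -0.2, 0.1)
)

table7Factors <- data.frame(
  gantry = c(90, 140, 160, 180, 200, 220, 270),
  measured = c(1.001, 1.195, 1.152, 1.144, 1.157, 1.201, 0.998),
  tps = c(1, 1.197, 1.159, 1.155, 1.159, 1.197, 1),
  deviation = c(0.1, -0.2, -0.6, -1.0, -0.2, 0.3, -0.2)
)
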