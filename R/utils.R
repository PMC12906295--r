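## Internal numeric primitives shared across analyses.

## All positions where a piecewise-linear curve crosses `level`, by linear
## interpolation between adjacent samples.  Exact hits are reported once.
.crossings <- function(x, y, level) {
  d <- y - level
  out <- numeric(0)
  n <- length(x)
  for (i in seq_len(n - 1)) {
    a <- d[i]; b <- d[i + 1]
    if (a == 0) out <- c(out, x[i])
    if ((a < 0 && b > 0) || (a > 0 && b < 0)) {
      out <- c(out, x[i] + (x[i + 1] - x[i]) * (-a) / (b - a))
    }
  }
  if (d[n] == 0) out <- c(out, x[n])
  unique(out)
}

## Width at a given level of a single-lobe curve: distance between the first
## rising and last falling crossing.  Errors if the curve does not cross the
## level exactly twice (multi-lobe or degenerate input).
.levelWidth <- function(x, y, level, what = "profile") {
  cr <- .crossings(x, y, level)
  if (length(cr) != 2) {
    stop(sprintf("%s crosses the level %.4g %d times (expected 2)",
                 what, level, length(cr)), call. = FALSE)
  }
  sort(cr)
}

## Sub-sample peak location by a 3-point parabola through the maximum and its
## neighbours; falls back to the grid maximum at the boundary or on a flat top.
.parabolicPeak <- function(x, y) {
  i <- which.max(y)
  if (i == 1 || i == length(y)) return(x[i])
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (denom >= 0) return(x[i])
  delta <- 0.5 * (y[i - 1] - y[i + 1]) / denom
  x[i] + delta * (x[i + 1] - x[i])
}

## Mean of every fully-contained h x w pixel window of `m` via an integral
## image (summed-area table).  Returns a (nrow-h+1) x (ncol-w+1) matrix of
## window means; partial windows are excluded.
.windowMeans <- function(m, h, w) {
  nr <- nrow(m); nc <- ncol(m)
  if (h > nr || w > nc) stop("window exceeds image bounds", call. = FALSE)
  S <- matrix(0, nr + 1, nc + 1)
  S[-1, -1] <- apply(apply(m, 2, cumsum), 1, cumsum) |> t()
  i <- seq_len(nr - h + 1)
  j <- seq_len(nc - w + 1)
  sums <- S[i + h, j + w, drop = FALSE] - S[i, j + w, drop = FALSE] -
    S[i + h, j, drop = FALSE] + S[i, j, drop = FALSE]
  sums / (h * w)
}

## Bilinear interpolation of matrix `m` (grid xg: cols, yg: rows) at arbitrary
## points; points outside the grid return `fill`.
.bilinear <- function(m, xg, yg, xq, yq, fill = NA_real_) {
  nx <- length(xg); ny <- length(yg)
  fx <- (xq - xg[1]) / (xg[nx] - xg[1]) * (nx - 1) + 1
  fy <- (yq - yg[1]) / (yg[ny] - yg[1]) * (ny - 1) + 1
  out <- rep(fill, length(xq))
  ok <- fx >= 1 & fx <= nx & fy >= 1 & fy <= ny
  fx <- fx[ok]; fy <- fy[ok]
  i0 <- pmin(floor(fy), ny - 1); j0 <- pmin(floor(fx), nx - 1)
  dy <- fy - i0; dx <- fx - j0
  v <- m[cbind(i0, j0)] * (1 - dx) * (1 - dy) +
    m[cbind(i0, j0 + 1)] * dx * (1 - dy) +
    m[cbind(i0 + 1, j0)] * (1 - dx) * dy +
    m[cbind(i0 + 1, j0 + 1)] * dx * dy
  out[ok] <- v
  out
}

## Local RNG scope: runs `expr` with a seed without disturbing global state.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
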