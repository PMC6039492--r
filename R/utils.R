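## Internal numerical helpers.

## Boxcar (moving-average) pooling of a matrix over a w x w window via summed
## area tables; pixels whose window leaves the matrix are NA. w = 1 is a no-op.
boxcarPool <- function(m, w) {
  w <- as.integer(w)
  if (w <= 1L) return(m)
  if (w %% 2L == 0L) stop("pooling window must be odd")
  H <- nrow(m); W <- ncol(m)
  if (w > H || w > W) stop("pooling window exceeds the map")
  r <- (w - 1L) %/% 2L
  cs <- rbind(0, apply(m, 2, cumsum))
  cs <- cbind(0, t(apply(cs, 1, cumsum)))
  i <- (r + 1L):(H - r); j <- (r + 1L):(W - r)
  out <- matrix(NA_real_, H, W)
  out[i, j] <- (cs[i + r + 1L, j + r + 1L, drop = FALSE] -
                cs[i - r, j + r + 1L, drop = FALSE] -
                cs[i + r + 1L, j - r, drop = FALSE] +
                cs[i - r, j - r, drop = FALSE]) / (w * w)
  out
}

## Connected-component labeling of a logical matrix (4- or 8-connectivity),
## iterative flood fill. Returns an integer matrix, 0 = background.
labelComponents <- function(mask, connectivity = 8) {
  stopifnot(is.logical(mask), connectivity %in% c(4, 8))
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  di <- c(-1L, 1L, 0L, 0L); dj <- c(0L, 0L, -1L, 1L)
  if (connectivity == 8) {
    di <- c(di, -1L, -1L, 1L, 1L); dj <- c(dj, -1L, 1L, -1L, 1L)
  }
  nextLab <- 0L
  idx <- which(mask)
  for (p in idx) {
    if (lab[p] != 0L) next
    nextLab <- nextLab + 1L
    stack <- p
    lab[p] <- nextLab
    while (length(stack)) {
      q <- stack[length(stack)]
      stack <- stack[-length(stack)]
      qi <- ((q - 1L) %% H) + 1L
      qj <- ((q - 1L) %/% H) + 1L
      ni <- qi + di; nj <- qj + dj
      ok <- ni >= 1L & ni <= H & nj >= 1L & nj <= W
      nidx <- (nj[ok] - 1L) * H + ni[ok]
      nidx <- nidx[mask[nidx] & lab[nidx] == 0L]
      if (length(nidx)) {
        lab[nidx] <- nextLab
        stack <- c(stack, nidx)
      }
    }
  }
  lab
}

## Run an expression with a local RNG seed, restoring the caller's RNG state.
withLocalSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

## Unnormalised log-normal curve parameterised by mode m and log-space SD sig:
##   g(x) = A exp(-(ln x - (ln m + sig^2))^2 / (2 sig^2)) / x,   x > 0.
## Its analytic integral over (0, Inf) is A * sig * sqrt(2*pi).
lognormalCurve <- function(x, amplitude, mode, shape) {
  mu <- log(mode) + shape^2
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- amplitude *
    exp(-(log(x[pos]) - mu)^2 / (2 * shape^2)) / x[pos]
  out
}

lognormalArea <- function(amplitude, shape) amplitude * shape * sqrt(2 * pi)
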