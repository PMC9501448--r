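# Run code under a fixed RNG seed, restoring global RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

# Block-mean / block-sum downsampling by an integer factor per axis.
block_reduce <- function(a, factor, op = c("mean", "sum")) {
  op <- match.arg(op)
  f <- as.integer(factor)
  if (f == 1L) return(a)
  d <- dim(a)
  if (any(d %% f != 0L))
    stop("grid not divisible by downsample factor ", f)
  dim(a) <- c(f, d[1] / f, f, d[2] / f, f, d[3] / f)
  a <- aperm(a, c(1, 3, 5, 2, 4, 6))
  dim(a) <- c(f^3, prod(d) / f^3)
  out <- if (op == "mean") colMeans(a) else colSums(a)
  dim(out) <- d / f
  out
}

# Integer roll of a 3-D array with constant fill (no wrap-around).
roll_int <- function(a, shift, fill = 0) {
  shift <- as.integer(round(shift))
  if (all(shift == 0L)) return(a)
  d <- dim(a)
  out <- array(fill, dim = d)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    s <- shift[ax]
    if (abs(s) >= d[ax]) return(out)
    if (s >= 0) { src[[ax]] <- 1:(d[ax] - s); dst[[ax]] <- (1 + s):d[ax] }
    else        { src[[ax]] <- (1 - s):d[ax]; dst[[ax]] <- 1:(d[ax] + s) }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Broadcast a per-slice vector (length n3) over an n1 x n2 x n3 array.
slice_profile_array <- function(profile, d) {
  array(rep(profile, each = d[1] * d[2]), dim = d)
}
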