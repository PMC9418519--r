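# internal helpers: axis mapping, deterministic seeding, array shifts

axisIndex <- function(axis) {
  i <- match(axis, c("y", "x", "z"))
  if (is.na(i)) stop("axis must be one of 'y', 'x', 'z'", call. = FALSE)
  i
}

# run code under a local RNG stream so generators are pure functions of seed
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed %% 2147483647))
  }
  force(code)
}

# derive a per-stage seed from a global one (kept below 2^31)
deriveSeed <- function(seed, stage) {
  s <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 48271 + s) %% 2147483587)
}

# pad a logical array with `value` on all sides
pad3 <- function(a, n = 1L, value = FALSE) {
  d <- dim(a)
  out <- array(value, d + 2L * n)
  out[n + seq_len(d[1]), n + seq_len(d[2]), n + seq_len(d[3])] <- a
  out
}

# overlapping index windows of array `a` for lattice offset v = (dy, dx, dz):
# returns list(A, B) with B the voxel at +v relative to A
shiftPair <- function(a, v) {
  d <- dim(a)
  ix <- function(n, s) if (s >= 0) seq_len(n - s) else (1 - s):n
  i1 <- ix(d[1], v[1]); j1 <- ix(d[2], v[2]); k1 <- ix(d[3], v[3])
  i2 <- i1 + v[1]; j2 <- j1 + v[2]; k2 <- k1 + v[3]
  list(A = a[i1, j1, k1, drop = FALSE], B = a[i2, j2, k2, drop = FALSE])
}

# number of positions where the phase changes along offset v (padded array)
countDiff <- function(p, v) {
  s <- shiftPair(p, v)
  sum(s$A != s$B)
}

# number of lattice cells (defined by the offset set) touched by foreground
countAnyOf <- function(p, offsets) {
  d <- dim(p)
  lo <- pmin(0L, Reduce(pmin, lapply(offsets, function(v) as.integer(v))))
  hi <- pmax(0L, Reduce(pmax, lapply(offsets, function(v) as.integer(v))))
  n1 <- d[1] - (hi[1] - lo[1]); n2 <- d[2] - (hi[2] - lo[2])
  n3 <- d[3] - (hi[3] - lo[3])
  acc <- array(FALSE, c(n1, n2, n3))
  for (v in offsets) {
    i <- (1L - lo[1] + v[1]):(n1 - lo[1] + v[1])
    j <- (1L - lo[2] + v[2]):(n2 - lo[2] + v[2])
    k <- (1L - lo[3] + v[3]):(n3 - lo[3] + v[3])
    acc <- acc | p[i, j, k, drop = FALSE]
  }
  sum(acc)
}

# voxel-centre coordinates (nm) along one dimension
voxelCenters <- function(n, h) (seq_len(n) - 0.5) * h

checkFlag <- function(x, choices, what) {
  if (length(x) != 1L || !x %in% choices)
    stop(sprintf("%s must be one of: %s", what,
                 paste(choices, collapse = ", ")), call. = FALSE)
  x
}
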