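# Internal helpers: seeded evaluation, bitmask arithmetic, log-space sums.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG
# state afterwards so seeded helpers do not perturb the global stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
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

#' Derive a stage seed from a master seed
#'
#' Stage seeds are a deterministic function of the master seed and the
#' stage name, so skipping or reordering pipeline stages never changes
#' another stage's random stream.
#'
#' @param master integer master seed.
#' @param stage character stage name.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
stage_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1, is.character(stage))
  m <- 2147483647
  h <- master %% m
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% m
  as.integer(h %% (m - 2) + 1)
}

logaddexp <- function(a, b) {
  m <- pmax(a, b)
  r <- m + log1p(exp(pmin(a, b) - m))
  r[is.infinite(m) & m < 0] <- -Inf
  r
}

# log(exp(a) - exp(b)) for a >= b; returns -Inf when a == b
logdiffexp <- function(a, b) {
  if (b > a + 1e-12) stop("logdiffexp: b > a")
  if (!is.finite(a)) return(-Inf)
  d <- b - a
  if (d >= 0) return(-Inf)
  a + log1p(-exp(d))
}

mask_of <- function(nodes) {
  if (length(nodes) == 0) return(0L)
  as.integer(sum(2^(nodes - 1)))
}

mask_nodes <- function(mask, p) which(bitwAnd(mask, bitwShiftL(1L, 0:(p - 1))) != 0L)

has_bit <- function(mask, node) bitwAnd(mask, bitwShiftL(1L, node - 1L)) != 0L

# remove node j's bit position from a global mask (j assumed absent)
compress_mask_r <- function(mask, j) {
  low <- bitwAnd(mask, bitwShiftL(1L, j - 1L) - 1L)
  high <- bitwShiftR(mask, j) * bitwShiftL(1L, j - 1L)
  bitwOr(low, as.integer(high))
}

popcount <- function(masks) {
  n <- 0L
  while (any(masks > 0L)) {
    n <- n + bitwAnd(masks, 1L)
    masks <- bitwShiftR(masks, 1L)
  }
  n
}

vech_names <- function(labels) {
  p <- length(labels)
  idx <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  paste(labels[idx[, 1]], labels[idx[, 2]], sep = "--")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
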