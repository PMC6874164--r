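# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards. seed = NULL uses the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number or NULL", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  # Mersenne-Twister states seeded from similar integers start weakly
  # correlated and the very first draws are not uniformly distributed;
  # discard a short warm-up run before use.
  stats::runif(32)
  force(code)
}

# Euclidean norm of the rows of a 3-column matrix.
row_norm <- function(m) {
  sqrt(rowSums(m * m))
}

vec_norm <- function(v) sqrt(sum(v * v))

unit_vec <- function(v) {
  n <- vec_norm(v)
  if (n == 0) stop("cannot normalize a zero vector", call. = FALSE)
  v / n
}

# Moving-average smoothing with edge shrinkage, used to give generator noise a
# realistic short-range temporal correlation while preserving the marginal sd.
smooth_noise <- function(n, sd, width = 5L) {
  if (sd <= 0) return(numeric(n))
  raw <- stats::rnorm(n + width - 1L)
  sm <- stats::filter(raw, rep(1 / width, width), sides = 1)
  sm <- as.numeric(sm)[width:(n + width - 1L)]
  sm * sd * sqrt(width)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
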