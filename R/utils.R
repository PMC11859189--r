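# Run code under a given seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Smooth random field on an nr x nc grid: white Gaussian noise blurred by
# a separable Gaussian kernel (row-normalized, so edges are handled by
# renormalization), then rank-transformed to uniform [0, 1] margins.
smooth_uniform_field <- function(nr, nc, scale = 8) {
  w <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (scale > 0) {
    kern <- function(n) {
      k <- stats::dnorm(abs(outer(seq_len(n), seq_len(n), "-")), sd = scale)
      k / rowSums(k)
    }
    w <- kern(nr) %*% w %*% t(kern(nc))
  }
  matrix((rank(w, ties.method = "first") - 0.5) / (nr * nc), nr, nc)
}
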