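# central finite differences of a scalar-valued function of an array
num_grad <- function(f, x, h = 1e-6) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

rel_err <- function(a, b) {
  max(abs(a - b)) / max(max(abs(b)), 1e-12)
}

# a small rendered sample, cached across tests within a run
demo_sample <- local({
  cache <- NULL
  function(size = 96L, seed = 404L) {
    if (is.null(cache)) cache <<- make_carapace_sample(seed, size = size)
    cache
  }
})
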