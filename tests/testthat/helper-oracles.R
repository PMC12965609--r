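# Independent brute-force ordinary-kriging oracle: assembles and solves the
# augmented variogram system one target at a time, with no shared code path
# beyond the closed-form variogram function.
brute_krige <- function(coords, values, target, vm) {
  n <- nrow(coords)
  G <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) {
      h <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      G[i, j] <- variogram_gamma(h, vm$type, vm$nugget, vm$psill, vm$range)
    }
  }
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  b <- numeric(n + 1)
  for (i in seq_len(n)) {
    h <- sqrt(sum((coords[i, ] - target)^2))
    b[i] <- variogram_gamma(h, vm$type, vm$nugget, vm$psill, vm$range)
  }
  b[n + 1] <- 1
  sol <- solve(A, b)
  list(pred = sum(sol[1:n] * values), lambda = sol[1:n], mu = sol[n + 1])
}

residual_field <- function(coords, values) {
  structure(list(coords = coords, residual = values), class = "residual_field")
}

# small cached scene shared across tests (built once per test run)
tiny_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_scene(
      scene_config(dim = c(40, 40), n_villages = 25, weather_block = 10,
                   block_grid = c(2, 2), seed = 101L))
    cache
  }
})
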