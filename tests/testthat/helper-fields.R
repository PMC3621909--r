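# Shared fixtures and independent oracles, all built in code.

# Small labelled field on explicit coordinates.
make_field <- function(x, y, types = 0L, bounds = NULL, id = "test") {
  nuclear_field(x = x, y = y, dot_count = types, bounds = bounds,
                embryo_id = id)
}

# Independent brute-force K oracle on the torus metric (minimum image),
# written without the package's counting kernel. Valid against the tiled
# estimator for r <= min(W, H) / 2, where every neighbour is counted once.
brute_torus_k <- function(field, type = NULL, grid) {
  nuc <- field$nuclei
  idx <- if (is.null(type)) seq_len(nrow(nuc)) else which(nuc$type == type)
  b <- field$bounds
  W <- b[2] - b[1]; H <- b[4] - b[3]
  x <- nuc$x[idx]; y <- nuc$y[idx]
  n <- length(x)
  d_i <- n / (W * H)
  dmat <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      dx <- abs(x[i] - x[j]); dx <- min(dx, W - dx)
      dy <- abs(y[i] - y[j]); dy <- min(dy, H - dy)
      dmat[i, j] <- sqrt(dx^2 + dy^2)
    }
  }
  diag(dmat) <- Inf
  vapply(grid$edges, function(r) sum(dmat <= r) / (d_i * n), numeric(1))
}

# A mold with inheritance-simulated labels, the package's end-to-end input.
inheritance_field <- function(mold, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  simulate_states(build_clones(mold), inheritance = TRUE)
}
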