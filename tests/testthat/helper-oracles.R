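# Brute-force training oracle: dense product over every (synapse, ON-bit)
# pair, independent of the sparse tabulation/neighbor-list implementation.
dense_train_oracle <- function(patterns, topology, profile) {
  N <- patterns$N
  w <- rep(1, N)
  for (on in patterns$on) {
    for (b in on) {
      delta <- topo_distance(topology, seq_len(N), rep(b, N))
      w <- w * leak_multiplier(profile, delta)
    }
  }
  w
}

# Dense readout oracle.
dense_response_oracle <- function(w, patterns) {
  m <- as.matrix(patterns)
  as.numeric(m %*% w)
}

# Small spatial layout on a line, spines at unit-ish spacing, for 3D tests.
line_layout <- function(n, spacing = 0.3) {
  coords <- cbind(x = seq_len(n) * spacing, y = 0, z = 0)
  nsplast:::new_spatial_layout(coords, rep(1L, n), "generated")
}
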