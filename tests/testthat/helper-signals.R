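# deterministic random test signal
random_signal <- function(n, fs = 1000, seed = 1) {
  withr::with_seed(seed, discrete_signal(rnorm(n), fs))
}

# bare-vector circular right shift mirroring the package convention
shift_vec <- function(v, s) {
  n <- length(v)
  s <- ((s %% n) + n) %% n
  if (s == 0) v else v[((seq_len(n) - 1 - s) %% n) + 1]
}

# sum of full-length subspaces as one numeric vector
subspace_sum <- function(ws) {
  Reduce(`+`, lapply(ws, function(w) w$samples))
}
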