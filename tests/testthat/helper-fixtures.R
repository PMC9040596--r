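# Shared fixtures and independent oracles used across the suite.

tiny_pool <- function() {
  assign_growth_rates(taxon_pool(c("a", "b", "c"), c(0.9, 0.09, 0.01)))
}

# Independent brute-force oracle for the batch model: fixed-step forward
# Euler on dN_i/dt = mu_i S/(K_s+S) N_i, dS/dt = -(c_cell/Y) sum dN/dt.
# Deliberately naive so it shares nothing with the adaptive integrator.
euler_batch <- function(n0, mu, params, dt = 1e-3, tol_S = 1e-6,
                        t_max = 1e4) {
  N <- as.numeric(n0)
  S <- params$S0
  t <- 0
  while (S > tol_S * params$S0 && t < t_max) {
    dN <- mu * S / (params$K_s + S) * N * dt
    dS <- sum(dN) * params$c_cell / params$Y
    if (dS > S) { # final partial step: consume exactly what is left
      dN <- dN * S / dS
      dS <- S
    }
    N <- N + dN
    S <- S - dS
    t <- t + dt
  }
  list(N = N, S = S, t = t)
}

# Random small catalog with 60-nt identifiers for amplicon tests.
test_catalog <- function(n = 3, copies = c(4, 2, 1), seed = 42) {
  make_identifier_catalog(n, lengths = 60, copies = copies, seed = seed)
}

# Embed an identifier into random background at a fixed offset.
embed_read <- function(identifier, read_length = 120, offset = 20,
                       alphabet = c("A", "C", "G", "T")) {
  bg <- paste(sample(alphabet, read_length, replace = TRUE), collapse = "")
  paste0(substr(bg, 1, offset - 1), identifier,
         substr(bg, offset + nchar(identifier), read_length))
}
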