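# shared fixtures, all generated in code

# tiny influenza dataset used by the I/O tests
tiny_psa <- function(S = 5, seed = 42) {
  sample_influenza(influenza_spec(), S = S, seed = seed)
}

# a hand-built single-triangle "mesh" exercising the FEM assembly directly
single_triangle_mesh <- function(v = rbind(c(0, 0), c(1, 0), c(0, 1))) {
  structure(list(vertices = v, triangles = matrix(1:3, 1)),
            class = "evppi_mesh")
}

# closed-form two-arm EVPI for an incremental net benefit ~ N(m, s^2):
# E[max(0, D)] - max(0, E[D]) = s phi(m/s) + m Phi(m/s) - max(m, 0)
normal_evpi <- function(m, s) {
  s * stats::dnorm(m / s) + m * stats::pnorm(m / s) - max(m, 0)
}

# canonical focal sets on the frozen 19-parameter fixture
fixture_focal <- function(n) paste0("theta", seq_len(n))
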