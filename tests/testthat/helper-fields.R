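# Synthetic fields and oracles shared across tests.

# ideal pinwheel: orientation = half the polar angle around (r0, c0)
ideal_pinwheel_angles <- function(n, r0, c0, sign = 1) {
  ang <- 0.5 * atan2(sign * (outer(seq_len(n), rep(1, n)) - r0),
                     outer(rep(1, n), seq_len(n)) - c0) * 180 / pi
  ang %% 180
}

# complex plane wave exp(2i pi (kr * r + kc * c))
plane_wave <- function(n, kr, kc) {
  ph <- outer(seq_len(n) * kr, seq_len(n) * kc, `+`) * 2 * pi
  matrix(complex(argument = ph), n, n)
}

crop_margin <- function(m, k) m[(k + 1):(nrow(m) - k), (k + 1):(ncol(m) - k)]

# independent direct implementation of the elastic-net energy
# E = -K sum_i alpha_i log sum_j exp(-|x_i-y_j|^2 / 2K^2)
#     + beta/2 sum_edges |y_j - y_k|^2
en_energy_oracle <- function(Y, X, alpha, K, beta, H, W) {
  cov_term <- 0
  for (i in seq_len(nrow(X))) {
    d2 <- colSums((t(Y) - X[i, ])^2)
    m <- min(d2)
    cov_term <- cov_term +
      alpha[i] * (-m / (2 * K^2) + log(sum(exp(-(d2 - m) / (2 * K^2)))))
  }
  edge_term <- 0
  node <- function(r, c) (c - 1) * H + r
  for (c in seq_len(W)) for (r in seq_len(H)) {
    if (r < H) edge_term <- edge_term +
        sum((Y[node(r, c), ] - Y[node(r + 1, c), ])^2)
    if (c < W) edge_term <- edge_term +
        sum((Y[node(r, c), ] - Y[node(r, c + 1), ])^2)
  }
  -K * cov_term + beta / 2 * edge_term
}

# memoised full-size simulations shared between acceptance tests
.sim_cache <- new.env(parent = emptyenv())
cached_run <- function(seed, alpha_over = 1) {
  key <- sprintf("s%d_a%g", seed, alpha_over)
  if (is.null(.sim_cache[[key]])) {
    sheet <- run_simulation(sim_config(seed = seed, alpha_over = alpha_over))
    .sim_cache[[key]] <- extract_maps(sheet)
  }
  .sim_cache[[key]]
}
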