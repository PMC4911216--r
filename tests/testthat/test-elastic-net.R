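test_that("a single node with one feature and no continuity moves fully onto it", {
  cx <- structure(list(Y = matrix(c(0.2, 0.3, 0, 0, 0), 1, 5),
                       width = 1, height = 1), class = "cortical_sheet")
  fs <- build_feature_set(nx = 1, ny = 1, n_op = 1)
  fs$points <- fs$points[1, , drop = FALSE]  # one feature
  fs$weights <- 1
  out <- elastic_net_step(cx, fs, K = 0.1, beta = 0, method = "dense")
  expect_equal(as.numeric(out$Y), as.numeric(fs$points[1, ]),
               tolerance = 1e-12)
})

test_that("coincident features at the node position are a fixed point", {
  y <- c(0.5, 0.5, 0, 0.08, 0)
  cx <- structure(list(Y = matrix(y, 1, 5), width = 1, height = 1),
                  class = "cortical_sheet")
  fs <- build_feature_set(nx = 1, ny = 1, n_op = 1)
  fs$points <- matrix(rep(y, 3), 3, 5, byrow = TRUE,
                      dimnames = list(NULL, colnames(fs$points)))
  fs$weights <- rep(1, 3)
  out <- elastic_net_step(cx, fs, K = 0.05, beta = 0, method = "dense")
  expect_equal(as.numeric(out$Y), y, tolerance = 1e-12)
})

test_that("responsibilities sum to one over cortical nodes at any K", {
  cfg <- sim_config(nx = 4, ny = 3, width = 10, height = 8, seed = 5)
  fs <- build_feature_set(cfg$nx, cfg$ny, cfg$d, cfg$r, cfg$n_op)
  cx <- init_cortex(cfg)
  for (K in c(0.2, 0.05, 0.01, 0.002)) {
    P <- responsibilities(cx, fs, K)
    expect_equal(max(abs(colSums(P) - 1)), 0, tolerance = 1e-12)
  }
})

test_that("factored and dense updates agree to machine precision", {
  cfg <- sim_config(nx = 5, ny = 4, width = 16, height = 12, seed = 3,
                    alpha_over = 3)
  fs <- build_feature_set(cfg$nx, cfg$ny, cfg$d, cfg$r, cfg$n_op,
                          cfg$alpha_over, cfg$over_assignments)
  cx <- init_cortex(cfg)
  cx$Y[, 3:5] <- cx$Y[, 3:5] + 0.01
  for (K in c(0.2, 0.05)) {
    a <- elastic_net_step(cx, fs, K, 10, method = "dense")
    b <- elastic_net_step(cx, fs, K, 10, method = "factored")
    expect_equal(a$Y, b$Y, tolerance = 1e-12)
  }
})

test_that("the elastic-net energy does not increase over a step", {
  ## 4x4 cortex, 4 features, fixed K; energy evaluated by a direct
  ## implementation of the formula, independent of the update code
  set.seed(7)
  H <- 4; W <- 4
  X <- cbind(runif(4), runif(4), c(-0.05, 0.05, -0.05, 0.05),
             0.08 * cos(c(0, 1, 2, 3)), 0.08 * sin(c(0, 1, 2, 3)))
  colnames(X) <- c("sx", "sy", "od", "opx", "opy")
  alpha <- c(1, 2, 1, 1)
  Y <- cbind(runif(16), runif(16), runif(16, -0.01, 0.01),
             runif(16, -0.01, 0.01), runif(16, -0.01, 0.01))
  cx <- structure(list(Y = Y, width = W, height = H),
                  class = "cortical_sheet")
  fs <- structure(list(points = X, weights = alpha), class = "feature_set")
  for (K in c(0.2, 0.1, 0.05)) {
    e0 <- en_energy_oracle(cx$Y, X, alpha, K, 10, H, W)
    out <- elastic_net_step(cx, fs, K, 10, method = "dense")
    e1 <- en_energy_oracle(out$Y, X, alpha, K, 10, H, W)
    expect_lte(e1, e0 + 1e-12)
  }
})

test_that("K must be positive", {
  cfg <- sim_config(nx = 2, ny = 2, width = 4, height = 4)
  fs <- build_feature_set(2, 2)
  cx <- init_cortex(cfg)
  expect_error(elastic_net_step(cx, fs, K = 0, beta = 10), "K")
  expect_error(elastic_net_step(cx, fs, K = -1, beta = 10), "K")
})

test_that("initialisation is seed-deterministic with smooth retinotopy", {
  cfg <- sim_config(width = 12, height = 10, seed = 42)
  a <- init_cortex(cfg)
  b <- init_cortex(cfg)
  expect_identical(a$Y, b$Y)
  ## zero perturbation amplitude leaves od/op exactly zero
  cfg0 <- sim_config(width = 12, height = 10, seed = 42,
                     od_noise = 0, op_noise = 0)
  z <- init_cortex(cfg0)
  expect_true(all(z$Y[, 3:5] == 0))
  ## retinotopy spans the unit square smoothly
  expect_true(all(z$Y[, 1] > 0 & z$Y[, 1] < 1))
  expect_equal(mean(z$Y[, 1]), 0.5, tolerance = 1e-12)
})

test_that("mean initial ocularity is zero within Monte-Carlo error", {
  ## od ~ U(-a, a): se of the mean over N nodes and S seeds is
  ## a/sqrt(3 N S)
  a <- 0.005; N <- 12 * 10; S <- 20
  m <- vapply(seq_len(S), function(s)
    mean(init_cortex(sim_config(width = 12, height = 10, seed = s,
                                od_noise = a))$Y[, 3]),
    numeric(1))
  expect_lt(abs(mean(m)), 3 * a / sqrt(3 * N * S))
})

test_that("annealing schedule implies the documented iteration counts", {
  expect_equal(n_iterations(sim_config(K0 = 0.2, decay = 0.9925,
                                       K_end = 0.0358)), 229L)
  expect_equal(n_iterations(sim_config(K0 = 0.2, decay = 0.5,
                                       K_end = 0.1)), 1L)
})

test_that("small simulations are reproducible and produce structured maps", {
  cfg <- sim_config(nx = 6, ny = 6, width = 24, height = 24, seed = 2)
  s1 <- run_simulation(cfg)
  s2 <- run_simulation(cfg)
  expect_identical(s1$Y, s2$Y)
  expect_equal(attr(s1, "iterations"), 229L)
  expect_lte(attr(s1, "final_K"), 0.0358)
  maps <- extract_maps(s1)
  expect_s3_class(maps$op, "op_map")
  expect_true(all(dim(maps$od$field) == c(24, 24)))
})

test_that("map readout follows the double-angle convention", {
  Y <- rbind(c(0.1, 0.1, 0.02, 0.08, 0),
             c(0.2, 0.1, 0.01, 0, -0.08),
             c(0.1, 0.2, 0.03, -0.08, 0),
             c(0.2, 0.2, 0.04, 0, 0.08))
  cx <- structure(list(Y = Y, width = 2, height = 2),
                  class = "cortical_sheet")
  maps <- extract_maps(cx)
  ang <- op_angle(maps$op)
  expect_equal(ang[1, 1], 0)
  expect_equal(ang[2, 1], 135)  # (0, -0.08): half of -90 wraps to 135
  expect_equal(ang[1, 2], 90)
  expect_equal(ang[2, 2], 45)
  expect_equal(op_selectivity(maps$op)[1, 1], 0.08)
  expect_true(all(maps$od$field > 0))
})
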