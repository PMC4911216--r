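# small imaging-stack fixture built in code
tiny_stack <- function(seed = 1, H = 32, W = 32, n_frames = 20,
                       n_dir = 4, n_trials = 2, noise = 0) {
  set.seed(seed)
  dirs <- (seq_len(n_dir) - 1) * 360 / n_dir
  conds <- rbind(
    expand.grid(direction = dirs, eye = c("L", "R"),
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE),
    data.frame(direction = NA_real_, eye = NA_character_))
  conds$blank <- is.na(conds$direction)
  data <- array(rnorm(n_trials * nrow(conds) * n_frames * H * W,
                      1, noise),
                c(n_trials, nrow(conds), n_frames, H, W))
  imaging_stack(data, conds, frame_rate = 5, stim_frames = 5:15)
}

test_that("frame alignment recovers planted integer shifts", {
  set.seed(5)
  ref <- gaussian_blur(matrix(rnorm(40 * 40), 40, 40), 2)
  shifted <- cortexmap:::translate_image(ref, 3, -2)
  stk <- tiny_stack(H = 40, W = 40, n_frames = 1, n_dir = 1, n_trials = 1)
  stk$data[1, , 1, , ] <- rep(shifted, each = dim(stk$data)[2])
  out <- align_frames(stk, reference = ref, max_shift = 5)
  sh <- attr(out, "shifts")
  expect_true(all(sh[1, , 1, 1] == -3))
  expect_true(all(sh[1, , 1, 2] == 2))
  ## reference aligned to itself: zero shift
  stk$data[1, 1, 1, , ] <- ref
  out2 <- align_frames(stk, reference = ref, max_shift = 5)
  expect_equal(attr(out2, "shifts")[1, 1, 1, ], c(0L, 0L))
})

test_that("alignment recovers most planted shifts under noise", {
  set.seed(6)
  ref <- gaussian_blur(matrix(rnorm(40 * 40), 40, 40), 2)
  sds <- sd(ref) / 5  # SNR 5
  hits <- 0
  shifts <- cbind(sample(-4:4, 20, TRUE), sample(-4:4, 20, TRUE))
  for (i in 1:20) {
    img <- cortexmap:::translate_image(ref, shifts[i, 1], shifts[i, 2]) +
      rnorm(1600, 0, sds)
    rec <- cortexmap:::best_shift(img, ref, 5)
    if (all(rec == -shifts[i, ])) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("condition averaging pools opposite directions and is linear", {
  stk <- tiny_stack(n_dir = 16)
  cs <- average_conditions(stk)
  expect_equal(length(cs$orientations), 8L)
  expect_equal(cs$orientations, seq(0, 157.5, by = 22.5))
  ## two trials with values v and -v average to exactly zero
  stk2 <- tiny_stack(n_trials = 2)
  stk2$data[2, , , , ] <- -stk2$data[1, , , , ]
  cs2 <- average_conditions(stk2)
  expect_equal(max(abs(cs2$data)), 0)
  ## averaging identical trials is idempotent
  stk3 <- tiny_stack(n_trials = 3)
  stk3$data[2, , , , ] <- stk3$data[1, , , , ]
  stk3$data[3, , , , ] <- stk3$data[1, , , , ]
  cs3 <- average_conditions(stk3)
  expect_equal(cs3$data[1, 1, 1, , ], stk3$data[1, 1, 1, , ])
  ## a missing condition is reported by name (both drift directions of
  ## one orientation must go, or pooling restores it)
  stk4 <- tiny_stack()
  gone <- !stk4$conditions$blank & stk4$conditions$eye == "R" &
    stk4$conditions$direction %% 180 == 0
  stk4$conditions$eye[gone] <- "L"
  expect_error(average_conditions(stk4), "missing conditions")
})

test_that("preprocessing removes DC exactly, keeps band, flips sign", {
  stk <- tiny_stack(H = 48, W = 48, n_dir = 2)
  cs <- average_conditions(stk)
  ## constant frames vanish after the high-pass
  cs$data[] <- 7
  out <- preprocess_frames(cs, hp_sigma = 10, lp_sigma = 1)
  expect_equal(max(abs(out$data)), 0, tolerance = 1e-10)
  ## a low-frequency sinusoid (wavelength >> 6 hp_sigma) is attenuated
  ## by more than 90%
  lowf <- sin(2 * pi * outer(1:48, rep(1, 48)) / 96)
  cs$data[] <- 0
  cs$data[1, 1, 1, , ] <- lowf
  out2 <- preprocess_frames(cs, hp_sigma = 4, lp_sigma = 0.5)
  expect_lt(max(abs(out2$data[1, 1, 1, 13:36, 13:36])),
            0.1 * max(abs(lowf)))
  ## a dark activity spot becomes positive after the sign flip
  spot <- matrix(0, 48, 48); spot[24, 24] <- -1
  cs$data[1, 1, 1, , ] <- spot
  out3 <- preprocess_frames(cs, hp_sigma = 10, lp_sigma = 1)
  expect_gt(out3$data[1, 1, 1, 24, 24], 0)
})

test_that("feature-stack composition obeys the closed-form identities", {
  stk <- tiny_stack(n_dir = 16)
  cs <- average_conditions(stk)
  ## identical responses for all orientations and eyes cancel exactly
  cs$data[] <- 3
  fs <- compose_feature_stacks(cs, "binocular")
  expect_equal(max(abs(fs$op_real)), 0, tolerance = 1e-12)
  expect_equal(max(abs(fs$op_imag)), 0, tolerance = 1e-12)
  expect_equal(max(abs(fs$od)), 0, tolerance = 1e-12)
  ## response 1 only at 0 degrees in both eyes: op_real = 1, op_imag = 0
  cs$data[] <- 0
  cs$data[1, 1, , , ] <- 1  # orientation 0, eye L
  cs$data[1, 2, , , ] <- 1  # orientation 0, eye R
  fs2 <- compose_feature_stacks(cs, "binocular")
  expect_equal(max(abs(fs2$op_real - 1)), 0, tolerance = 1e-12)
  expect_equal(max(abs(fs2$op_imag)), 0, tolerance = 1e-12)
  ## left-eye-only responses: OD strictly negative
  cs$data[] <- 0
  cs$data[, 1, , , ] <- 1
  fs3 <- compose_feature_stacks(cs, "left")
  expect_true(all(fs3$od < 0))
})

test_that("whitening and rotation have the contracted algebra", {
  set.seed(9)
  n_f <- 12; H <- 30; W <- 30
  ## smooth planted sources with random mixing
  s1 <- gaussian_blur(matrix(rnorm(H * W), H, W), 3)
  s2 <- gaussian_blur(matrix(rnorm(H * W), H, W), 1.2)
  A <- matrix(rnorm(n_f * 2), n_f, 2)
  stack <- array(A %*% rbind(as.vector(s1), as.vector(s2)),
                 c(n_f, H, W))
  ss <- esd_unmix(stack, shift = c(3, 3), bulk_factor = 0)
  ## whitened frame covariance is the identity
  Z <- ss$rotation %*% matrix(ss$sources, dim(ss$sources)[1], H * W)
  expect_lt(max(abs(tcrossprod(Z) / (H * W) -
                      diag(nrow(Z)))), 1e-8)
  ## rotation is orthogonal
  V <- ss$rotation
  expect_lt(max(abs(t(V) %*% V - diag(ncol(V)))), 1e-8)
  ## rank-deficient input: only 2 components kept, count reported
  expect_equal(dim(ss$sources)[1], 2L)
  expect_equal(ss$n_dropped, n_f - 2L)
})

test_that("planted sources are unmixed cleanly, with and without noise", {
  ## the field must hold enough independent patches of the smoother
  ## source for the shifted cross-covariance to resolve the rotation
  set.seed(10)
  H <- 96; W <- 96; n_f <- 50
  s1 <- gaussian_blur(matrix(rnorm(H * W), H, W), 4)   # long range
  s2 <- gaussian_blur(matrix(rnorm(H * W), H, W), 1)   # short range
  s1 <- s1 / sd(s1); s2 <- s2 / sd(s2)
  A <- matrix(rnorm(n_f * 2), n_f, 2)
  clean <- A %*% rbind(as.vector(s1), as.vector(s2))

  score <- function(stack) {
    ss <- esd_unmix(array(stack, c(n_f, H, W)), shift = c(5, 5),
                    bulk_factor = 0)
    src <- matrix(ss$sources, dim(ss$sources)[1], H * W)
    c(max(abs(cor(t(src), as.vector(s1)))),
      max(abs(cor(t(src), as.vector(s2)))))
  }
  r_clean <- score(clean)
  expect_gt(min(r_clean), 0.99)
  noisy <- clean + rnorm(length(clean), 0, 0.1 * sd(clean))
  ## with 10% pixel noise the bulk guard keeps recovery above 0.95
  ss <- esd_unmix(array(noisy, c(n_f, H, W)), shift = c(5, 5))
  src <- matrix(ss$sources, dim(ss$sources)[1], H * W)
  expect_gt(max(abs(cor(t(src), as.vector(s1)))), 0.95)
  expect_gt(max(abs(cor(t(src), as.vector(s2)))), 0.95)
})

test_that("unmixing a single source returns it up to sign", {
  set.seed(11)
  H <- 24; W <- 24
  s <- gaussian_blur(matrix(rnorm(H * W), H, W), 2)
  kern <- seq(0, 1, length.out = 10)
  stack <- array(outer(kern, as.vector(s)), c(10, H, W))
  ss <- esd_unmix(stack, shift = c(2, 2))
  expect_equal(dim(ss$sources)[1], 1L)
  expect_gt(abs(cor(as.vector(ss$sources[1, , ]), as.vector(s))), 0.999)
})

test_that("the pipeline is linear before source selection", {
  set.seed(12)
  H <- 24; W <- 24; n_f <- 10
  s <- gaussian_blur(matrix(rnorm(H * W), H, W), 2)
  kern <- seq_len(n_f) / n_f
  stack <- array(outer(kern, as.vector(s)), c(n_f, H, W))
  s1 <- esd_unmix(stack, shift = c(2, 2))
  s2 <- esd_unmix(3 * stack, shift = c(2, 2))
  ## coefficient x source products scale with the input
  m1 <- s1$coefficients[, 1] %o% as.vector(s1$sources[1, , ])
  m2 <- s2$coefficients[, 1] %o% as.vector(s2$sources[1, , ])
  expect_equal(m2, 3 * m1, tolerance = 1e-8)
})

test_that("source selection follows the stimulus-locked template", {
  set.seed(13)
  H <- 64; W <- 64; n_f <- 50
  tmpl <- response_template(n_f, 11:35)
  sig <- gaussian_blur(matrix(rnorm(H * W), H, W), 3)
  nui <- gaussian_blur(matrix(rnorm(H * W), H, W), 1)
  stack <- array(outer(tmpl, as.vector(sig)) +
                   outer(sin(seq_len(n_f)), as.vector(nui)),
                 c(n_f, H, W))
  ss <- esd_unmix(stack, shift = c(4, 4))
  m <- extract_feature_map(ss, final_lp_sigma = 0)
  expect_gt(abs(cor(as.vector(m), as.vector(sig))), 0.99)
  ## the plateau of the selected coefficient series is positive
  expect_gt(attr(m, "score"), 0.6)
  ## flat coefficients: advisory error asking for a manual index
  ss0 <- ss
  ss0$coefficients[] <- 0
  expect_error(extract_feature_map(ss0), "manual")
})

test_that("vector averaging reads out single-orientation responses", {
  stk <- tiny_stack(n_dir = 16)
  cs <- average_conditions(stk)
  cs$data[] <- 0
  oi <- 4  # orientation 67.5 degrees
  cs$data[oi, , , , ] <- 1
  base <- vector_average_baseline(cs)
  ang <- op_angle(base$op)
  expect_equal(max(abs(ang - cs$orientations[oi])), 0, tolerance = 1e-9)
  ## equal responses across orientations: zero vector
  cs$data[] <- 2
  base2 <- vector_average_baseline(cs)
  expect_equal(max(Mod(base2$op$field)), 0, tolerance = 1e-12)
})
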