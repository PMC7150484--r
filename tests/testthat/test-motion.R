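test_that("mutual information has its information-theoretic properties", {
  set.seed(21)
  a <- matrix(runif(128 * 128), 128, 128)
  # MI(X, X) equals the marginal histogram entropy
  bins <- 32L
  idx <- pmin(pmax(floor(a * bins), 0), bins - 1)
  p <- tabulate(idx + 1L, nbins = bins) / length(a)
  h <- -sum(p[p > 0] * log(p[p > 0]))
  expect_equal(mutual_information(a, a, bins), h, tolerance = 1e-10)
  expect_gt(h, 0)
  # constant frame carries no information
  expect_equal(mutual_information(matrix(0.5, 64, 64),
                                  matrix(runif(64 * 64), 64, 64)), 0)
  # symmetry
  b <- matrix(runif(128 * 128), 128, 128)
  expect_equal(mutual_information(a, b, 64), mutual_information(b, a, 64),
               tolerance = 1e-12)
  # independent frames: only finite-sample bias remains
  expect_lt(mutual_information(a, b, 64), 0.2)
  expect_lt(mutual_information(a, b, 16), 0.01)
  expect_error(mutual_information(a, matrix(0, 2, 2)), "shape")
})

test_that("independent noise never increases mutual information", {
  set.seed(31)
  base <- matrix(rep(seq(0, 1, length.out = 64), each = 64), 64, 64)
  b0 <- pmin(pmax(base + matrix(rnorm(64 * 64, 0, 0.05), 64, 64), 0), 1)
  mi0 <- mutual_information(base, b0, 16)
  worse <- replicate(20, {
    bn <- pmin(pmax(b0 + matrix(rnorm(64 * 64, 0, 0.2), 64, 64), 0), 1)
    mutual_information(base, bn, 16)
  })
  expect_true(all(worse < mi0 + 0.02))
})

test_that("movement checks run at the cadence and alarm on scene change", {
  cfg <- phantom_preset("jump", seed = 0)
  sq <- generate_phantom_sequence(cfg)
  init <- sq$truth_masks[[1]]
  fp0 <- preprocess_frame(sq$frames[[1]], init, preprocess_params())
  st <- monitor_state(fp0, init)
  expect_equal(check_motion(st, fp0, 7)$decision, "not_checked")
  r0 <- check_motion(st, fp0, 0)
  expect_equal(r0$decision, "stable")
  # identical frame at a later checkpoint stays stable
  st1 <- r0$state
  r1 <- check_motion(st1, fp0, 10)
  expect_equal(r1$decision, "stable")
  expect_false(is.na(r1$state$baseline_mi))
})

test_that("the monitor raises exactly one alarm at the first post-jump checkpoint", {
  cfg <- phantom_preset("jump", seed = 3)
  sq <- generate_phantom_sequence(cfg)
  init <- sq$truth_masks[[1]]
  st <- NULL
  decisions <- character(0)
  for (i in seq_along(sq$frames)) {
    fp <- preprocess_frame(sq$frames[[i]], init, preprocess_params())
    if (is.null(st)) st <- monitor_state(fp, init)
    r <- check_motion(st, fp, i - 1L)
    st <- r$state
    decisions[i] <- r$decision
  }
  checkpoints <- which(decisions != "not_checked") - 1L
  expect_equal(checkpoints, seq(0L, 110L, by = 10L))
  expect_equal(sum(decisions == "alarm" & seq_along(decisions) - 1L < 40), 0L)
  expect_equal(decisions[41], "alarm")          # frame time 40
  expect_equal(decisions[51], "stable")         # stands down post-correction
})

test_that("NCC matching recovers known shifts with documented tie-breaks", {
  set.seed(41)
  img <- matrix(runif(80 * 80), 80, 80)
  box <- c(30, 49, 25, 44)
  tmpl <- img[box[1]:box[2], box[3]:box[4]]
  m <- ncc_match(img, tmpl, box, c(0, 8))
  expect_equal(m$displacement, c(0, 0))
  expect_equal(m$score, 1, tolerance = 1e-9)
  shifted <- translate_mask(img, 3, -2)  # translate_mask shifts any matrix
  shifted[shifted == 0] <- stats::runif(sum(shifted == 0))
  m2 <- ncc_match(shifted, tmpl, box, c(0, 8))
  expect_equal(m2$displacement, c(3, -2))
  expect_error(ncc_match(img, matrix(0.5, 5, 5), c(10, 14, 10, 14), c(0, 4)),
               "zero variance")
})

test_that("the moving force splits into integer steps that sum exactly", {
  u <- matrix(0, 40, 40); u[18:22, 18:22] <- 1
  st <- monitor_state(matrix(runif(1600), 40, 40), u, alpha = 4L)
  st$force_total <- c(8, 0); st$pending_force <- c(8, 0)
  shifts <- matrix(0, 4, 2)
  for (j in 1:4) {
    r <- apply_moving_force(u, st)
    u <- r$u; st <- r$state; shifts[j, ] <- r$shift
  }
  expect_equal(shifts[, 1], rep(2, 4))
  expect_equal(colSums(shifts), c(8, 0))

  u2 <- matrix(0, 40, 40); u2[18:22, 18:22] <- 1
  st2 <- monitor_state(matrix(runif(1600), 40, 40), u2, alpha = 2L)
  st2$force_total <- c(5, 0); st2$pending_force <- c(5, 0)
  r1 <- apply_moving_force(u2, st2)
  r2 <- apply_moving_force(r1$u, r1$state)
  expect_equal(r1$shift, c(3, 0))
  expect_equal(r2$shift, c(2, 0))
  # zero force is a no-op
  st0 <- r2$state
  r3 <- apply_moving_force(r2$u, st0)
  expect_equal(r3$u, r2$u)
  # pushing the mask off the grid is a tracking-lost error
  stx <- monitor_state(matrix(runif(1600), 40, 40), u2, alpha = 1L)
  stx$force_total <- c(100, 0); stx$pending_force <- c(100, 0)
  expect_error(apply_moving_force(u2, stx), "tracking lost")
})

test_that("sonication is gated by the alarm flag", {
  u <- matrix(0, 20, 20); u[8:12, 8:12] <- 1
  st <- monitor_state(matrix(runif(400), 20, 20), u)
  expect_equal(gate_by_alarm(st), "fire")
  st$alarm <- TRUE
  expect_equal(gate_by_alarm(st), "hold")
  st$alarm <- FALSE
  expect_equal(gate_by_alarm(st), "fire")
})
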