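# Pose features: kinematics, dispersion, geometry, angles, reversal, sleep,
# the 57-column assembly, PCA reduction, and linear separability.

# hand-built track helper: straight body along -x behind the snout
makeTrack <- function(snoutXY, fps = 20, tank = c(1000, 1000),
                      heading = c(1, 0)) {
  n <- nrow(snoutXY)
  h <- matrix(heading, n, 2, byrow = TRUE)
  d <- cumsum(c(10, 8, 6, 4))
  coords <- cbind(
    snoutXY,
    snoutXY - d[1] * h, snoutXY - d[2] * h,
    snoutXY - d[3] * h, snoutXY - d[4] * h,
    snoutXY - d[1] * h + 3 * cbind(-h[, 2], h[, 1]))
  colnames(coords) <- as.vector(rbind(paste0("x_", behaviorome:::KEYPOINTS),
                                      paste0("y_", behaviorome:::KEYPOINTS)))
  # column order above is per-keypoint (x,y) pairs; rebuild properly
  kp <- behaviorome:::KEYPOINTS
  pos <- list(snout = snoutXY, midbody = snoutXY - d[1] * h,
              endbody = snoutXY - d[2] * h, tail = snoutXY - d[3] * h,
              fan = snoutXY - d[4] * h,
              sidebody = snoutXY - d[1] * h + 3 * cbind(-h[, 2], h[, 1]))
  coords <- matrix(NA_real_, n, 12,
                   dimnames = list(NULL, as.vector(rbind(paste0("x_", kp),
                                                         paste0("y_", kp)))))
  for (k in kp) {
    coords[, paste0("x_", k)] <- pos[[k]][, 1]
    coords[, paste0("y_", k)] <- pos[[k]][, 2]
  }
  methods::new("KeypointTrack", frame = seq_len(n) - 1L,
               timestamp = (seq_len(n) - 1) / fps, coords = coords,
               visible = matrix(TRUE, n, 6, dimnames = list(NULL, kp)),
               tankSize = tank, fps = fps, meta = list())
}

identityFilterConfig <- poseConfig(filterB = 1)

test_that("kinematics: speeds, heading, and the filter oracle", {
  still <- makeTrack(matrix(rep(c(100, 100), each = 60), 60))
  kin <- computeKinematics(still, identityFilterConfig)
  expect_true(all(kin$velocity[-1, ] == 0))

  adv <- makeTrack(cbind(100 + 5 * (0:59), 100))
  kin2 <- computeKinematics(adv, identityFilterConfig)
  expect_equal(unname(kin2$velocity[10, "snout_velocity"]), 100)  # px/s
  expect_equal(kin2$heading[10, ], c(1, 0))

  # filtered velocity of a step change matches direct convolution
  cfg <- poseConfig()   # 5-tap moving average
  x <- c(rep(0, 30), rep(10, 30))
  step <- makeTrack(cbind(100 + x, 100))
  kin3 <- computeKinematics(step, cfg)
  filt <- stats::filter(c(rep(100 + x[1], 4), 100 + x), rep(0.2, 5),
                        sides = 1)
  filt <- as.numeric(filt[-(1:4)])
  expect_equal(unname(kin3$velocity[-1, "snout_velocity"]),
               abs(diff(filt)) * 20, tolerance = 1e-10)

  one <- makeTrack(matrix(c(1, 1), 1))
  expect_warning(k1 <- computeKinematics(one, cfg), "single-frame")
  expect_true(all(is.na(k1$velocity)))
})

test_that("dispersion follows the bounding-box circle rule", {
  cfg <- poseConfig()
  still <- matrix(rep(c(50, 50), each = 100), 100)
  expect_true(all(computeDispersion(still, cfg) == 0))

  # snout sweeping 10 px in x within the window: area = 25 * pi
  sweep10 <- cbind(rep(seq(0, 10, length.out = 20), 5), 0)
  disp <- computeDispersion(sweep10, cfg)
  expect_equal(disp[40], 25 * pi)

  # 6 x 8 rectangle corners: diagonal 10 -> 25 * pi, equals the exact MEC
  rect <- cbind(rep(c(0, 6, 6, 0), 10), rep(c(0, 0, 8, 8), 10))
  disp2 <- computeDispersion(rect, cfg)
  expect_equal(disp2[40], 25 * pi)
  expect_equal(minEnclosingCircleArea(unique(rect)), 25 * pi)

  # oracle inequality: box-diagonal circle >= exact minimum enclosing circle
  set.seed(11)
  for (i in 1:20) {
    pts <- matrix(runif(2 * 15, 0, 50), ncol = 2)
    dx <- diff(range(pts[, 1])); dy <- diff(range(pts[, 2]))
    boxArea <- pi * (dx^2 + dy^2) / 4
    expect_gte(boxArea, minEnclosingCircleArea(pts) - 1e-9)
  }

  # translation and 90-degree rotation invariance
  set.seed(12)
  path <- cbind(cumsum(rnorm(80)), cumsum(rnorm(80)))
  d0 <- computeDispersion(path, cfg)
  expect_equal(computeDispersion(path + 100, cfg), d0)
  expect_equal(computeDispersion(cbind(-path[, 2], path[, 1]), cfg), d0)
})

test_that("geometry: body length, counts, and edge distance", {
  tr <- makeTrack(matrix(rep(c(3, 50), each = 40), 40), tank = c(100, 100))
  geo <- computeGeometry(tr, poseConfig())
  expect_equal(unname(geo$body_length[1]), 28)  # 10 + 8 + 6 + 4
  expect_true(all(geo$counts == 1))
  expect_equal(unname(geo$dist_snout[1]), 3)
  # day-normalized length is centered at zero for a rigid body
  expect_equal(max(abs(geo$body_length_norm)), 0, tolerance = 1e-12)
  expect_equal(unname(geo$tail_fan_prop[1]), 4 / 28)
})

test_that("angles: interior angles, curvature sign, mirror flip", {
  straight <- makeTrack(matrix(rep(c(100, 100), each = 10), 10))
  ang <- computeAngles(straight)
  expect_equal(unname(ang$alpha1[1]), pi)
  expect_equal(unname(ang$alpha_all[1]), 3 * pi)
  expect_equal(unname(ang$theta1[1]), 0)

  # right angle at the midbody
  kp <- behaviorome:::KEYPOINTS
  coords <- matrix(NA_real_, 5, 12,
                   dimnames = list(NULL, as.vector(rbind(paste0("x_", kp),
                                                         paste0("y_", kp)))))
  pos <- list(snout = c(0, 10), midbody = c(0, 0), endbody = c(10, 0),
              tail = c(20, 0), fan = c(30, 0), sidebody = c(5, 5))
  for (k in kp) {
    coords[, paste0("x_", k)] <- pos[[k]][1]
    coords[, paste0("y_", k)] <- pos[[k]][2]
  }
  tr <- methods::new("KeypointTrack", frame = 0:4,
                     timestamp = (0:4) / 20, coords = coords,
                     visible = matrix(TRUE, 5, 6,
                                      dimnames = list(NULL, kp)),
                     tankSize = c(100, 100), fps = 20, meta = list())
  expect_equal(unname(computeAngles(tr)$alpha1[1]), pi / 2)

  # body laid on an arc: curvature sign from the cross-product oracle,
  # and the sign flips under mirror reflection of the track
  phi <- seq(0, pi / 3, length.out = 5)   # snout ahead on a CCW arc
  pts <- 50 * cbind(cos(rev(phi)), sin(rev(phi)))
  posA <- list(snout = pts[1, ], midbody = pts[2, ], endbody = pts[3, ],
               tail = pts[4, ], fan = pts[5, ], sidebody = pts[2, ] + 1)
  for (k in kp) {
    coords[, paste0("x_", k)] <- posA[[k]][1]
    coords[, paste0("y_", k)] <- posA[[k]][2]
  }
  arcTr <- methods::new("KeypointTrack", frame = 0:4,
                        timestamp = (0:4) / 20, coords = coords,
                        visible = matrix(TRUE, 5, 6,
                                         dimnames = list(NULL, kp)),
                        tankSize = c(200, 200), fps = 20, meta = list())
  angA <- computeAngles(arcTr)
  h <- posA$snout - posA$midbody
  tg <- posA$snout - posA$endbody
  oracleSign <- sign(h[1] * tg[2] - h[2] * tg[1])
  expect_equal(sign(angA$theta1[1]), oracleSign)
  expect_true(all(sign(c(angA$theta1[1], angA$theta2[1], angA$theta3[1]))
                  == oracleSign))
  # mirror: reflect y
  coordsM <- coords
  coordsM[, grep("^y_", colnames(coords))] <-
    -coords[, grep("^y_", colnames(coords))]
  mirTr <- methods::new("KeypointTrack", frame = 0:4,
                        timestamp = (0:4) / 20, coords = coordsM,
                        visible = matrix(TRUE, 5, 6,
                                         dimnames = list(NULL, kp)),
                        tankSize = c(200, 200), fps = 20, meta = list())
  angM <- computeAngles(mirTr)
  expect_equal(angM$theta1[1], -angA$theta1[1])
  expect_equal(angM$alpha1[1], angA$alpha1[1])   # interior angles unchanged
})

test_that("reversal scoring separates forward, backward, and sideways", {
  cfg <- poseConfig()
  fwd <- makeTrack(cbind(100 + 2 * (0:79), 100))
  rf <- detectReversal(fwd, cfg)
  expect_true(all(rf$dot_product[-1] > 0))
  expect_true(all(rf$reversal_binary == 0))

  bwd <- makeTrack(cbind(300 - 2 * (0:79), 100))  # heading +x, moving -x
  rb <- detectReversal(bwd, cfg)
  expect_true(all(rb$dot_product[-1] < 0))
  expect_true(all(rb$reversal_binary[-1] == 1))

  ortho <- makeTrack(cbind(100, 100 + 2 * (0:79)))  # heading +x, moving +y
  ro <- detectReversal(ortho, cfg)
  expect_lt(max(abs(ro$dot_product[-1])), 1e-9)
  expect_true(all(ro$reversal_binary == 0))
})

test_that("sleep labeling follows the run-length rule", {
  cfg <- poseConfig()  # threshold 50, minimum 60 s
  fps <- 20
  # 90 s still (dispersion 0), then 60 s of motion
  disp <- c(rep(0, 90 * fps), rep(500, 60 * fps))
  sl <- scoreSleep(disp, cfg, fps)
  expect_equal(sum(sl), 90 * fps)
  expect_true(all(sl[1:(90 * fps)]))

  disp30 <- c(rep(0, 30 * fps), rep(500, 90 * fps))
  expect_equal(sum(scoreSleep(disp30, cfg, fps)), 0)

  cruising <- rep(400, 120 * fps)
  expect_equal(sum(scoreSleep(cruising, cfg, fps)), 0)

  # missing dispersion breaks a run
  broken <- rep(0, 90 * fps)
  broken[900] <- NA
  sl2 <- scoreSleep(broken, cfg, fps)
  expect_equal(sum(sl2), 0)
})

test_that("assembled features have exactly 57 aligned columns", {
  cfg <- simConfig(seed = 5, jitterSd = 0.3)
  tr <- simulateTrack(behaviorProgram(programSegment("rest", 30),
                                      programSegment("cruise", 20),
                                      programSegment("drift", 10)), cfg)
  pf <- assembleFeatures(tr)
  expect_equal(ncol(featureMatrix(pf)), 57L)
  expect_equal(nrow(featureMatrix(pf)), nFrames(tr))
  # with no jitter the rigid body keeps its length: zero rolling-SD
  tr0 <- simulateTrack(behaviorProgram(programSegment("cruise", 20)),
                       simConfig(seed = 5, jitterSd = 0))
  fm0 <- featureMatrix(assembleFeatures(tr0))
  expect_equal(max(abs(fm0[-(1:2), "std_body_length_norm"]), na.rm = TRUE), 0,
               tolerance = 1e-6)
})

test_that("PC reduction: orthonormal loadings and degenerate ranks", {
  set.seed(21)
  # rank-2 data embedded in 8 columns
  base <- matrix(rnorm(400 * 2), 400, 2)
  X <- base %*% matrix(rnorm(16), 2, 8) +
    matrix(rnorm(400 * 8, 0, 1e-8), 400, 8)
  colnames(X) <- paste0("f", 1:8)
  pf <- reduceToPCs(X, nPcs = 5, config = poseConfig(smoothWindow = 1L))
  expect_lt(sum(pf@explainedVar[3:5]), 1e-6)
  L <- pf@loadings
  expect_equal(crossprod(L), diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(pf@explainedVar) <= 1e-12))

  # isotropic data spreads variance about evenly
  iso <- matrix(rnorm(4000 * 6), 4000, 6)
  colnames(iso) <- paste0("g", 1:6)
  pfI <- reduceToPCs(iso, nPcs = 6, config = poseConfig(smoothWindow = 1L))
  expect_true(all(abs(pfI@explainedVar - 1 / 6) < 0.05))

  # constant columns are dropped with a warning and recorded
  Xc <- cbind(X, const = 1)
  expect_warning(pfc <- reduceToPCs(Xc, nPcs = 3,
                                    config = poseConfig(smoothWindow = 1L)),
                 "constant")
  expect_identical(pfc@dropped, "const")
})

test_that("linear separability behaves at its extremes", {
  set.seed(31)
  n <- 150
  sep <- rbind(matrix(rnorm(n * 5, 0), n, 5),
               matrix(rnorm(n * 5, 8), n, 5))
  lab <- rep(c(0, 1), each = n)
  expect_gt(linearSeparability(sep, lab), 0.98)

  same <- matrix(rnorm(2 * n * 5), 2 * n, 5)
  accNull <- linearSeparability(same, sample(lab))
  expect_lt(abs(accNull - 0.5), 0.12)

  expect_error(linearSeparability(same, rep(1, 2 * n)), "two label")
})
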