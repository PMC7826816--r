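test_that("level north-facing device gives the identity orientation", {
  o <- orientation_from_accel_mag(data.frame(
    acclx = 0, accly = 0, acclz = 1, magx = 0.5, magy = 0, magz = -0.4
  ))
  expect_equal(unlist(o), c(roll = 0, pitch = 0, yaw = 0))
})

test_that("orientation recovery inverts synthesis over a grid of angles", {
  g <- c(0, 0, 1)
  m <- c(0.5, 0, -0.4)
  grid <- expand.grid(
    roll = seq(-1.3, 1.3, length.out = 7),
    pitch = seq(-1.3, 1.3, length.out = 7),
    yaw = seq(-3, 3, length.out = 9)
  )
  for (i in seq_len(nrow(grid))) {
    R <- rotation_matrix(grid$roll[i], grid$pitch[i], grid$yaw[i])
    a <- as.vector(t(R) %*% g)
    mm <- as.vector(t(R) %*% m)
    o <- orientation_from_accel_mag(data.frame(
      acclx = a[1], accly = a[2], acclz = a[3],
      magx = mm[1], magy = mm[2], magz = mm[3]
    ))
    expect_equal(o$roll, grid$roll[i], tolerance = 1e-9)
    expect_equal(o$pitch, grid$pitch[i], tolerance = 1e-9)
    expect_lt(abs(atan2(sin(o$yaw - grid$yaw[i]), cos(o$yaw - grid$yaw[i]))), 1e-9)
  }
  # the specific pose 20/10/35 degrees recovers exactly
  ang <- c(20, 10, 35) * pi / 180
  R <- rotation_matrix(ang[1], ang[2], ang[3])
  a <- as.vector(t(R) %*% g)
  mm <- as.vector(t(R) %*% m)
  o <- orientation_from_accel_mag(data.frame(
    acclx = a[1], accly = a[2], acclz = a[3],
    magx = mm[1], magy = mm[2], magz = mm[3]
  ))
  expect_equal(unlist(o), c(roll = ang[1], pitch = ang[2], yaw = ang[3]),
    tolerance = 1e-9
  )
})

test_that("degenerate sensor inputs are rejected and yaw ignores accel scale", {
  expect_error(
    orientation_from_accel_mag(data.frame(
      acclx = 0, accly = 0, acclz = 0, magx = 0.5, magy = 0, magz = 0
    )),
    class = "escalert_parameter_error"
  )
  expect_error(
    orientation_from_accel_mag(data.frame(
      acclx = 0, accly = 0, acclz = 1, magx = 0, magy = 0, magz = 0
    )),
    class = "escalert_parameter_error"
  )
  base <- data.frame(
    acclx = 0.2, accly = -0.1, acclz = 0.95, magx = 0.4, magy = 0.1, magz = -0.3
  )
  scaled <- base
  scaled[c("acclx", "accly", "acclz")] <- base[c("acclx", "accly", "acclz")] * 3.7
  expect_equal(
    orientation_from_accel_mag(scaled)$yaw,
    orientation_from_accel_mag(base)$yaw
  )
})

test_that("rotation matrices are proper rotations with the stated axis order", {
  expect_equal(rotation_matrix(0, 0, 0), diag(3))
  # pure roll about x maps y to z
  expect_equal(
    as.vector(rotation_matrix(pi / 2, 0, 0) %*% c(0, 1, 0)),
    c(0, 0, 1),
    tolerance = 1e-12
  )
  set.seed(7)
  for (i in 1:1000) {
    R <- rotation_matrix(runif(1, -pi, pi), runif(1, -pi, pi), runif(1, -pi, pi))
    expect_lt(max(abs(R %*% t(R) - diag(3))), 1e-12)
    expect_lt(abs(det(R) - 1), 1e-12)
  }
})

test_that("homogeneous transforms translate the origin and compose pointwise", {
  H <- homogeneous_transform(0, 0, 0, c(0, 0, 300))
  expect_equal(H[1:3, 1:3], diag(3))
  expect_equal(H[1:3, 4], c(0, 0, 300))
  set.seed(11)
  for (i in 1:20) {
    o1 <- runif(3, -1, 1)
    d1 <- runif(3, -300, 300)
    o2 <- runif(3, -1, 1)
    d2 <- runif(3, -300, 300)
    H1 <- homogeneous_transform(o1[1], o1[2], o1[3], d1)
    H2 <- homogeneous_transform(o2[1], o2[2], o2[3], d2)
    expect_equal(as.vector(H1 %*% c(0, 0, 0, 1))[1:3], d1)
    # composition equals rotate-then-translate applied twice to a point cloud
    pts <- matrix(runif(15, -100, 100), 3)
    R1 <- rotation_matrix(o1[1], o1[2], o1[3])
    R2 <- rotation_matrix(o2[1], o2[2], o2[3])
    manual <- R1 %*% (R2 %*% pts + d2) + d1
    via_H <- (H1 %*% H2 %*% rbind(pts, 1))[1:3, ]
    expect_equal(via_H, manual, tolerance = 1e-12)
  }
})

test_that("forward kinematics matches a straight chain and the composition oracle", {
  two_link <- body_model(tibble::tibble(
    joint = c("base", "j1", "j2"),
    parent = c(NA, "base", "j1"),
    dx = 0, dy = 0, dz = c(0, 300, 250)
  ))
  idle <- tibble::tibble(joint = two_link$joint, roll = 0, pitch = 0, yaw = 0)
  pose <- forward_kinematics(idle, two_link)
  expect_equal(pose$z, c(0, 300, 550))
  expect_equal(pose$x, c(0, 0, 0))

  # elbow joint pitched 90 degrees, against the independent oracle
  bent <- idle
  bent$pitch[2] <- pi / 2
  pose_b <- forward_kinematics(bent, two_link)
  oracle <- fk_oracle(bent, two_link)
  expect_equal(as.matrix(pose_b[, c("x", "y", "z")]), oracle,
    tolerance = 1e-9, ignore_attr = TRUE
  )
  # +90 pitch about y swings the distal z-link into +x
  expect_equal(pose_b$x[3], 250, tolerance = 1e-9)
  expect_equal(pose_b$z[3], 300, tolerance = 1e-9)

  expect_error(
    forward_kinematics(idle[1:2, ], two_link),
    class = "escalert_parameter_error"
  )
})

test_that("random poses conserve link lengths and agree with the oracle", {
  model <- default_body_model()
  link_len <- sqrt(model$dx^2 + model$dy^2 + model$dz^2)
  set.seed(23)
  for (i in 1:200) {
    o <- random_orientations(model)
    pose <- forward_kinematics(o, model)
    expect_equal(as.matrix(pose[, c("x", "y", "z")]), fk_oracle(o, model),
      tolerance = 1e-9, ignore_attr = TRUE
    )
    for (j in which(!is.na(model$parent))) {
      pj <- match(model$parent[j], model$joint)
      d <- sqrt(sum((pose[j, c("x", "y", "z")] - pose[pj, c("x", "y", "z")])^2))
      expect_equal(d, link_len[j], tolerance = 1e-6)
    }
    # every per-joint rotation stays orthonormal
    for (R in attr(pose, "rotations")) {
      expect_lt(max(abs(R %*% t(R) - diag(3))), 1e-9)
    }
  }
})
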