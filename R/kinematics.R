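# IMU orientation and upper-body forward kinematics.
#
# Conventions: base frame at the spine base, x front, y left, z up; at rest
# the accelerometer reads +1 g opposite gravity, i.e. (0, 0, 1) in the base
# frame. Angles are roll about x, pitch about y, yaw about z, and the
# segment rotation is R = Rz(yaw) %*% Ry(pitch) %*% Rx(roll). Roll and
# pitch are recovered from the gravity direction and yaw from the
# tilt-compensated magnetometer, so no gyroscope integration or fusion
# filter is involved.

#' Tilt-compensated orientation from accelerometer + magnetometer readings
#'
#' Roll and pitch come from the gravity direction
#' (`roll = atan2(accly, acclz)`, `pitch = atan2(-acclx,
#' sqrt(accly^2 + acclz^2))`); yaw comes from the magnetometer after
#' de-rotating roll and pitch. The result is exact (up to noise) whenever
#' the device is quasi-static, roll and pitch are within (-pi/2, pi/2), and
#' the local magnetic field has a nonzero horizontal component pointing
#' magnetic north. Yaw is invariant to overall scaling of either vector.
#'
#' @param samples data frame with columns `acclx, accly, acclz` (g) and
#'   `magx, magy, magz` (any consistent unit), one row per sample.
#' @return tibble with columns `roll`, `pitch`, `yaw` in radians;
#'   roll/pitch in (-pi/2, pi/2), yaw in (-pi, pi].
#' @examples
#' orientation_from_accel_mag(
#'   data.frame(acclx = 0, accly = 0, acclz = 1, magx = 0.5, magy = 0, magz = -0.4)
#' )
#' @export
orientation_from_accel_mag <- function(samples) {
  s <- as_tibble(samples)
  need <- c("acclx", "accly", "acclz", "magx", "magy", "magz")
  miss <- setdiff(need, names(s))
  if (length(miss)) abort_schema(paste("missing columns:", paste(miss, collapse = ", ")))
  a_norm <- sqrt(s$acclx^2 + s$accly^2 + s$acclz^2)
  m_norm <- sqrt(s$magx^2 + s$magy^2 + s$magz^2)
  if (any(!is.na(a_norm) & a_norm == 0)) {
    abort_parameter("degenerate input: zero acceleration vector (orientation undefined)")
  }
  if (any(!is.na(m_norm) & m_norm == 0)) {
    abort_parameter("degenerate input: zero magnetic vector (yaw undefined)")
  }
  roll <- atan2(s$accly, s$acclz)
  pitch <- atan2(-s$acclx, sqrt(s$accly^2 + s$acclz^2))
  sr <- sin(roll)
  cr <- cos(roll)
  sp <- sin(pitch)
  cp <- cos(pitch)
  yaw <- atan2(
    s$magz * sr - s$magy * cr,
    s$magx * cp + s$magy * sp * sr + s$magz * cr * sp
  )
  tibble(roll = roll, pitch = pitch, yaw = yaw)
}

#' Rotation matrix of a roll/pitch/yaw orientation
#'
#' `R = Rz(yaw) %*% Ry(pitch) %*% Rx(roll)` — the intrinsic
#' yaw-pitch-roll convention; always orthonormal with determinant +1.
#'
#' @param roll,pitch,yaw angles in radians. A single orientation; see
#'   [forward_kinematics()] for whole poses.
#' @return a 3x3 rotation matrix.
#' @export
rotation_matrix <- function(roll, pitch, yaw) {
  sr <- sin(roll)
  cr <- cos(roll)
  sp <- sin(pitch)
  cp <- cos(pitch)
  sy <- sin(yaw)
  cy <- cos(yaw)
  matrix(
    c(
      cy * cp, cy * sp * sr - sy * cr, sy * sr + cy * sp * cr,
      sy * cp, sy * sp * sr + cy * cr, sy * sp * cr - cy * sr,
      -sp, cp * sr, cp * cr
    ),
    nrow = 3, byrow = TRUE
  )
}

#' Homogeneous transform from an orientation and a translation
#'
#' @param roll,pitch,yaw angles in radians.
#' @param d length-3 translation vector in mm.
#' @return a 4x4 homogeneous transformation matrix `[R d; 0 1]`.
#' @export
homogeneous_transform <- function(roll, pitch, yaw, d) {
  stopifnot(length(d) == 3L)
  H <- diag(4)
  H[1:3, 1:3] <- rotation_matrix(roll, pitch, yaw)
  H[1:3, 4] <- d
  H
}

#' Define an upper-body joint model
#'
#' A body model is a tree of joints rooted at the spine base: each joint
#' has a parent and a fixed translation `(dx, dy, dz)` in mm expressed in
#' the parent joint's frame (the manually measured link lengths).
#'
#' @param joints data frame with columns `joint`, `parent` (`NA` for the
#'   root), `dx`, `dy`, `dz` (mm).
#' @return a `body_model` tibble.
#' @export
body_model <- function(joints) {
  df <- as_tibble(joints)
  need <- c("joint", "parent", "dx", "dy", "dz")
  if (!all(need %in% names(df))) {
    abort_schema(paste("body model needs columns:", paste(need, collapse = ", ")))
  }
  if (sum(is.na(df$parent)) != 1L) abort_schema("exactly one root joint (parent = NA)")
  unknown <- setdiff(stats::na.omit(df$parent), df$joint)
  if (length(unknown)) {
    abort_schema(paste("parent(s) not defined as joints:", paste(unknown, collapse = ", ")))
  }
  len <- sqrt(df$dx^2 + df$dy^2 + df$dz^2)
  if (any(len[!is.na(df$parent)] <= 0)) abort_schema("link lengths must be > 0")
  # parents must be resolvable before children (tree order)
  structure(df, class = c("body_model", class(df)))
}

#' Default upper-body model
#'
#' Spine base to torso (three stacked back segments), shoulders, elbows and
#' wrists, with link lengths in mm appropriate for a school-age child;
#' replace the lengths with per-garment measured values in practice.
#'
#' @param torso_mm,shoulder_mm,upper_arm_mm,forearm_mm link lengths in mm.
#' @return a [body_model()].
#' @export
default_body_model <- function(torso_mm = 400, shoulder_mm = 150,
                               upper_arm_mm = 250, forearm_mm = 220) {
  body_model(tibble(
    joint = c(
      "spine_base", "torso", "l_shoulder", "r_shoulder",
      "l_elbow", "r_elbow", "l_wrist", "r_wrist"
    ),
    parent = c(
      NA, "spine_base", "torso", "torso",
      "l_shoulder", "r_shoulder", "l_elbow", "r_elbow"
    ),
    dx = 0,
    dy = c(0, 0, shoulder_mm, -shoulder_mm, 0, 0, 0, 0),
    dz = c(0, torso_mm, 0, 0, -upper_arm_mm, -upper_arm_mm, -forearm_mm, -forearm_mm)
  ))
}

#' Reconstruct joint positions by forward kinematics
#'
#' Composes the per-joint homogeneous transforms along each root-to-joint
#' path: the global transform of joint *n* is `H_1 %*% ... %*% H_n` and its
#' position is the translation part. Adjacent-joint distances therefore
#' equal the model's link lengths for every pose (rigid-body property).
#'
#' @param orientations data frame with columns `joint`, `roll`, `pitch`,
#'   `yaw` (radians), one row per model joint.
#' @param model a [body_model()].
#' @return a `skeleton_pose` tibble with columns `joint`, `x`, `y`, `z`
#'   (mm, base frame); per-joint global rotation matrices are attached as
#'   the `rotations` attribute.
#' @export
forward_kinematics <- function(orientations, model) {
  o <- as_tibble(orientations)
  if (!all(c("joint", "roll", "pitch", "yaw") %in% names(o))) {
    abort_schema("orientations need columns joint, roll, pitch, yaw")
  }
  if (!setequal(o$joint, model$joint) || nrow(o) != nrow(model)) {
    abort_parameter("orientation count/names do not match the body model joints")
  }
  o <- o[match(model$joint, o$joint), ]
  H_global <- vector("list", nrow(model))
  names(H_global) <- model$joint
  pos <- matrix(NA_real_, nrow(model), 3)
  for (i in seq_len(nrow(model))) {
    H_i <- homogeneous_transform(
      o$roll[i], o$pitch[i], o$yaw[i],
      c(model$dx[i], model$dy[i], model$dz[i])
    )
    p <- model$parent[i]
    H_global[[i]] <- if (is.na(p)) H_i else H_global[[p]] %*% H_i
    pos[i, ] <- H_global[[i]][1:3, 4]
  }
  structure(
    tibble(joint = model$joint, x = pos[, 1], y = pos[, 2], z = pos[, 3]),
    rotations = purrr::map(H_global, function(H) H[1:3, 1:3]),
    class = c("skeleton_pose", class(tibble()))
  )
}
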