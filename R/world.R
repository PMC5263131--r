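#' Create a 2D pose
#'
#' @param x,y position in meters.
#' @param theta heading in radians, wrapped to (-pi, pi]; theta = 0 points
#'   along +x, positive angles are counterclockwise.
#' @return a named list with class `nl_pose`.
#' @export
pose2d <- function(x = 0, y = 0, theta = 0) {
  stopifnot(is.finite(x), is.finite(y), is.finite(theta))
  structure(list(x = x, y = y, theta = wrap_angle(theta)), class = "nl_pose")
}

#' Build a world
#'
#' Assembles the deterministic 2D world: differential-drive robots carrying
#' a camera (optionally on a pan joint), planar arms, colored screens, and
#' a publish/subscribe topic bus. All dimensions are meters and radians.
#'
#' @param robots named list of robot specs (see [world_robot()]).
#' @param arms named list of arm specs (see [world_arm()]).
#' @param screens named list of screen specs (see [world_screen()]).
#' @param background RGB background color, 0-255.
#' @return an object of class `nl_world`.
#' @export
build_world <- function(robots = list(), arms = list(), screens = list(),
                        background = c(128, 128, 128)) {
  w <- structure(
    list(
      robots = robots, arms = arms, screens = screens,
      background = as.numeric(background),
      bus = list(topics = list()),
      pending = list(),
      time = 0
    ),
    class = "nl_world"
  )
  w$initial <- world_snapshot(w)
  w <- publish_sensors(w)
  w
}

#' Differential-drive robot spec
#'
#' A four-wheeled base reduced to differential-drive (unicycle) kinematics:
#' forward speed v = (vl + vr)/2, turn rate omega = (vr - vl)/track. The
#' camera is mounted at the robot pose, optionally on a pan joint whose
#' angle is positive toward the *right* of the image (screen convention,
#' as used by the eye controller).
#'
#' @param pose initial [pose2d()].
#' @param track track width (m).
#' @param fov horizontal field of view (rad).
#' @param res_x,res_y camera resolution (pixels).
#' @param pan initial camera pan angle (rad, image convention).
#' @return a robot spec list.
#' @export
world_robot <- function(pose = pose2d(), track = 0.4, fov = pi / 2,
                        res_x = 64, res_y = 64, pan = 0) {
  stopifnot(track > 0, res_x >= 1, res_y >= 1, fov > 0)
  list(
    pose = pose, vl = 0, vr = 0, track = track,
    camera = list(fov = fov, width = as.integer(res_x), height = as.integer(res_y)),
    pan = pan, pan_vel = 0, pan_limit = pi / 2
  )
}

#' Planar arm spec
#'
#' Serial revolute chain in the plane; angles advance by commanded joint
#' velocities (or an instantaneous `set_joints` command) and are clamped
#' to the joint limits.
#'
#' @param lengths link lengths (m).
#' @param angles initial joint angles (rad).
#' @param limits matrix with one row per joint, columns lower/upper (rad).
#' @return an arm spec list.
#' @export
world_arm <- function(lengths = c(0.4, 0.3, 0.2), angles = NULL, limits = NULL) {
  n <- length(lengths)
  angles <- angles %||% numeric(n)
  stopifnot(length(angles) == n)
  limits <- limits %||% cbind(rep(-pi, n), rep(pi, n))
  if (any(angles < limits[, 1]) || any(angles > limits[, 2])) abort("initial angles violate joint limits")
  list(lengths = lengths, angles = angles, limits = limits, qdot = numeric(n))
}

#' Screen spec
#'
#' A flat colored screen modeled as an oriented segment of given width with
#' a vertical extent (`height`) used for apparent-size fill in the camera.
#' The displayed content is either a solid color or a pattern: a colored
#' circle on a background (the tracking target), whose center is given in
#' screen fractions.
#'
#' @param center length-2 position (m).
#' @param width,height physical size (m).
#' @param color RGB 0-255 (solid display).
#' @param angle orientation of the screen segment (rad); the default pi/2
#'   makes a screen on the +x axis face a robot at the origin.
#' @param pattern optional list(kind = "circle", background =, fg =,
#'   cx =, cy =, radius =) with cx, cy, radius as fractions of the width.
#' @return a screen spec list.
#' @export
world_screen <- function(center, width = 1, height = NULL, color = c(0, 0, 255),
                         angle = pi / 2, pattern = NULL) {
  stopifnot(width > 0)
  list(
    center = as.numeric(center), width = width, height = height %||% width,
    color = as.numeric(color), angle = angle, pattern = pattern
  )
}

world_snapshot <- function(world) {
  list(
    robots = lapply(world$robots, function(r) r[c("pose", "vl", "vr", "pan", "pan_vel")]),
    arms = lapply(world$arms, function(a) a[c("angles", "qdot")]),
    screens = lapply(world$screens, function(s) s[c("color", "pattern")])
  )
}

# ---------------------------------------------------------------------------
# topic bus

#' Publish a message on the topic bus
#'
#' Latest-value semantics per topic (two publishes in one step: last writer
#' wins) with a monotonically increasing sequence number so subscribers
#' observe messages in publication order.
#'
#' @param world an `nl_world`.
#' @param topic topic name.
#' @param msg message (any R value).
#' @return the updated world.
#' @export
bus_publish <- function(world, topic, msg) {
  ch <- world$bus$topics[[topic]] %||% list(seq = 0L)
  ch$latest <- msg
  ch$seq <- ch$seq + 1L
  world$bus$topics[[topic]] <- ch
  world
}

#' Read the latest message on a topic
#'
#' @param world an `nl_world`.
#' @param topic topic name.
#' @return the latest message, or NULL if nothing was ever published.
#' @export
bus_read <- function(world, topic) world$bus$topics[[topic]]$latest

# command topics understood by the world, with their schemas
command_schema <- function(world, topic) {
  parts <- strsplit(topic, "/", fixed = TRUE)[[1]]
  if (length(parts) != 2) return(NULL)
  id <- parts[1]
  verb <- parts[2]
  if (id %in% names(world$robots) && verb == "wheel_cmd") {
    return(list(target = "robot", id = id, fields = c("left", "right")))
  }
  if (id %in% names(world$robots) && verb == "pan_cmd") {
    return(list(target = "pan", id = id, fields = "vel"))
  }
  if (id %in% names(world$arms) && verb == "joint_vel_cmd") {
    return(list(target = "arm_vel", id = id, fields = "qdot"))
  }
  if (id %in% names(world$arms) && verb == "set_joints") {
    return(list(target = "arm_pos", id = id, fields = "angles"))
  }
  if (id %in% names(world$screens) && verb == "set_target") {
    return(list(target = "screen_target", id = id, fields = c("cx")))
  }
  NULL
}

#' Apply an actuator command
#'
#' Validates the message against the topic's schema and stages it; the
#' command takes effect at the *next* world step, never retroactively.
#' Known command topics: `<robot>/wheel_cmd` (left, right m/s),
#' `<robot>/pan_cmd` (vel rad/s), `<arm>/joint_vel_cmd` (qdot rad/s),
#' `<arm>/set_joints` (angles rad), `<screen>/set_target` (cx, optional cy
#' as width fractions).
#'
#' @param world an `nl_world`.
#' @param topic command topic.
#' @param msg named list matching the schema.
#' @return the updated world.
#' @export
apply_command <- function(world, topic, msg) {
  sch <- command_schema(world, topic)
  if (is.null(sch)) abort(paste0("unknown command topic '", topic, "'"))
  missing <- setdiff(sch$fields, names(msg))
  if (length(missing)) {
    abort(paste0("message on '", topic, "' lacks field(s): ", paste(missing, collapse = ", ")))
  }
  if (!all(vapply(msg, function(v) is.numeric(v) && all(is.finite(v)), logical(1)))) {
    abort(paste0("message on '", topic, "' must be finite numeric"))
  }
  world <- bus_publish(world, topic, msg)
  world$pending[[topic]] <- msg
  world
}

apply_pending <- function(world) {
  for (topic in names(world$pending)) {
    msg <- world$pending[[topic]]
    sch <- command_schema(world, topic)
    if (sch$target == "robot") {
      world$robots[[sch$id]]$vl <- msg$left
      world$robots[[sch$id]]$vr <- msg$right
    } else if (sch$target == "pan") {
      world$robots[[sch$id]]$pan_vel <- msg$vel
    } else if (sch$target == "arm_vel") {
      world$arms[[sch$id]]$qdot <- rep_len(msg$qdot, length(world$arms[[sch$id]]$angles))
    } else if (sch$target == "arm_pos") {
      a <- world$arms[[sch$id]]
      world$arms[[sch$id]]$angles <- clamp(
        rep_len(msg$angles, length(a$angles)), a$limits[, 1], a$limits[, 2]
      )
    } else if (sch$target == "screen_target") {
      s <- world$screens[[sch$id]]
      if (is.null(s$pattern)) abort(paste0("screen '", sch$id, "' has no pattern to move"))
      s$pattern$cx <- msg$cx
      if (!is.null(msg$cy)) s$pattern$cy <- msg$cy
      world$screens[[sch$id]] <- s
    }
  }
  world$pending <- list()
  world
}

# ---------------------------------------------------------------------------
# stepping

#' Advance the world by one timestep
#'
#' Applies staged commands, integrates robot poses with the closed-form
#' unicycle solution (exact for straight lines and arcs, so two steps of dt
#' compose to one step of 2 dt under constant commands), advances arm
#' joints, then republishes every sensor topic (`<robot>/camera`,
#' `<robot>/pose`, `<arm>/joints`, `<arm>/tcp`, `<screen>/target_pos`).
#'
#' @param world an `nl_world`.
#' @param dt timestep in ms.
#' @return the updated world.
#' @export
step_world <- function(world, dt) {
  stopifnot(dt > 0)
  world <- apply_pending(world)
  dts <- dt / 1000
  for (nm in names(world$robots)) {
    r <- world$robots[[nm]]
    v <- (r$vl + r$vr) / 2
    omega <- (r$vr - r$vl) / r$track
    p <- r$pose
    if (abs(omega) < 1e-12) {
      p$x <- p$x + v * dts * cos(p$theta)
      p$y <- p$y + v * dts * sin(p$theta)
    } else {
      th1 <- p$theta + omega * dts
      p$x <- p$x + v / omega * (sin(th1) - sin(p$theta))
      p$y <- p$y - v / omega * (cos(th1) - cos(p$theta))
      p$theta <- wrap_angle(th1)
    }
    r$pose <- p
    r$pan <- clamp(r$pan + r$pan_vel * dts, -r$pan_limit, r$pan_limit)
    world$robots[[nm]] <- r
  }
  for (nm in names(world$arms)) {
    a <- world$arms[[nm]]
    a$angles <- clamp(a$angles + a$qdot * dts, a$limits[, 1], a$limits[, 2])
    world$arms[[nm]] <- a
  }
  world$time <- world$time + dt
  publish_sensors(world)
}

publish_sensors <- function(world) {
  for (nm in names(world$robots)) {
    r <- world$robots[[nm]]
    world <- bus_publish(world, paste0(nm, "/camera"), render_camera(world, nm))
    world <- bus_publish(world, paste0(nm, "/pose"),
                         list(x = r$pose$x, y = r$pose$y, theta = r$pose$theta, pan = r$pan))
  }
  for (nm in names(world$arms)) {
    a <- world$arms[[nm]]
    world <- bus_publish(world, paste0(nm, "/joints"), list(angles = a$angles))
    world <- bus_publish(world, paste0(nm, "/tcp"),
                         list(xy = arm_forward_kinematics(a$angles, a$lengths)))
  }
  for (nm in names(world$screens)) {
    s <- world$screens[[nm]]
    if (!is.null(s$pattern)) {
      world <- bus_publish(world, paste0(nm, "/target_pos"),
                           list(xy = screen_point(s, s$pattern$cx, s$pattern$cy %||% 0.5)))
    }
  }
  world
}

# world coordinates of a point on a screen given fractional coords
screen_point <- function(s, fx, fy = 0.5) {
  d <- c(cos(s$angle), sin(s$angle))
  s$center + (fx - 0.5) * s$width * d
}

#' Planar serial-chain forward kinematics
#'
#' Tool center point of a planar revolute chain: cumulative joint angles,
#' links summed tip to tip.
#'
#' @param angles joint angles (rad).
#' @param lengths link lengths (m), same length as `angles`.
#' @return numeric length-2 TCP position (m).
#' @export
#' @examples
#' arm_forward_kinematics(c(0, 0, 0), c(1, 1, 1)) # c(3, 0)
arm_forward_kinematics <- function(angles, lengths) {
  stopifnot(length(angles) == length(lengths))
  cum <- cumsum(angles)
  c(sum(lengths * cos(cum)), sum(lengths * sin(cum)))
}

#' Change what a screen displays
#'
#' @param world an `nl_world`.
#' @param id screen name.
#' @param color RGB 0-255 (switches the screen to solid display).
#' @return the updated world.
#' @export
set_screen_color <- function(world, id, color) {
  if (!id %in% names(world$screens)) abort(paste0("unknown screen '", id, "'"))
  world$screens[[id]]$color <- as.numeric(color)
  world$screens[[id]]$pattern <- NULL
  world
}

#' @rdname set_screen_color
#' @param pattern a pattern list as in [world_screen()].
#' @export
set_screen_pattern <- function(world, id, pattern) {
  if (!id %in% names(world$screens)) abort(paste0("unknown screen '", id, "'"))
  world$screens[[id]]$pattern <- pattern
  world
}

#' Restore the robot poses recorded at world construction
#'
#' Resets every robot to its initial pose with zeroed velocities and every
#' arm to its initial configuration; screens (the environment) are left
#' untouched — pose, brain and environment are independent reset targets.
#'
#' @param world an `nl_world`.
#' @return the updated world.
#' @export
reset_robot_pose <- function(world) {
  for (nm in names(world$robots)) {
    world$robots[[nm]][c("pose", "vl", "vr", "pan", "pan_vel")] <- world$initial$robots[[nm]]
    world$robots[[nm]]$vl <- 0
    world$robots[[nm]]$vr <- 0
    world$robots[[nm]]$pan_vel <- 0
  }
  for (nm in names(world$arms)) {
    world$arms[[nm]]$angles <- world$initial$arms[[nm]]$angles
    world$arms[[nm]]$qdot <- 0 * world$arms[[nm]]$qdot
  }
  world$pending <- list()
  publish_sensors(world)
}

reset_environment <- function(world) {
  for (nm in names(world$screens)) {
    world$screens[[nm]][c("color", "pattern")] <- world$initial$screens[[nm]]
  }
  publish_sensors(world)
}

# ---------------------------------------------------------------------------
# camera

#' Render the synthetic camera of a robot
#'
#' Equiangular raycast: each pixel column is a ray in the horizontal field
#' of view (column 0 at the left edge); the nearest intersected screen wins
#' and fills the rows inside its apparent height, sampled through the
#' screen's pattern if it has one; everything else is the background color.
#' Identical world state gives a bit-identical image.
#'
#' @param world an `nl_world`.
#' @param robot robot name.
#' @return an integer array `height x width x 3`, RGB 0-255, row-major with
#'   origin top-left, of class `nl_image`.
#' @export
render_camera <- function(world, robot) {
  r <- world$robots[[robot]]
  if (is.null(r)) abort(paste0("unknown robot '", robot, "'"))
  cam <- r$camera
  W <- cam$width
  H <- cam$height
  img <- array(0L, dim = c(H, W, 3))
  for (ch in 1:3) img[, , ch] <- as.integer(world$background[ch])

  heading <- r$pose$theta - r$pan # pan positive = rightward (image convention)
  # column c (1-based): angular offset, positive to the left of heading
  offs <- (0.5 - ((seq_len(W) - 0.5) / W)) * cam$fov
  ray_th <- heading + offs
  dx <- cos(ray_th)
  dy <- sin(ray_th)
  vfov <- cam$fov * H / W
  row_ang <- (0.5 - ((seq_len(H) - 0.5) / H)) * vfov # positive = up

  best_t <- rep(Inf, W)
  best_s <- rep(NA_real_, W)
  best_id <- rep(NA_integer_, W)
  for (si in seq_along(world$screens)) {
    s <- world$screens[[si]]
    e <- c(cos(s$angle), sin(s$angle)) * s$width / 2
    p1 <- s$center - e
    seg <- 2 * e
    # O + t d = p1 + u seg
    det <- dx * (-seg[2]) - dy * (-seg[1])
    ox <- p1[1] - r$pose$x
    oy <- p1[2] - r$pose$y
    t <- (ox * (-seg[2]) + oy * seg[1]) / det
    u <- (dx * oy - dy * ox) / det
    hit <- is.finite(t) & t > 1e-9 & u >= 0 & u <= 1 & t < best_t
    best_t[hit] <- t[hit]
    best_s[hit] <- u[hit]
    best_id[hit] <- si
  }

  for (c_ in which(is.finite(best_t))) {
    s <- world$screens[[best_id[c_]]]
    half_ang <- atan2(s$height / 2, best_t[c_])
    rows <- which(abs(row_ang) <= half_ang)
    if (!length(rows)) next
    if (is.null(s$pattern)) {
      for (ch in 1:3) img[rows, c_, ch] <- as.integer(s$color[ch])
    } else {
      pat <- s$pattern
      fx <- best_s[c_]
      # vertical fraction on the screen: 0 at top
      fy <- 0.5 - (tan(row_ang[rows]) * best_t[c_]) / s$height
      dxm <- (fx - pat$cx) * s$width
      dym <- (fy - (pat$cy %||% 0.5)) * s$height
      inside <- (dxm^2 + dym^2) <= (pat$radius * s$width)^2
      bg <- as.numeric(pat$background)
      fg <- as.numeric(pat$fg)
      for (ch in 1:3) {
        img[rows, c_, ch] <- as.integer(ifelse(inside, fg[ch], bg[ch]))
      }
    }
  }
  structure(img, class = "nl_image")
}
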