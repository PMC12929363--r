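# Shared generators for synthetic test scenes. Everything is seeded by the
# caller; these helpers only build geometry.

hd_intrinsics <- function(f = 915, dist = numeric(5), id = "cam") {
  camera_intrinsics(f, f, 960, 540, dist, 1920, 1080, camera_id = id)
}

# two cameras above the floor looking at the origin, plus floor points
coplanar_two_view <- function(n = 100, az = c(0.3, 1.9), radius = 2.8,
                              height = 2.8, extent = 1.5) {
  P1 <- look_at_pose(c(radius * cos(az[1]), radius * sin(az[1]), height), c(0, 0, 0))
  P2 <- look_at_pose(c(radius * cos(az[2]), radius * sin(az[2]), height), c(0, 0, 0))
  X <- cbind(runif(n, -extent, extent), runif(n, -extent, extent), 0)
  list(P1 = P1, P2 = P2, X = X)
}

# small rig of n cameras on a circle, all seeing a floor grid
small_rig_tracks <- function(n_cam = 6, nx = 30, ny = 15, sigma = 0,
                             f = 915, extent = c(1.5, 0.9)) {
  K <- hd_intrinsics(f)
  poses <- lapply(seq_len(n_cam), function(i)
    look_at_pose(c(2.8 * cos(2 * pi * i / n_cam + 0.2),
                   2.8 * sin(2 * pi * i / n_cam + 0.2), 2.8), c(0, 0, 0)))
  names(poses) <- sprintf("cam%02d", seq_len(n_cam))
  g <- expand.grid(x = seq(-extent[1], extent[1], length.out = nx),
                   y = seq(-extent[2], extent[2], length.out = ny))
  X <- cbind(g$x, g$y, 0)
  obs <- do.call(rbind, lapply(names(poses), function(cid) {
    px <- project_point(K, poses[[cid]], X)
    data.frame(camera_id = cid, marker_id = seq_len(nrow(X)) - 1L,
               x = px[, 1] + rnorm(nrow(X), 0, sigma),
               y = px[, 2] + rnorm(nrow(X), 0, sigma))
  }))
  Ks <- setNames(rep(list(K), n_cam), names(poses))
  list(tracks = build_tracks(obs), intrinsics = Ks, poses = poses, X = X)
}

rot_geodesic_deg <- function(Ra, Rb) rotation_angle(Ra, Rb) * 180 / pi

unit_or_zero <- function(v) {
  n <- sqrt(sum(v^2))
  if (n > 1e-12) v / n else v * 0
}

# physically valid plane-induced homography: camera 2 on the same side of
# the plane as camera 1 (n z-positive convention, plane at distance d)
random_rotation <- msmcalib:::random_rotation

random_plane_homography <- function() {
  repeat {
    R <- random_rotation()
    if (rotation_angle(R) > 1) next
    t <- rnorm(3)
    n <- unit_or_zero(c(rnorm(2) * 0.3, 1))
    d <- runif(1, 1, 3)
    if (d + sum(n * (t(R) %*% t)) > 0.1) break
  }
  list(H = R + t %*% t(n) / d, R = R, t = t, n = n, d = d)
}
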