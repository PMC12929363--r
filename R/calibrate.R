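# Incremental external calibration from observation tracks, in the style of
# incremental SfM but initialized by plane-induced homography decomposition:
# coplanar floor points are degenerate for essential-matrix initialization,
# so the initial pair's relative motion comes from the inter-image
# homography instead. Registration then proceeds camera by camera via PnP,
# triangulation and intermediate bundle adjustment.

default_calib_options <- function(options = list()) {
  modifyList(list(
    seed = 1L,
    ransac_px = 3,              # RANSAC threshold, pixels
    min_shared = 50,            # minimum shared correspondences for the initial pair
    min_pnp_points = 4,
    min_inlier_ratio = 0.3,
    min_tri_angle_deg = 1,      # triangulation filters for new points
    max_tri_reproj_px = 4,
    score_levels = 6L,
    ba_maxit = 200L,            # final bundle adjustment
    ba_tol = 1e-10,
    ba_maxit_intermediate = 30L,
    ba_tol_intermediate = 1e-8,
    retriangulate_every = 3L,
    init_min_tri_frac = 0.6,    # minimum fraction of initial-pair inlier
                                # tracks surviving triangulation filters
    outlier_sigmas = 4,         # post-BA residual rejection
    coplanar = FALSE
  ), options)
}

#' Multi-level view score of a set of image points
#'
#' Measures how many and how uniformly distributed a camera's usable
#' correspondences are: for levels `l = 1..levels` the image is partitioned
#' into `2^l x 2^l` cells and every occupied cell at level `l` contributes
#' weight `2^l`. More points and better spread both increase the score,
#' which orders initial-pair selection and incremental registration.
#'
#' @param px Nx2 matrix of pixel points (0-based).
#' @param width,height image size in pixels.
#' @param levels number of pyramid levels (default 6).
#' @return non-negative scalar score; 0 for no points.
#' @export
view_score <- function(px, width, height, levels = 6L) {
  px <- matrix(px, ncol = 2)
  if (!nrow(px)) return(0)
  score <- 0
  for (l in seq_len(levels)) {
    k <- 2^l
    cellx <- pmin(pmax(floor(px[, 1] / (width / k)), 0), k - 1)
    celly <- pmin(pmax(floor(px[, 2] / (height / k)), 0), k - 1)
    score <- score + k * length(unique(cellx * k + celly))
  }
  score
}

# undistorted observation table with normalized coordinates
prepare_observations <- function(tracks, intrinsics) {
  obs <- tracks$observations
  cams <- unique(obs$camera_id)
  missing <- setdiff(cams, names(intrinsics))
  if (length(missing))
    stop("missing intrinsics for camera(s): ", paste(missing, collapse = ", "))
  obs$xu <- NA_real_; obs$yu <- NA_real_
  obs$xn <- NA_real_; obs$yn <- NA_real_
  for (cid in cams) {
    sel <- obs$camera_id == cid
    K <- intrinsics[[cid]]
    xn <- pixel_to_normalized(K, as.matrix(obs[sel, c("x", "y")]))
    obs$xn[sel] <- xn[, 1]; obs$yn[sel] <- xn[, 2]
    obs$xu[sel] <- xn[, 1] * K$fx + K$cx
    obs$yu[sel] <- xn[, 2] * K$fy + K$cy
  }
  obs
}

ideal_intrinsics <- function(K) {
  camera_intrinsics(K$fx, K$fy, K$cx, K$cy, numeric(5), K$width, K$height,
                    camera_id = K$camera_id)
}

#' Select the initial camera pair
#'
#' Scores every camera pair on the correspondences the two cameras share
#' (their pair-restricted view scores) and returns the pair maximizing the
#' smaller of the two scores. Pairs sharing fewer than `min_shared`
#' correspondences are ineligible; ties break lexicographically.
#'
#' @param tracks an [build_tracks()] object.
#' @param intrinsics named list of [camera_intrinsics()] keyed by camera id.
#' @param min_shared minimum number of shared correspondences.
#' @param levels view-score pyramid depth.
#' @return character vector c(camera_a, camera_b).
#' @export
select_initial_pair <- function(tracks, intrinsics, min_shared = 50, levels = 6L) {
  ranked <- rank_initial_pairs(tracks, intrinsics, min_shared, levels)
  if (!nrow(ranked))
    stop("calibration cannot start: no camera pair shares at least ",
         min_shared, " correspondences")
  c(ranked$camera_a[1], ranked$camera_b[1])
}

# all eligible pairs ordered by decreasing pair-restricted min score,
# ties broken lexicographically
rank_initial_pairs <- function(tracks, intrinsics, min_shared = 50, levels = 6L) {
  obs <- tracks$observations
  cams <- sort(unique(obs$camera_id))
  if (length(cams) < 2) stop("calibration cannot start: need at least 2 cameras")
  bycam <- split(obs, obs$camera_id)
  rows <- list()
  for (i in seq_along(cams)) for (j in seq_along(cams)) {
    if (j <= i) next
    a <- cams[i]; b <- cams[j]
    shared <- intersect(bycam[[a]]$marker_id, bycam[[b]]$marker_id)
    if (length(shared) < min_shared) next
    oa <- bycam[[a]]; oa <- oa[oa$marker_id %in% shared, ]
    ob <- bycam[[b]]; ob <- ob[ob$marker_id %in% shared, ]
    Ka <- intrinsics[[a]]; Kb <- intrinsics[[b]]
    sa <- view_score(as.matrix(oa[, c("x", "y")]), Ka$width, Ka$height, levels)
    sb <- view_score(as.matrix(ob[, c("x", "y")]), Kb$width, Kb$height, levels)
    rows[[length(rows) + 1]] <- data.frame(camera_a = a, camera_b = b,
                                           score = min(sa, sb),
                                           n_shared = length(shared))
  }
  if (!length(rows))
    return(data.frame(camera_a = character(), camera_b = character(),
                      score = numeric(), n_shared = integer()))
  out <- do.call(rbind, rows)
  out[order(-out$score, out$camera_a, out$camera_b), , drop = FALSE]
}

#' Initialize the reconstruction from one camera pair
#'
#' Places `camera_a` at the identity and estimates `camera_b`'s relative
#' motion by robust inter-image homography estimation followed by analytic
#' homography decomposition (the rigorous route for coplanar scene points),
#' fixing the provisional gauge with a unit baseline. Inlier tracks are
#' triangulated as the initial scene points.
#'
#' @param camera_a,camera_b camera ids.
#' @param tracks an [build_tracks()] object.
#' @param intrinsics named list of [camera_intrinsics()].
#' @param options options list, see [calibrate()].
#' @return a `reconstruction` object.
#' @export
initialize_pair <- function(camera_a, camera_b, tracks, intrinsics,
                            options = list()) {
  opts <- default_calib_options(options)
  obs <- prepare_observations(tracks, intrinsics)
  rec <- structure(list(
    obs = obs,
    intrinsics = intrinsics,
    K_ideal = lapply(intrinsics, ideal_intrinsics),
    poses = list(),
    registered = character(),
    points = matrix(numeric(), 0, 3),
    opts = opts,
    seed_k = 0L,
    n_registrations = 0L,
    log = character()
  ), class = "reconstruction")

  oa <- obs[obs$camera_id == camera_a, ]
  ob <- obs[obs$camera_id == camera_b, ]
  shared <- intersect(oa$marker_id, ob$marker_id)
  if (length(shared) < 4) stop("initialization error: fewer than 4 shared correspondences")
  oa <- oa[match(shared, oa$marker_id), ]
  ob <- ob[match(shared, ob$marker_id), ]
  x1 <- cbind(oa$xn, oa$yn); x2 <- cbind(ob$xn, ob$yn)
  hr <- estimate_homography_ransac(x1, x2, opts$ransac_px,
                                   intrinsics[[camera_a]], intrinsics[[camera_b]],
                                   seed = derive_seed(opts$seed, 1))
  cands <- decompose_homography(hr$H)
  sel <- select_decomposition(cands, x1[hr$inliers, , drop = FALSE],
                              x2[hr$inliers, , drop = FALSE])
  if (vnorm(sel$t) < 1e-9)
    stop("initialization error: no-parallax pair (pure rotation), zero baseline")
  rec$poses[[camera_a]] <- camera_pose()
  rec$poses[[camera_b]] <- camera_pose(sel$R, unit(sel$t))
  rec$registered <- c(camera_a, camera_b)
  # scale gauge: freeze the largest translation coordinate of camera_b
  rec$fixed_coord_cam <- camera_b
  rec$fixed_coord_idx <- 3L + which.max(abs(unit(sel$t)))
  rec$log <- c(rec$log, sprintf(
    "init pair (%s, %s): %d/%d homography inliers", camera_a, camera_b,
    sum(hr$inliers), length(shared)))
  rec <- triangulate_new_points(rec, restrict = shared[hr$inliers])
  rec$init_stats <- list(n_inliers = sum(hr$inliers),
                         n_triangulated = nrow(rec$points))
  if (nrow(rec$points) < 4)
    stop("initialization error: fewer than 4 triangulated points survive the filters")
  # two-view refinement: polish the decomposition-based relative pose
  bundle_adjust(rec, coplanar = FALSE, maxit = opts$ba_maxit_intermediate,
                tol = opts$ba_tol_intermediate)
}

#' @export
print.reconstruction <- function(x, ...) {
  cat(sprintf("reconstruction: %d/%d cameras registered, %d points\n",
              length(x$registered), length(unique(x$obs$camera_id)),
              nrow(x$points)))
  invisible(x)
}

# triangulate all not-yet-reconstructed tracks observable by >= 2 registered
# cameras, applying the admission filters
triangulate_new_points <- function(rec, restrict = NULL) {
  opts <- rec$opts
  obs <- rec$obs[rec$obs$camera_id %in% rec$registered, ]
  have <- rownames(rec$points)
  cand <- setdiff(unique(obs$marker_id), as.integer(have))
  if (!is.null(restrict)) cand <- intersect(cand, restrict)
  obs <- obs[obs$marker_id %in% cand, ]
  if (!nrow(obs)) return(rec)
  cnt <- table(obs$marker_id)
  cand <- as.integer(names(cnt)[cnt >= 2])
  obs <- obs[obs$marker_id %in% cand, ]
  if (!nrow(obs)) return(rec)
  cam_idx <- match(obs$camera_id, rec$registered)
  tri <- triangulate_batch(rec$poses[rec$registered],
                           data.frame(cam = cam_idx, pt = obs$marker_id,
                                      xn1 = obs$xn, xn2 = obs$yn),
                           cand)
  centers <- t(vapply(rec$poses[rec$registered], pose_center, numeric(3)))
  keep <- logical(length(cand))
  for (j in seq_along(cand)) {
    if (!tri$ok[j]) next
    X <- tri$X[j, ]
    rows <- which(obs$marker_id == cand[j])
    cs <- centers[cam_idx[rows], , drop = FALSE]
    if (triangulation_angle(X, cs) < opts$min_tri_angle_deg * pi / 180) next
    # reprojection filter (undistorted pixel domain)
    ok <- TRUE
    for (r in rows) {
      cid <- obs$camera_id[r]
      pr <- project_points_depth(rec$K_ideal[[cid]], rec$poses[[cid]], X,
                                 distorted = FALSE)
      if (pr$depth <= 0 ||
          sqrt((pr$px[1] - obs$xu[r])^2 + (pr$px[2] - obs$yu[r])^2) >
          opts$max_tri_reproj_px) { ok <- FALSE; break }
    }
    keep[j] <- ok
  }
  if (any(keep)) {
    newX <- tri$X[keep, , drop = FALSE]
    rownames(newX) <- as.character(cand[keep])
    rec$points <- rbind(rec$points, newX)
  }
  rec
}

#' Register the next camera
#'
#' Selects the unregistered camera with the highest view score on
#' correspondences with already-triangulated points, estimates its pose by
#' robust PnP, triangulates newly observable tracks, and runs an
#' intermediate bundle adjustment over all registered cameras. Every
#' `retriangulate_every`-th registration re-attempts previously rejected
#' tracks.
#'
#' @param rec a `reconstruction` from [initialize_pair()].
#' @return the updated reconstruction; attribute `registered` carries the
#'   camera id, or `NULL` if no eligible camera remains (attribute
#'   `unregistered` lists the leftovers).
#' @export
register_next <- function(rec) {
  opts <- rec$opts
  all_cams <- unique(rec$obs$camera_id)
  todo <- setdiff(all_cams, rec$registered)
  if (!length(todo)) {
    attr(rec, "registered") <- NULL
    attr(rec, "unregistered") <- character()
    return(rec)
  }
  have_ids <- as.integer(rownames(rec$points))
  best <- NULL; best_score <- -Inf
  for (cid in sort(todo)) {
    oc <- rec$obs[rec$obs$camera_id == cid & rec$obs$marker_id %in% have_ids, ]
    if (nrow(oc) < opts$min_pnp_points) next
    K <- rec$intrinsics[[cid]]
    sc <- view_score(as.matrix(oc[, c("x", "y")]), K$width, K$height,
                     opts$score_levels)
    if (sc > best_score) { best_score <- sc; best <- cid }
  }
  if (is.null(best)) {
    attr(rec, "registered") <- NULL
    attr(rec, "unregistered") <- todo
    return(rec)
  }
  # try candidate cameras in descending score order; a camera whose robust
  # PnP fails is skipped (it may become registrable after later BAs)
  cand_order <- names(sort(vapply(sort(todo), function(cid) {
    oc <- rec$obs[rec$obs$camera_id == cid & rec$obs$marker_id %in% have_ids, ]
    if (nrow(oc) < opts$min_pnp_points) return(-Inf)
    K <- rec$intrinsics[[cid]]
    view_score(as.matrix(oc[, c("x", "y")]), K$width, K$height,
               opts$score_levels)
  }, numeric(1)), decreasing = TRUE))
  pn <- NULL; cid <- NULL
  for (cand in cand_order) {
    oc <- rec$obs[rec$obs$camera_id == cand & rec$obs$marker_id %in% have_ids, ]
    if (nrow(oc) < opts$min_pnp_points) next
    X <- rec$points[as.character(oc$marker_id), , drop = FALSE]
    rec$seed_k <- rec$seed_k + 1L
    pn <- tryCatch(
      pnp_ransac(rec$K_ideal[[cand]], X, cbind(oc$xu, oc$yu),
                 threshold_px = opts$ransac_px,
                 seed = derive_seed(opts$seed, 100 + rec$seed_k),
                 min_inlier_ratio = opts$min_inlier_ratio),
      error = function(e) NULL)
    if (!is.null(pn)) { cid <- cand; break }
    rec$log <- c(rec$log, sprintf("registration of %s deferred (PnP failed)", cand))
  }
  if (is.null(pn)) {
    attr(rec, "registered") <- NULL
    attr(rec, "unregistered") <- todo
    return(rec)
  }
  oc <- rec$obs[rec$obs$camera_id == cid & rec$obs$marker_id %in% have_ids, ]
  rec$poses[[cid]] <- pn$pose
  rec$registered <- c(rec$registered, cid)
  rec$n_registrations <- rec$n_registrations + 1L
  rec$log <- c(rec$log, sprintf("registered %s: %d/%d PnP inliers, score %.0f",
                                cid, sum(pn$inliers), nrow(oc), best_score))
  rec <- triangulate_new_points(rec)
  if (rec$n_registrations %% opts$retriangulate_every == 0L) {
    rec <- triangulate_new_points(rec)  # re-attempt previously rejected tracks
  }
  rec <- bundle_adjust(rec, coplanar = FALSE,
                       maxit = opts$ba_maxit_intermediate,
                       tol = opts$ba_tol_intermediate)
  attr(rec, "registered") <- cid
  rec
}

#' Bundle adjustment over a reconstruction
#'
#' Jointly refines all registered camera poses and scene points by
#' minimizing the summed squared reprojection error (intrinsics fixed).
#' The gauge is fixed by freezing the first camera's pose and one
#' translation coordinate of the initial pair's second camera (the scale).
#' With `coplanar = TRUE`, points are reparametrized as 2D coordinates in a
#' floor plane fitted by total least squares and refined jointly with the
#' poses (a hard constraint, not a penalty).
#'
#' @param rec a `reconstruction`.
#' @param coplanar enforce the floor-coplanarity constraint.
#' @param maxit,tol Levenberg-Marquardt iteration cap and relative objective
#'   change tolerance.
#' @return the reconstruction with refined poses and points; attributes
#'   `ba_objective`, `ba_converged` report the final state.
#' @export
bundle_adjust <- function(rec, coplanar = FALSE, maxit = rec$opts$ba_maxit,
                          tol = rec$opts$ba_tol) {
  if (length(rec$registered) < 2) stop("bundle adjustment needs >= 2 registered cameras")
  have_ids <- as.integer(rownames(rec$points))
  obs <- rec$obs[rec$obs$camera_id %in% rec$registered &
                 rec$obs$marker_id %in% have_ids, ]
  cnt <- table(obs$marker_id)
  ok_ids <- as.integer(names(cnt)[cnt >= 2])
  obs <- obs[obs$marker_id %in% ok_ids, ]
  pt_idx <- match(obs$marker_id, ok_ids)
  cam_idx <- match(obs$camera_id, rec$registered)
  X <- rec$points[as.character(ok_ids), , drop = FALSE]
  fixed_coord <- NULL
  fc <- match(rec$fixed_coord_cam %||% NA, rec$registered)
  if (!is.na(fc) && fc > 1) fixed_coord <- c(fc, rec$fixed_coord_idx)
  ba_obs <- data.frame(cam = cam_idx, pt = pt_idx, x = obs$xu, y = obs$yu)
  Ks <- rec$K_ideal[rec$registered]
  if (coplanar) {
    pf <- fit_plane_tls(X)
    uv <- X %*% pf$Fm[, 1:2]
    res <- ba_core(ba_obs, rec$poses[rec$registered], Ks,
                   list(uv = uv, plane = pf), model = "plane",
                   fixed_cams = 1L, fixed_coord = fixed_coord,
                   maxit = maxit, tol = tol)
    Fm <- res$structure$plane$Fm; d <- res$structure$plane$d
    Xn <- res$structure$uv %*% t(Fm[, 1:2, drop = FALSE]) +
      matrix(d * Fm[, 3], nrow(X), 3, byrow = TRUE)
    rec$on_floor <- TRUE
    rec$plane <- res$structure$plane
  } else {
    res <- ba_core(ba_obs, rec$poses[rec$registered], Ks,
                   list(X = X), model = "free",
                   fixed_cams = 1L, fixed_coord = fixed_coord,
                   maxit = maxit, tol = tol)
    Xn <- res$structure$X
    rec$on_floor <- FALSE
  }
  rownames(Xn) <- as.character(ok_ids)
  rec$points <- Xn
  for (i in seq_along(rec$registered))
    rec$poses[[rec$registered[i]]] <- res$cams[[i]]
  attr(rec, "ba_objective") <- res$objective
  attr(rec, "ba_converged") <- res$converged
  rec$log <- c(rec$log, sprintf("BA(%s): obj %.6g after %d iters",
                                if (coplanar) "plane" else "free",
                                res$objective, res$n_iter))
  rec
}

# total least squares plane fit; returns frame Fm = [e1 e2 n] and offset d
# with the normal oriented so d >= 0
fit_plane_tls <- function(X) {
  mu <- colMeans(X)
  sv <- svd(sweep(X, 2, mu), nu = 0)
  n <- sv$v[, 3]
  d <- sum(n * mu)
  if (d < 0) { n <- -n; d <- -d }
  e1 <- sv$v[, 1]; e2 <- cross3(n, e1)
  Fm <- cbind(e1, e2, n)
  if (det(Fm) < 0) { e2 <- -e2; Fm <- cbind(e1, e2, n) }
  list(Fm = Fm, d = d)
}

# per-observation residuals in the undistorted pixel domain
reconstruction_residuals <- function(rec) {
  have_ids <- as.integer(rownames(rec$points))
  obs <- rec$obs[rec$obs$camera_id %in% rec$registered &
                 rec$obs$marker_id %in% have_ids, ]
  du <- dv <- numeric(nrow(obs))
  for (cid in rec$registered) {
    sel <- which(obs$camera_id == cid)
    if (!length(sel)) next
    X <- rec$points[as.character(obs$marker_id[sel]), , drop = FALSE]
    pr <- project_points_depth(rec$K_ideal[[cid]], rec$poses[[cid]], X,
                               distorted = FALSE)
    du[sel] <- pr$px[, 1] - obs$xu[sel]
    dv[sel] <- pr$px[, 2] - obs$yu[sel]
    bad <- pr$depth <= 0
    du[sel][bad] <- Inf; dv[sel][bad] <- Inf
  }
  data.frame(camera_id = obs$camera_id, marker_id = obs$marker_id,
             du = du, dv = dv, enorm = sqrt(du^2 + dv^2))
}

#' Calibrate a multi-camera system from observation tracks
#'
#' The full incremental pipeline: initial-pair selection by pair-restricted
#' view scores, homography-decomposition initialization, incremental PnP
#' registration with intermediate bundle adjustment, a final bundle
#' adjustment, one robust outlier-rejection pass, and a concluding bundle
#' adjustment (optionally with the floor-coplanarity constraint).
#'
#' @param tracks an [build_tracks()] object (>= 2 cameras).
#' @param intrinsics named list of [camera_intrinsics()] keyed by camera id.
#' @param options list of options overriding the defaults: `seed` (RNG seed
#'   for all robust stages), `coplanar` (constrain points to a fitted floor
#'   plane in the final refinement), `ransac_px`, `min_shared`,
#'   `min_tri_angle_deg`, `max_tri_reproj_px`, `outlier_sigmas`, and the
#'   bundle-adjustment controls `ba_maxit`/`ba_tol`.
#' @return an object of class `calibration_result`: estimated poses, scene
#'   points, per-observation residuals, per-camera mean reprojection errors,
#'   registered/unregistered camera lists and a gauge description.
#' @export
calibrate <- function(tracks, intrinsics, options = list()) {
  opts <- default_calib_options(options)
  ranked <- rank_initial_pairs(tracks, intrinsics, opts$min_shared,
                               opts$score_levels)
  if (!nrow(ranked))
    stop("calibration cannot start: no camera pair shares at least ",
         opts$min_shared, " correspondences")
  # walk the ranked pairs: a pair whose decomposition fails or whose inlier
  # tracks mostly die in the triangulation filters (weak baseline) is
  # skipped in favor of the next-best pair
  rec <- NULL
  for (k in seq_len(min(nrow(ranked), 10L))) {
    cand <- tryCatch(
      initialize_pair(ranked$camera_a[k], ranked$camera_b[k], tracks,
                      intrinsics, opts),
      error = function(e) NULL)
    if (is.null(cand)) next
    frac <- cand$init_stats$n_triangulated / cand$init_stats$n_inliers
    if (frac < opts$init_min_tri_frac && k < nrow(ranked)) next
    rec <- cand
    break
  }
  if (is.null(rec))
    stop("calibration cannot start: no candidate pair initialized successfully")
  unregistered <- character()
  repeat {
    rec <- register_next(rec)
    done <- is.null(attr(rec, "registered"))
    if (done) { unregistered <- attr(rec, "unregistered"); break }
  }
  rec <- bundle_adjust(rec, coplanar = FALSE)
  # robust outlier pass: drop observations beyond outlier_sigmas robust sigmas
  res <- reconstruction_residuals(rec)
  scale <- 1.4826 * median(res$enorm)
  thr <- opts$outlier_sigmas * max(scale, 1e-12)
  drop <- res$enorm > thr
  n_out <- sum(drop)
  if (n_out) {
    key_obs <- paste(rec$obs$camera_id, rec$obs$marker_id)
    key_out <- paste(res$camera_id[drop], res$marker_id[drop])
    rec$obs <- rec$obs[!key_obs %in% key_out, ]
    rec$log <- c(rec$log, sprintf("outlier pass: removed %d observations (thr %.3g px)",
                                  n_out, thr))
  }
  rec <- bundle_adjust(rec, coplanar = opts$coplanar)
  res <- reconstruction_residuals(rec)
  per_cam <- tapply(res$enorm, res$camera_id, mean)
  out <- structure(list(
    poses = rec$poses[rec$registered],
    points = data.frame(marker_id = as.integer(rownames(rec$points)),
                        X = rec$points[, 1], Y = rec$points[, 2],
                        Z = rec$points[, 3],
                        on_floor = isTRUE(rec$on_floor), row.names = NULL),
    residuals = res,
    mean_reproj_px = setNames(as.numeric(per_cam), names(per_cam)),
    registered = rec$registered,
    unregistered = unregistered,
    n_outliers_removed = n_out,
    gauge = paste("first registered camera at identity;",
                  "scale fixed by freezing one translation coordinate of the",
                  "initial pair's second camera (unit baseline at initialization)"),
    options = opts,
    log = rec$log,
    reconstruction = rec
  ), class = "calibration_result")
  out
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("calibration_result: %d cameras registered (%d unregistered), %d points\n",
              length(x$registered), length(x$unregistered), nrow(x$points)))
  cat(sprintf("  mean reprojection error: %.4g px (overall)\n",
              mean(x$residuals$enorm)))
  for (cid in names(x$mean_reproj_px))
    cat(sprintf("    %s: %.4g px\n", cid, x$mean_reproj_px[[cid]]))
  cat("  gauge:", x$gauge, "\n")
  invisible(x)
}
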