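# Configuration and artifact I/O. All outputs are plain text: YAML configs,
# CSV tables, JSON reports, and a pose file format that states its
# convention in the header. Numeric fields are written with full precision
# (%.17g) so that reruns with the same seed are byte-identical.

fmt_num <- function(x) sprintf("%.17g", x)

#' Read per-camera intrinsics from a YAML config
#'
#' The file holds a `cameras:` list, one block per camera with fields
#' camera_id, fx, fy, cx, cy, dist (list, `(k1, k2, p1, p2, k3)` order),
#' width, height. All invariants of [camera_intrinsics()] are enforced;
#' violations name the offending camera.
#'
#' @param path YAML file path.
#' @return named list of [camera_intrinsics()] keyed by camera id.
#' @export
load_intrinsics <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$cameras)) stop("intrinsics config: missing 'cameras' list")
  out <- list()
  for (cam in cfg$cameras) {
    cid <- cam$camera_id %||% "<unnamed>"
    need <- c("fx", "fy", "cx", "cy", "width", "height")
    miss <- need[!need %in% names(cam)]
    if (length(miss))
      stop(sprintf("intrinsics config: camera '%s' missing field(s): %s",
                   cid, paste(miss, collapse = ", ")))
    K <- tryCatch(
      camera_intrinsics(cam$fx, cam$fy, cam$cx, cam$cy,
                        as.numeric(unlist(cam$dist %||% numeric(0))),
                        cam$width, cam$height, camera_id = cid),
      error = function(e)
        stop(sprintf("intrinsics config: camera '%s': %s", cid,
                     conditionMessage(e))))
    out[[cid]] <- K
  }
  out
}

#' Write per-camera intrinsics to a YAML config
#'
#' @param intrinsics named list of [camera_intrinsics()].
#' @param path output YAML path.
#' @return the path, invisibly.
#' @export
save_intrinsics <- function(intrinsics, path) {
  ids <- names(intrinsics) %||%
    vapply(intrinsics, `[[`, character(1), "camera_id")
  cams <- lapply(seq_along(intrinsics), function(i) {
    K <- intrinsics[[i]]
    list(camera_id = ids[i], fx = K$fx, fy = K$fy, cx = K$cx, cy = K$cy,
         dist = as.list(K$dist), width = K$width, height = K$height)
  })
  yaml::write_yaml(list(
    convention = "pixels are 0-based pixel centers, x right, y down; dist order (k1,k2,p1,p2,k3)",
    cameras = unname(cams)), path)
  invisible(path)
}

#' Write camera poses to a plain-text file
#'
#' One line per camera: camera id, the row-major 3x3 rotation and the
#' translation, in the world-to-camera convention (`x_cam = R X + t`),
#' stated in the header. Full double precision, so identical poses produce
#' byte-identical files.
#'
#' @param poses named list of [camera_pose()].
#' @param path output path.
#' @param seed optional seed recorded in the header.
#' @return the path, invisibly.
#' @export
save_poses <- function(poses, path, seed = NULL) {
  lines <- c("# camera poses",
             "# convention: world-to-camera, x_cam = R %*% X + t; R row-major",
             "# fields: camera_id r11 r12 r13 r21 r22 r23 r31 r32 r33 tx ty tz")
  if (!is.null(seed)) lines <- c(lines, sprintf("# seed: %d", as.integer(seed)))
  for (cid in names(poses)) {
    P <- poses[[cid]]
    lines <- c(lines, paste(cid, paste(fmt_num(c(t(P$R), P$t)), collapse = " ")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read camera poses written by [save_poses()]
#'
#' @param path pose file path.
#' @return named list of [camera_pose()].
#' @export
load_poses <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 13) stop("pose file: malformed line: ", ln)
    v <- as.numeric(parts[-1])
    out[[parts[1]]] <- camera_pose(matrix(v[1:9], 3, 3, byrow = TRUE), v[10:12])
  }
  out
}

#' Write and read observation/track tables
#'
#' Plain CSV with one header row; coordinates are 0-based pixel centers.
#'
#' @param observations data frame (camera_id, marker_id, x, y, ...).
#' @param path CSV path.
#' @return `save_observations`: the path, invisibly; `load_observations`:
#'   an [build_tracks()] object.
#' @export
save_observations <- function(observations, path) {
  write.csv(observations, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname save_observations
#' @export
load_observations <- function(path) {
  build_tracks(read.csv(path, stringsAsFactors = FALSE))
}

#' Write a projection schedule descriptor
#'
#' @param schedule a [make_schedule()] object.
#' @param path output YAML path.
#' @return the path, invisibly.
#' @export
save_schedule <- function(schedule, path) {
  yaml::write_yaml(list(
    projector_resolution = schedule$projector_resolution,
    scales = schedule$scales,
    base_side_m = schedule$base_side,
    px_per_m = schedule$px_per_m,
    slot_duration_s = schedule$slot_duration,
    n_arrays = schedule$n_arrays,
    markers_per_array = schedule$markers_per_array,
    grid = c(schedule$grid_nx, schedule$grid_ny),
    margin_px = schedule$margin_px,
    offset_grid = schedule$offset_grid), path)
  invisible(path)
}

#' Read a projection schedule descriptor
#'
#' @param path YAML path written by [save_schedule()].
#' @return a [make_schedule()] object (markers regenerated from the layout).
#' @export
load_schedule <- function(path) {
  s <- yaml::read_yaml(path)
  make_schedule(n_arrays = s$n_arrays, markers_per_array = s$markers_per_array,
                scales = as.numeric(unlist(s$scales)),
                projector_resolution = as.numeric(unlist(s$projector_resolution)),
                base_side = s$base_side_m, px_per_m = s$px_per_m,
                grid_nx = s$grid[[1]], grid_ny = s$grid[[2]],
                margin_px = s$margin_px, offset_grid = s$offset_grid,
                slot_duration = s$slot_duration_s)
}

#' Save calibration outputs
#'
#' Writes the pose file, the points table, the residuals table and a JSON
#' run summary (per-camera mean reprojection error, registration order,
#' seed, gauge) into `dir`.
#'
#' @param result a `calibration_result` from [calibrate()].
#' @param dir output directory (created if absent).
#' @return invisible list of written paths.
#' @export
save_calibration <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    poses = file.path(dir, "poses.txt"),
    points = file.path(dir, "points.csv"),
    residuals = file.path(dir, "residuals.csv"),
    summary = file.path(dir, "summary.json"))
  save_poses(result$poses, paths$poses, seed = result$options$seed)
  write.csv(result$points, paths$points, row.names = FALSE, quote = FALSE)
  write.csv(result$residuals, paths$residuals, row.names = FALSE, quote = FALSE)
  summary <- list(
    seed = result$options$seed,
    coplanar = isTRUE(result$options$coplanar),
    registered = result$registered,
    unregistered = result$unregistered,
    registration_log = result$log,
    mean_reproj_px = as.list(result$mean_reproj_px),
    overall_mean_reproj_px = mean(result$residuals$enorm),
    n_points = nrow(result$points),
    n_outliers_removed = result$n_outliers_removed,
    gauge = result$gauge)
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

#' Run the full pipeline from a configuration
#'
#' Stages: load intrinsics, obtain observations (a detections table, a
#' frames directory, or a precomputed observations CSV), build tracks,
#' calibrate, and write every stage artifact plus a manifest (seed, config
#' hash, package version) into the output directory. Stage failures abort
#' with the stage name; artifacts of completed stages are retained.
#'
#' @param config list (or path of a YAML file) with fields: `intrinsics`
#'   (path), one of `observations` (CSV path), `detections` (CSV path) or
#'   `frames` (directory with `<camera_id>/frame_<idx>.png`), optional
#'   `schedule` (path), `out` (output directory), and `options` passed to
#'   [calibrate()].
#' @return the `calibration_result`, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out %||% "calibration_out"
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  intr <- stage("intrinsics", {
    stopifnot(!is.null(config$intrinsics), file.exists(config$intrinsics))
    load_intrinsics(config$intrinsics)
  })
  schedule <- if (!is.null(config$schedule))
    stage("schedule", load_schedule(config$schedule)) else NULL
  tracks <- stage("observations", {
    if (!is.null(config$observations)) {
      stopifnot(file.exists(config$observations))
      load_observations(config$observations)
    } else if (!is.null(config$detections)) {
      stopifnot(file.exists(config$detections))
      det <- read.csv(config$detections, stringsAsFactors = FALSE)
      build_tracks(detections_to_observations(det, schedule))
    } else if (!is.null(config$frames)) {
      det <- detect_directory(config$frames)
      build_tracks(detections_to_observations(det, schedule))
    } else stop("configuration error: no observations, detections or frames input")
  })
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  save_observations(tracks$observations, file.path(out_dir, "observations.csv"))
  result <- stage("calibrate", calibrate(tracks, intr, config$options %||% list()))
  save_calibration(result, out_dir)
  cfg_for_hash <- config[setdiff(names(config), "log_level")]
  manifest <- list(
    package = "msmcalib",
    version = as.character(utils::packageVersion("msmcalib")),
    seed = (config$options %||% list())$seed %||% 1L,
    config_hash = fnv1a_hex(paste(deparse(cfg_for_hash), collapse = "")),
    stages = c("intrinsics", "observations", "calibrate"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(result)
}

#' Detect markers in a directory of per-camera frames
#'
#' Expects `dir/<camera_id>/frame_<idx>.png`; returns the combined raw
#' detection table.
#'
#' @param dir root frames directory.
#' @return data frame as [detect_frame()] plus camera_id, frame_idx.
#' @export
detect_directory <- function(dir) {
  cams <- list.dirs(dir, recursive = FALSE)
  out <- list()
  for (cd in cams) {
    cid <- basename(cd)
    files <- sort(list.files(cd, pattern = "^frame_\\d+\\.png$", full.names = TRUE))
    for (f in files) {
      idx <- as.integer(sub("^frame_(\\d+)\\.png$", "\\1", basename(f)))
      det <- detect_frame(f)
      if (nrow(det)) {
        det$camera_id <- cid
        det$frame_idx <- idx
        out[[length(out) + 1]] <- det
      }
    }
  }
  if (!length(out))
    return(data.frame(camera_id = character(), frame_idx = integer(),
                      symbol_id = integer(), decode_confidence = numeric(),
                      x1 = numeric(), y1 = numeric(), x2 = numeric(), y2 = numeric(),
                      x3 = numeric(), y3 = numeric(), x4 = numeric(), y4 = numeric()))
  do.call(rbind, out)
}

#' Generate an on-disk synthetic fixture dataset
#'
#' Renders a reduced projection schedule (9 arrays x 8 MSMs, 3 scales on a
#' small projector footprint) seen by a 5-camera rig -- four wide cameras
#' and one long-focal close-up camera emulating the large scale gap between
#' far-field and zoomed views -- and writes PNG frames, the ground-truth
#' poses, the intrinsics config and the schedule descriptor. The wide
#' cameras resolve only the larger marker scales while the close-up camera
#' sees the smallest: exactly the multi-scale situation the markers exist
#' for.
#'
#' @param dir output directory.
#' @param seed RNG seed (camera placement jitter).
#' @return list with `dir`, `schedule`, `intrinsics`, `gt_poses`, `g_proj`,
#'   and the per-camera/per-frame visibility metadata.
#' @export
make_fixture <- function(dir = tempfile("msm_fixture_"), seed = 1L) {
  schedule <- fixture_schedule()
  g_proj <- projector_floor_homography(800, schedule$projector_resolution)
  rigdef <- fixture_rig(seed)
  intr <- lapply(rigdef, `[[`, "K")
  names(intr) <- vapply(rigdef, `[[`, character(1), "camera_id")
  poses <- lapply(rigdef, `[[`, "pose")
  names(poses) <- names(intr)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  save_intrinsics(intr, file.path(dir, "intrinsics.yaml"))
  save_poses(poses, file.path(dir, "gt_poses.txt"), seed = seed)
  save_schedule(schedule, file.path(dir, "schedule.yaml"))
  meta <- list()
  nsc <- length(schedule$scales)
  for (cid in names(intr)) {
    cdir <- file.path(dir, cid)
    dir.create(cdir, showWarnings = FALSE)
    for (a in seq_len(schedule$n_arrays) - 1L) {
      for (si in seq_len(nsc)) {
        fr <- render_camera_view(schedule, a, si, g_proj,
                                 intr[[cid]], poses[[cid]])
        frame_idx <- a * nsc + (si - 1L)
        png::writePNG(fr$image,
                      file.path(cdir, sprintf("frame_%04d.png", frame_idx)))
        m <- fr$markers
        m$camera_id <- cid; m$frame_idx <- frame_idx; m$scale_idx <- si
        meta[[length(meta) + 1]] <- m
      }
    }
  }
  list(dir = dir, schedule = schedule, intrinsics = intr, gt_poses = poses,
       g_proj = g_proj, meta = do.call(rbind, meta))
}

# reduced schedule for fixtures: 9 arrays x 8 markers, 3 scales, small
# 2 cm base marker so wide cameras resolve only the large scales
fixture_schedule <- function() {
  make_schedule(n_arrays = 9, markers_per_array = 8,
                scales = c(1, 2.8, 8),
                projector_resolution = c(1920, 1080),
                base_side = 0.02, px_per_m = 800,
                grid_nx = 4, grid_ny = 2, margin_px = 220,
                offset_grid = 3, slot_duration = 0.1)
}

# 4 wide cameras + 1 long-focal close-up camera
fixture_rig <- function(seed = 1L) {
  with_seed(seed, {
    mk <- function(cid, f, center) {
      list(camera_id = cid,
           K = camera_intrinsics(f, f, 960, 540, numeric(5), 1920, 1080,
                                 camera_id = cid),
           pose = look_at_pose(center, c(0, 0, 0)))
    }
    az <- runif(4, 0, 2 * pi)[order(runif(4))] + seq(0, 3) * pi / 2
    wide <- lapply(1:4, function(i)
      mk(sprintf("wide%02d", i), 915,
         c(2.6 * cos(az[i] + runif(1, -0.2, 0.2)),
           2.6 * sin(az[i] + runif(1, -0.2, 0.2)), 2.7)))
    zoom <- list(mk("zoom01", 8000, c(0.4 + runif(1, -0.05, 0.05),
                                      0.25 + runif(1, -0.05, 0.05), 2.6)))
    c(wide, zoom)
  })
}

#' Detect, fuse and calibrate a rendered fixture
#'
#' Convenience wrapper running the detection module over every rendered
#' frame of a [make_fixture()] dataset (in memory or from disk) and
#' returning tracks plus the detection coverage against the geometric
#' visibility oracle.
#'
#' @param fixture result of [make_fixture()].
#' @return list with `tracks`, `detections`, `coverage` (fraction of
#'   camera-marker pairs with at least one decodable rendered instance that
#'   produced a fused observation).
#' @export
process_fixture <- function(fixture) {
  det <- detect_directory(fixture$dir)
  obs <- detections_to_observations(det, fixture$schedule)
  tracks <- build_tracks(obs)
  # visibility oracle: a (camera, marker) pair counts as visible when at
  # least one scale instance was rendered completely inside the image at a
  # decodable size (projected side >= 24 px)
  vis <- fixture$meta[fixture$meta$drawn & !is.na(fixture$meta$clipped) &
                        !fixture$meta$clipped &
                        !is.na(fixture$meta$side_px) &
                        fixture$meta$side_px >= 24, ]
  vis_pairs <- unique(vis[, c("camera_id", "marker_id")])
  got <- paste(obs$camera_id, obs$marker_id)
  coverage <- mean(paste(vis_pairs$camera_id, vis_pairs$marker_id) %in% got)
  list(tracks = tracks, detections = det, coverage = coverage,
       n_visible_pairs = nrow(vis_pairs))
}
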