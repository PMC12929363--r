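# Sparse bundle adjustment: Levenberg-Marquardt on the summed squared pixel
# reprojection error, with the structure parameters eliminated through the
# Schur complement. Three structure models share the engine:
#   free  - every 3D point is a free 3-vector,
#   plane - points are 2D coordinates in a floor plane optimized jointly
#           (hard coplanarity reparametrization, not a penalty),
#   board - points are rigid boards of known local geometry; each board
#           contributes one 6-dof pose block (the moving-board gold
#           standard used by the simulator).
# Rotations update by composing axis-angle increments onto the current
# estimate. Intrinsics are always held fixed.

# obs: data.frame(cam, pt, x, y) with undistorted pixel observations;
# for the board model additional columns lx, ly, lz give the point's
# board-local coordinates. cams: list of camera_pose. K_list: list of
# camera_intrinsics (distortion ignored here). structure: model-dependent,
# see above. fixed_cams: indices of cameras fully frozen. fixed_coord:
# c(cam, k) freezing the k-th local coordinate (1:3 rotation, 4:6
# translation) of one camera, the scale gauge.
ba_core <- function(obs, cams, K_list, structure,
                    model = c("free", "plane", "board"),
                    fixed_cams = 1L, fixed_coord = NULL,
                    maxit = 200L, tol = 1e-10, lambda_init = 1e-6) {
  model <- match.arg(model)
  ncam <- length(cams)
  N <- nrow(obs)
  stopifnot(N >= 1)
  cam_i <- as.integer(obs$cam)
  pt_i <- as.integer(obs$pt)
  M <- if (model == "board") length(structure$boards) else
    nrow(structure_points(structure, model))
  p <- switch(model, free = 3L, plane = 2L, board = 6L)
  nplane <- if (model == "plane") 3L else 0L

  # theta layout: free camera coords first, then plane params
  free_mask <- matrix(TRUE, 6, ncam)
  free_mask[, fixed_cams] <- FALSE
  if (!is.null(fixed_coord)) free_mask[fixed_coord[2], fixed_coord[1]] <- FALSE
  theta_col <- matrix(0L, 6, ncam)
  theta_col[free_mask] <- seq_len(sum(free_mask))
  ntheta <- sum(free_mask) + nplane
  plane_cols <- if (nplane) sum(free_mask) + 1:3 else integer()

  fx <- vapply(K_list, `[[`, numeric(1), "fx")[cam_i]
  fy <- vapply(K_list, `[[`, numeric(1), "fy")[cam_i]
  cx <- vapply(K_list, `[[`, numeric(1), "cx")[cam_i]
  cy <- vapply(K_list, `[[`, numeric(1), "cy")[cam_i]

  state <- list(cams = cams, structure = structure)

  eval_all <- function(st, jac = TRUE) {
    X <- structure_world_points(st$structure, model, obs, pt_i)   # N x 3
    Rm <- array(unlist(lapply(st$cams, function(P) P$R)), c(3, 3, ncam))
    tm <- vapply(st$cams, function(P) P$t, numeric(3))
    # camera transform, vectorized by gathering per-obs rotation rows
    R11 <- Rm[1, 1, cam_i]; R12 <- Rm[1, 2, cam_i]; R13 <- Rm[1, 3, cam_i]
    R21 <- Rm[2, 1, cam_i]; R22 <- Rm[2, 2, cam_i]; R23 <- Rm[2, 3, cam_i]
    R31 <- Rm[3, 1, cam_i]; R32 <- Rm[3, 2, cam_i]; R33 <- Rm[3, 3, cam_i]
    Xc1 <- R11 * X[, 1] + R12 * X[, 2] + R13 * X[, 3] + tm[1, cam_i]
    Xc2 <- R21 * X[, 1] + R22 * X[, 2] + R23 * X[, 3] + tm[2, cam_i]
    Xc3 <- R31 * X[, 1] + R32 * X[, 2] + R33 * X[, 3] + tm[3, cam_i]
    bad <- Xc3 <= 1e-9
    z <- ifelse(bad, 1, Xc3)
    ru <- fx * Xc1 / z + cx - obs$x
    rv <- fy * Xc2 / z + cy - obs$y
    ru[bad] <- 1e6; rv[bad] <- 1e6
    out <- list(F = sum(ru^2) + sum(rv^2), ru = ru, rv = rv, bad = bad)
    if (!jac) return(out)
    iz <- 1 / z
    du <- cbind(fx * iz, 0, -fx * Xc1 * iz^2)       # du/dXc
    dv <- cbind(0, fy * iz, -fy * Xc2 * iz^2)
    # camera rotation block: a %*% (-[Y]_x), Y = Xc - t
    Y1 <- Xc1 - tm[1, cam_i]; Y2 <- Xc2 - tm[2, cam_i]; Y3 <- Xc3 - tm[3, cam_i]
    rotblock <- function(d) cbind(d[, 2] * (-Y3) + d[, 3] * Y2,
                                  d[, 1] * Y3 + d[, 3] * (-Y1),
                                  d[, 1] * (-Y2) + d[, 2] * Y1)
    Jcam_u <- cbind(rotblock(du), du)
    Jcam_v <- cbind(rotblock(dv), dv)
    # structure blocks: d/dXw = d %*% R_c, then model-specific chain
    dRu <- cbind(du[, 1] * R11 + du[, 3] * R31,
                 du[, 1] * R12 + du[, 3] * R32,
                 du[, 1] * R13 + du[, 3] * R33)
    dRv <- cbind(dv[, 2] * R21 + dv[, 3] * R31,
                 dv[, 2] * R22 + dv[, 3] * R32,
                 dv[, 2] * R23 + dv[, 3] * R33)
    chain <- structure_jacobian(st$structure, model, obs, pt_i, X, dRu, dRv)
    out$Jcam_u <- Jcam_u; out$Jcam_v <- Jcam_v
    out$Jstr_u <- chain$Jstr_u; out$Jstr_v <- chain$Jstr_v
    out$Jpl_u <- chain$Jpl_u; out$Jpl_v <- chain$Jpl_v
    out
  }

  # constant sparse index patterns
  obs_rows_u <- seq_len(N); obs_rows_v <- N + seq_len(N)
  # theta triplets for camera blocks
  cam_cols <- theta_col[, cam_i, drop = FALSE]          # 6 x N
  keep_cam <- cam_cols > 0
  th_i <- c(rep(obs_rows_u, each = 6)[keep_cam], rep(obs_rows_v, each = 6)[keep_cam],
            if (nplane) c(rep(obs_rows_u, each = 3), rep(obs_rows_v, each = 3)))
  th_j <- c(cam_cols[keep_cam], cam_cols[keep_cam],
            if (nplane) rep(plane_cols, 2 * N))
  str_i <- c(rep(obs_rows_u, each = p), rep(obs_rows_v, each = p))
  str_cols0 <- (rep(pt_i, each = p) - 1L) * p + rep(seq_len(p), N)
  str_j <- c(str_cols0, str_cols0)

  lam <- lambda_init
  cur <- eval_all(state)
  F0 <- cur$F
  converged <- FALSE
  n_iter <- 0L
  for (it in seq_len(maxit)) {
    n_iter <- it
    # assemble sparse Jacobians from the current evaluation
    thx <- c(t(cur$Jcam_u)[keep_cam], t(cur$Jcam_v)[keep_cam],
             if (nplane) c(t(cur$Jpl_u), t(cur$Jpl_v)))
    Jth <- Matrix::sparseMatrix(i = th_i, j = th_j, x = thx,
                                dims = c(2 * N, ntheta))
    Jst <- Matrix::sparseMatrix(i = str_i, j = str_j,
                                x = c(t(cur$Jstr_u), t(cur$Jstr_v)),
                                dims = c(2 * N, p * M))
    r <- c(cur$ru, cur$rv)
    Hthth <- as.matrix(Matrix::crossprod(Jth))
    W <- Matrix::crossprod(Jth, Jst)                    # ntheta x pM
    bth <- -as.numeric(Matrix::crossprod(Jth, r))
    bst <- -as.numeric(Matrix::crossprod(Jst, r))
    Hss <- Matrix::crossprod(Jst)                        # block diagonal
    accepted <- FALSE
    for (try in 1:12) {
      Minv <- block_diag_inverse(Hss, p, M, lam)
      if (is.null(Minv)) { lam <- lam * 4; next }
      Hl <- Hthth; diag(Hl) <- diag(Hl) * (1 + lam) + 1e-12
      WM <- W %*% Minv
      S <- Hl - as.matrix(WM %*% Matrix::t(W))
      rhs <- bth - as.numeric(WM %*% bst)
      dth <- tryCatch(solve(S, rhs), error = function(e) NULL)
      if (is.null(dth)) { lam <- lam * 4; next }
      dst <- as.numeric(Minv %*% (bst - as.numeric(Matrix::t(W) %*% dth)))
      trial <- apply_ba_step(state, model, dth, dst, theta_col, plane_cols, p, M)
      ev <- eval_all(trial, jac = FALSE)
      if (is.finite(ev$F) && ev$F < cur$F) {
        state <- trial
        lam <- max(lam / 3, 1e-12)
        Fnew <- ev$F
        accepted <- TRUE
        break
      }
      lam <- lam * 4
    }
    if (!accepted) { converged <- TRUE; break }  # no descent direction left
    relchange <- (cur$F - Fnew) / max(cur$F, 1e-300)
    cur <- eval_all(state)
    if (relchange < tol || cur$F / N < 1e-22) { converged <- TRUE; break }
  }
  list(cams = state$cams, structure = state$structure,
       objective = cur$F, initial_objective = F0,
       n_iter = n_iter, converged = converged,
       warning = !converged)
}

structure_points <- function(structure, model) {
  switch(model,
         free = structure$X,
         plane = structure$uv,
         board = stop("board model has pose blocks, not points"))
}

# world coordinates of the observed points, N x 3
structure_world_points <- function(structure, model, obs, pt_i) {
  if (model == "free") {
    structure$X[pt_i, , drop = FALSE]
  } else if (model == "plane") {
    Fm <- structure$plane$Fm; d <- structure$plane$d
    uv <- structure$uv[pt_i, , drop = FALSE]
    cbind(uv[, 1] * Fm[1, 1] + uv[, 2] * Fm[1, 2] + d * Fm[1, 3],
          uv[, 1] * Fm[2, 1] + uv[, 2] * Fm[2, 2] + d * Fm[2, 3],
          uv[, 1] * Fm[3, 1] + uv[, 2] * Fm[3, 2] + d * Fm[3, 3])
  } else {
    Rb <- array(unlist(lapply(structure$boards, function(b) b$R)),
                c(3, 3, length(structure$boards)))
    tb <- vapply(structure$boards, function(b) b$t, numeric(3))
    L <- cbind(obs$lx, obs$ly, obs$lz)
    cbind(Rb[1, 1, pt_i] * L[, 1] + Rb[1, 2, pt_i] * L[, 2] + Rb[1, 3, pt_i] * L[, 3] + tb[1, pt_i],
          Rb[2, 1, pt_i] * L[, 1] + Rb[2, 2, pt_i] * L[, 2] + Rb[2, 3, pt_i] * L[, 3] + tb[2, pt_i],
          Rb[3, 1, pt_i] * L[, 1] + Rb[3, 2, pt_i] * L[, 2] + Rb[3, 3, pt_i] * L[, 3] + tb[3, pt_i])
  }
}

# chain rule from world-point derivatives (dRu, dRv: N x 3 = d(resid)/dXw)
# to the structure parameter blocks
structure_jacobian <- function(structure, model, obs, pt_i, X, dRu, dRv) {
  if (model == "free") {
    list(Jstr_u = dRu, Jstr_v = dRv, Jpl_u = NULL, Jpl_v = NULL)
  } else if (model == "plane") {
    Fm <- structure$plane$Fm
    e1 <- Fm[, 1]; e2 <- Fm[, 2]; nn <- Fm[, 3]
    Ju_uv <- cbind(dRu %*% e1, dRu %*% e2)
    Jv_uv <- cbind(dRv %*% e1, dRv %*% e2)
    # plane params: tilt about e1, tilt about e2, offset along n
    # dX/da = e1 x X, dX/db = e2 x X, dX/dd = n
    cxp <- function(e, X) cbind(e[2] * X[, 3] - e[3] * X[, 2],
                                e[3] * X[, 1] - e[1] * X[, 3],
                                e[1] * X[, 2] - e[2] * X[, 1])
    A1 <- cxp(e1, X); A2 <- cxp(e2, X)
    Jpl_u <- cbind(rowSums(dRu * A1), rowSums(dRu * A2), dRu %*% nn)
    Jpl_v <- cbind(rowSums(dRv * A1), rowSums(dRv * A2), dRv %*% nn)
    list(Jstr_u = Ju_uv, Jstr_v = Jv_uv, Jpl_u = Jpl_u, Jpl_v = Jpl_v)
  } else {
    tb <- vapply(structure$boards, function(b) b$t, numeric(3))
    Y <- X - t(tb[, pt_i, drop = FALSE])        # R_b L per obs
    rotblock <- function(d, Y) cbind(d[, 2] * (-Y[, 3]) + d[, 3] * Y[, 2],
                                     d[, 1] * Y[, 3] + d[, 3] * (-Y[, 1]),
                                     d[, 1] * (-Y[, 2]) + d[, 2] * Y[, 1])
    list(Jstr_u = cbind(rotblock(dRu, Y), dRu),
         Jstr_v = cbind(rotblock(dRv, Y), dRv),
         Jpl_u = NULL, Jpl_v = NULL)
  }
}

apply_ba_step <- function(state, model, dth, dst, theta_col, plane_cols, p, M) {
  cams <- state$cams
  for (c in seq_along(cams)) {
    cols <- theta_col[, c]
    d6 <- numeric(6)
    d6[cols > 0] <- dth[cols[cols > 0]]
    if (all(d6 == 0)) next
    cams[[c]] <- list(R = rot_from_rotvec(d6[1:3]) %*% cams[[c]]$R,
                      t = cams[[c]]$t + d6[4:6])
    class(cams[[c]]) <- "camera_pose"
  }
  structure <- state$structure
  if (model == "free") {
    structure$X <- structure$X + matrix(dst, M, 3, byrow = TRUE)
  } else if (model == "plane") {
    structure$uv <- structure$uv + matrix(dst, M, 2, byrow = TRUE)
    if (length(plane_cols)) {
      dpl <- dth[plane_cols]
      Fm <- structure$plane$Fm
      w <- dpl[1] * Fm[, 1] + dpl[2] * Fm[, 2]
      Rup <- rot_from_rotvec(w)
      Fm <- Rup %*% Fm
      # re-orthonormalize the frame
      Fm <- closest_rotation(Fm)
      structure$plane$Fm <- Fm
      structure$plane$d <- structure$plane$d + dpl[3]
    }
  } else {
    for (b in seq_len(M)) {
      d6 <- dst[(b - 1) * 6 + 1:6]
      structure$boards[[b]] <- list(
        R = rot_from_rotvec(d6[1:3]) %*% structure$boards[[b]]$R,
        t = structure$boards[[b]]$t + d6[4:6])
    }
  }
  list(cams = cams, structure = structure)
}

# Inverse of the (LM-augmented) block diagonal structure Hessian as a sparse
# matrix. Hss: sparse p*M x p*M with p x p blocks; closed-form inverses for
# p = 2, 3, per-block solve for larger p.
block_diag_inverse <- function(Hss, p, M, lam) {
  if (p <= 3) {
    # extract dense blocks: M x p^2 (row-major within block)
    B <- matrix(0, M, p * p)
    for (a in seq_len(p)) for (b in seq_len(p)) {
      rows <- seq(a, p * M, by = p)
      cols <- seq(b, p * M, by = p)
      B[, (a - 1) * p + b] <- Hss[cbind(rows, cols)]
    }
    # LM augmentation on the diagonal
    for (a in seq_len(p)) {
      k <- (a - 1) * p + a
      B[, k] <- B[, k] * (1 + lam) + 1e-12
    }
    if (p == 2) {
      det <- B[, 1] * B[, 4] - B[, 2] * B[, 3]
      if (any(!is.finite(det)) || any(abs(det) < 1e-300)) return(NULL)
      inv <- cbind(B[, 4], -B[, 2], -B[, 3], B[, 1]) / det
    } else {
      a11 <- B[, 1]; a12 <- B[, 2]; a13 <- B[, 3]
      a21 <- B[, 4]; a22 <- B[, 5]; a23 <- B[, 6]
      a31 <- B[, 7]; a32 <- B[, 8]; a33 <- B[, 9]
      det <- a11 * (a22 * a33 - a23 * a32) - a12 * (a21 * a33 - a23 * a31) +
        a13 * (a21 * a32 - a22 * a31)
      if (any(!is.finite(det)) || any(abs(det) < 1e-300)) return(NULL)
      inv <- cbind(a22 * a33 - a23 * a32, a13 * a32 - a12 * a33, a12 * a23 - a13 * a22,
                   a23 * a31 - a21 * a33, a11 * a33 - a13 * a31, a13 * a21 - a11 * a23,
                   a21 * a32 - a22 * a31, a12 * a31 - a11 * a32, a11 * a22 - a12 * a21) / det
    }
    ii <- rep((seq_len(M) - 1) * p, each = p * p) + rep(rep(seq_len(p), each = p), M)
    jj <- rep((seq_len(M) - 1) * p, each = p * p) + rep(rep(seq_len(p), times = p), M)
    Matrix::sparseMatrix(i = ii, j = jj, x = as.numeric(t(inv)),
                         dims = c(p * M, p * M))
  } else {
    trips_i <- integer(0); trips_j <- integer(0); trips_x <- numeric(0)
    for (k in seq_len(M)) {
      rows <- (k - 1) * p + seq_len(p)
      Bk <- as.matrix(Hss[rows, rows])
      diag(Bk) <- diag(Bk) * (1 + lam) + 1e-12
      Ik <- tryCatch(solve(Bk), error = function(e) NULL)
      if (is.null(Ik)) return(NULL)
      trips_i <- c(trips_i, rep(rows, each = p))
      trips_j <- c(trips_j, rep(rows, times = p))
      trips_x <- c(trips_x, as.numeric(t(Ik)))
    }
    Matrix::sparseMatrix(i = trips_i, j = trips_j, x = trips_x,
                         dims = c(p * M, p * M))
  }
}
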