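# Fiducial detection: connected bright components -> quad corners ->
# sub-pixel edge refinement -> payload decoding. Runs in the raw image;
# centers are undistorted only downstream, at the single fused point.

# bilinear interpolation of img at 0-based pixel coords (vectorized)
interp_bilinear <- function(img, x, y) {
  H <- nrow(img); W <- ncol(img)
  x <- pmin(pmax(x, 0), W - 1 - 1e-9)
  y <- pmin(pmax(y, 0), H - 1 - 1e-9)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  i0 <- y0 + 1; j0 <- x0 + 1
  v00 <- img[cbind(i0, j0)]
  v01 <- img[cbind(i0, pmin(j0 + 1, W))]
  v10 <- img[cbind(pmin(i0 + 1, H), j0)]
  v11 <- img[cbind(pmin(i0 + 1, H), pmin(j0 + 1, W))]
  v00 * (1 - fx) * (1 - fy) + v01 * fx * (1 - fy) +
    v10 * (1 - fx) * fy + v11 * fx * fy
}

#' Center of a square fiducial from its imaged corners
#'
#' The intersection of the imaged diagonals. Because incidence is preserved
#' by projective maps, this center is equivariant under homographies:
#' `center(H corners) = H center(corners)` -- the property that makes marker
#' centers consistent across arbitrarily different viewpoints and scales.
#'
#' @param corners 4x2 matrix of corner pixels in cyclic order.
#' @return length-2 center point.
#' @export
center_from_corners <- function(corners) {
  corners <- matrix(corners, ncol = 2)
  stopifnot(nrow(corners) == 4)
  hp <- cbind(corners, 1)
  l1 <- cross3(hp[1, ], hp[3, ])
  l2 <- cross3(hp[2, ], hp[4, ])
  c0 <- cross3(l1, l2)
  scale <- max(abs(corners))
  if (abs(c0[3]) < 1e-12 * max(vnorm(l1) * vnorm(l2), 1e-300) ||
      !quad_convex(corners))
    stop("degenerate quad: collinear corners or diagonals do not intersect")
  c0[1:2] / c0[3]
}

quad_convex <- function(corners) {
  s <- numeric(4)
  for (i in 1:4) {
    a <- corners[i, ]; b <- corners[i %% 4 + 1, ]; cc <- corners[(i + 1) %% 4 + 1, ]
    s[i] <- (b[1] - a[1]) * (cc[2] - a[2]) - (b[2] - a[2]) * (cc[1] - a[1])
  }
  all(s > 0) || all(s < 0)
}

# order 4 points counterclockwise (in image coords) around their centroid
order_quad <- function(pts) {
  ctr <- colMeans(pts)
  ang <- atan2(pts[, 2] - ctr[2], pts[, 1] - ctr[1])
  pts[order(ang), , drop = FALSE]
}

# initial 4 corner guesses from a convex hull (0-based pixel coords)
hull_corners <- function(hp) {
  ctr <- colMeans(hp)
  i1 <- which.max(rowSums(sweep(hp, 2, ctr)^2))
  d1 <- rowSums(sweep(hp, 2, hp[i1, ])^2)
  i2 <- which.max(d1)
  a <- hp[i1, ]; b <- hp[i2, ]
  # signed distance from line a-b
  sd <- (b[1] - a[1]) * (hp[, 2] - a[2]) - (b[2] - a[2]) * (hp[, 1] - a[1])
  i3 <- which.max(sd); i4 <- which.min(sd)
  if (abs(sd[i3]) < 1e-9 || abs(sd[i4]) < 1e-9) return(NULL)
  order_quad(hp[c(i1, i3, i2, i4), , drop = FALSE])
}

# refine quad edges to sub-pixel: locate the 50% intensity crossing along
# edge normals, fit a line per edge, intersect adjacent edges
refine_quad <- function(img, quad, lo = 0, hi = 1) {
  mid <- (lo + hi) / 2
  lines <- vector("list", 4)
  ctr <- colMeans(quad)
  for (e in 1:4) {
    a <- quad[e, ]; b <- quad[e %% 4 + 1, ]
    len <- vnorm(b - a)
    ns <- max(8, min(40, round(len / 3)))
    tt <- seq(0.15, 0.85, length.out = ns)
    base <- cbind(a[1] + tt * (b[1] - a[1]), a[2] + tt * (b[2] - a[2]))
    dir <- unit(b - a)
    nrm <- c(dir[2], -dir[1])
    if (sum((ctr - a) * nrm) > 0) nrm <- -nrm   # normal points outward
    offs <- seq(-2, 2, by = 0.25)
    prof <- matrix(interp_bilinear(img,
                                   rep(base[, 1], each = length(offs)) + offs * nrm[1],
                                   rep(base[, 2], each = length(offs)) + offs * nrm[2]),
                   length(offs), ns)
    pts <- matrix(NA_real_, ns, 2)
    for (s in seq_len(ns)) {
      p <- prof[, s]
      # inside (bright) to outside (dark): find last crossing below mid
      below <- which(p < mid)
      above <- which(p >= mid)
      if (!length(below) || !length(above)) next
      k <- which(p[-length(p)] >= mid & p[-1] < mid)
      if (!length(k)) next
      k <- k[1]
      frac <- (p[k] - mid) / (p[k] - p[k + 1])
      o <- offs[k] + frac * (offs[k + 1] - offs[k])
      pts[s, ] <- base[s, ] + o * nrm
    }
    pts <- pts[stats::complete.cases(pts), , drop = FALSE]
    if (nrow(pts) < 4) return(NULL)
    # total least squares line fit with one reweighting pass
    fit_line <- function(p) {
      mu <- colMeans(p)
      sv <- svd(sweep(p, 2, mu), nu = 0)
      dirv <- sv$v[, 1]
      nv <- c(dirv[2], -dirv[1])
      list(n = nv, d = sum(nv * mu))
    }
    L <- fit_line(pts)
    res <- abs(pts %*% L$n - L$d)
    keep <- res <= 2 * stats::median(res) + 1e-6
    if (sum(keep) >= 4) L <- fit_line(pts[keep, , drop = FALSE])
    lines[[e]] <- L
  }
  corners <- matrix(NA_real_, 4, 2)
  for (e in 1:4) {
    L1 <- lines[[e]]; L2 <- lines[[e %% 4 + 1]]
    A <- rbind(L1$n, L2$n)
    if (abs(det(A)) < 1e-9) return(NULL)
    corners[e %% 4 + 1, ] <- solve(A, c(L1$d, L2$d))
  }
  # corner e%%4+1 is the intersection of edge e and edge e+1
  corners
}

# homography from canonical cell grid corners to image corners
quad_homography <- function(corners, nc = MSQ6_CELLS) {
  src <- matrix(c(0, 0, nc, 0, nc, nc, 0, nc), 4, 2, byrow = TRUE)
  homography_dlt(src, corners)
}

#' Detect fiducial markers in a grayscale frame
#'
#' Segments bright connected components, extracts convex quadrilaterals,
#' refines their edges to sub-pixel precision, and decodes the payload grid
#' (trying all four rotations against the family checksum). Corners of each
#' detection are returned in the symbol's canonical order, so corner 1 is
#' the same physical corner in every view.
#'
#' @param image numeric matrix (height x width) in \[0, 1\], or the path of
#'   a PNG file.
#' @param min_side minimum quad side length in pixels for decoding.
#' @param max_id reject decoded symbol ids above this value.
#' @return data frame of raw detections: symbol_id, decode_confidence, and
#'   corner coordinates x1..y4 (0-based pixels); zero rows when nothing is
#'   decodable.
#' @export
detect_frame <- function(image, min_side = 8, max_id = MSQ6_MAX_ID) {
  if (is.character(image)) image <- load_frame_png(image)
  empty <- data.frame(symbol_id = integer(), decode_confidence = numeric(),
                      x1 = numeric(), y1 = numeric(), x2 = numeric(), y2 = numeric(),
                      x3 = numeric(), y3 = numeric(), x4 = numeric(), y4 = numeric())
  mx <- max(image)
  if (mx < 0.2) return(empty)
  bw <- image > 0.5 * mx
  lab <- EBImage::bwlabel(bw)
  idx <- which(lab > 0)
  if (!length(idx)) return(empty)
  labs <- lab[idx]
  H <- nrow(image)
  ys <- (idx - 1) %% H          # 0-based row = y
  xs <- (idx - 1) %/% H         # 0-based col = x
  comp <- split(seq_along(idx), labs)
  out <- list()
  for (cp in comp) {
    if (length(cp) < 25) next
    px <- cbind(xs[cp], ys[cp])
    hull <- grDevices::chull(px)
    hp <- px[hull, , drop = FALSE]
    quad <- hull_corners(hp)
    if (is.null(quad)) next
    sides <- sqrt(rowSums((quad - quad[c(2, 3, 4, 1), ])^2))
    if (min(sides) < min_side) next
    rq <- tryCatch(refine_quad(image, quad), error = function(e) NULL)
    if (is.null(rq) || !quad_convex(rq)) rq <- quad
    Hq <- tryCatch(quad_homography(rq), error = function(e) NULL)
    if (is.null(Hq)) next
    # sample the 8x8 cell grid (cell centers), average a 3x3 stencil
    gc <- expand.grid(u = seq_len(MSQ6_CELLS) - 0.5, v = seq_len(MSQ6_CELLS) - 0.5)
    val <- numeric(nrow(gc))
    for (du in c(-0.15, 0, 0.15)) for (dv in c(-0.15, 0, 0.15)) {
      s <- apply_homography(Hq, cbind(gc$u + du, gc$v + dv))
      val <- val + interp_bilinear(image, s[, 1], s[, 2])
    }
    val <- val / 9
    grid <- matrix(val, MSQ6_CELLS, MSQ6_CELLS, byrow = FALSE)
    # grid[v+1, u+1]? val is ordered with u varying fastest -> rows = u.
    grid <- t(grid)  # rows = v (grid y), cols = u (grid x)
    thr <- (max(val) + min(val)) / 2
    bitsM <- (grid >= thr) * 1L
    ring <- c(bitsM[1, ], bitsM[MSQ6_CELLS, ], bitsM[, 1], bitsM[, MSQ6_CELLS])
    if (mean(ring) < 0.9) next
    dec <- msq6_decode_payload(bitsM[2:7, 2:7])
    if (is.null(dec) || dec$id > max_id) next
    # canonicalize corner order for the detected rotation: rotating the
    # payload k times clockwise means the image quad is rotated; shift the
    # corner cycle accordingly
    cn <- rq[((0:3 + dec$rot) %% 4) + 1, , drop = FALSE]
    conf <- min(1, 2 * min(abs(range(val) - thr)) / max(mx, 1e-9))
    out[[length(out) + 1]] <- data.frame(
      symbol_id = dec$id, decode_confidence = conf,
      x1 = cn[1, 1], y1 = cn[1, 2], x2 = cn[2, 1], y2 = cn[2, 2],
      x3 = cn[3, 1], y3 = cn[3, 2], x4 = cn[4, 1], y4 = cn[4, 2])
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  # no duplicate symbol per frame: keep the most confident
  res <- res[order(-res$decode_confidence), ]
  res <- res[!duplicated(res$symbol_id), ]
  res[order(res$symbol_id), , drop = FALSE]
}

#' @rdname detect_frame
#' @param path PNG file path.
#' @export
load_frame_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1] * 0.299 + a[, , 2] * 0.587 + a[, , 3] * 0.114
  a
}
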