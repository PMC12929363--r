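#' Closed-form Sim(3) alignment (Umeyama)
#'
#' Least-squares similarity transform `y ~ s * R x + t` between two matched
#' 3D point sets, with the determinant correction that guarantees a proper
#' rotation. Used to remove the gauge freedom (global similarity) before
#' comparing estimated camera poses or point clouds with ground truth.
#'
#' @param source Nx3 matrix of source points (N >= 3, not collinear).
#' @param target Nx3 matrix of matched target points.
#' @param with_scale estimate the scale (default `TRUE`; otherwise fixed 1).
#' @return an object of class `sim3`: list with `s` (positive scale), `R`
#'   (3x3 proper rotation), `t` (length-3 translation).
#' @export
umeyama_sim3 <- function(source, target, with_scale = TRUE) {
  source <- matrix(source, ncol = 3); target <- matrix(target, ncol = 3)
  n <- nrow(source)
  stopifnot(nrow(target) == n)
  if (n < 3) stop("degenerate configuration: need at least 3 points")
  mu_s <- colMeans(source); mu_t <- colMeans(target)
  Xs <- sweep(source, 2, mu_s); Xt <- sweep(target, 2, mu_t)
  var_s <- mean(rowSums(Xs^2))
  if (var_s < 1e-20) stop("degenerate configuration: coincident source points")
  C <- crossprod(Xt, Xs) / n
  sv <- svd(C)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1e-300))
    stop("degenerate configuration: collinear source points")
  S <- diag(3)
  if (det(sv$u) * det(sv$v) < 0) S[3, 3] <- -1
  R <- sv$u %*% S %*% t(sv$v)
  s <- if (with_scale) sum(diag(diag(sv$d) %*% S)) / var_s else 1
  if (s <= 0) stop("degenerate configuration: non-positive scale")
  t <- mu_t - s * as.numeric(R %*% mu_s)
  structure(list(s = s, R = R, t = t), class = "sim3")
}

#' @export
print.sim3 <- function(x, ...) {
  cat(sprintf("sim3: scale %.6g, angle %.4g deg, |t| %.4g\n",
              x$s, rotation_angle(x$R) * 180 / pi, vnorm(x$t)))
  invisible(x)
}

#' Apply a Sim(3) transform to points
#'
#' @param S a `sim3` object from [umeyama_sim3()].
#' @param x Nx3 matrix of points.
#' @return Nx3 matrix of transformed points `s R x + t`.
#' @export
apply_sim3 <- function(S, x) {
  x <- matrix(x, ncol = 3)
  S$s * x %*% t(S$R) + matrix(S$t, nrow(x), 3, byrow = TRUE)
}
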