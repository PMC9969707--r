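# Closed-form rigid / similarity alignment (orthogonal Procrustes with
# optional isotropic scale, reflections rejected).

# Least-squares transform mapping rows of X onto rows of Y:
#   Y ~ s * X %*% t(R) + t
# Returns list(R, s, t, rms).  Proper rotation enforced (det +1).
procrustes_fit <- function(X, Y, scale = FALSE) {
  X <- rbind(X); Y <- rbind(Y)
  stopifnot(nrow(X) == nrow(Y), nrow(X) >= 3)
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
  S <- crossprod(Xc, Yc)
  sv <- svd(S)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  s <- if (scale) sum(diag(D) * sv$d) / sum(Xc^2) else 1
  t <- unname(my - s * as.numeric(R %*% mx))
  fitted <- s * Xc %*% t(R)
  rms <- sqrt(mean(rowSums((fitted - Yc)^2)))
  list(R = R, s = s, t = t, rms = rms)
}

#' Apply a rigid/similarity transform to points
#' @param points n x 3 matrix.
#' @param tf list with rotation `R`, scale `s`, translation `t` (as returned
#'   by [landmark_register()] or [rigid_align_models()]).
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(points, tf) {
  pts <- rbind(points)
  out <- tf$s * pts %*% t(tf$R)
  sweep(out, 2, tf$t, `+`)
}

compose_random_rigid <- function() {
  # uniform-ish random rotation via QR of a Gaussian matrix
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(R = q, s = 1, t = rnorm(3, 0, 20))
}
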