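# Optimal least-squares superposition (Kabsch). Returns the rotation R and
# translation t such that P %*% R + t best matches Q.
kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  list(rotation = R, translation = cq - as.numeric(cp %*% R))
}

rmsd_pair <- function(P, Q, superpose = TRUE) {
  if (superpose) {
    k <- kabsch(P, Q)
    P <- sweep(P %*% k$rotation, 2, k$translation, "+")
  }
  sqrt(sum((P - Q)^2) / nrow(P))
}

#' Per-frame RMSD of a trajectory with smoothed first derivative
#'
#' RMSD of every frame against a reference frame, optionally after optimal
#' least-squares (Kabsch) superposition. The first derivative is computed by
#' central differences on a moving-average-smoothed RMSD series; equilibration
#' is conventionally read off where the derivative settles near zero.
#'
#' @param traj A `trajectory` with at least 2 frames.
#' @param reference Reference frame index (1-based). Default 1.
#' @param selection `"CA"` (default) or `"all"` atoms.
#' @param superpose Remove rigid-body motion first? Default `TRUE`.
#' @param smooth_window Odd moving-average window for the smoothed series.
#' @return Data frame `(time, rmsd, smoothed, smoothed_derivative)`.
#' @export
rmsd_series <- function(traj, reference = 1L, selection = c("CA", "all"),
                        superpose = TRUE, smooth_window = 5L) {
  stopifnot(inherits(traj, "trajectory"))
  selection <- match.arg(selection)
  if (length(traj$frames) < 2L) stopf("need at least 2 frames")
  coords <- lapply(traj$frames, function(f) {
    a <- f$atoms
    if (selection == "CA") a <- a[a$atom == "CA", , drop = FALSE]
    if (nrow(a) == 0L) stopf("selection '%s' matches no atoms", selection)
    as.matrix(a[, c("x", "y", "z")])
  })
  nat <- vapply(coords, nrow, integer(1))
  if (length(unique(nat)) != 1L) stopf("frames have mismatched atom counts")
  Q <- coords[[reference]]
  r <- vapply(coords, rmsd_pair, numeric(1), Q = Q, superpose = superpose)

  w <- as.integer(smooth_window)
  if (w %% 2L == 0L) w <- w + 1L
  half <- (w - 1L) %/% 2L
  n <- length(r)
  sm <- vapply(seq_len(n), function(i) {
    mean(r[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
  t <- traj$times
  deriv <- numeric(n)
  if (n >= 3L) {
    deriv[2:(n - 1)] <- (sm[3:n] - sm[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  }
  deriv[1] <- (sm[2] - sm[1]) / (t[2] - t[1])
  deriv[n] <- (sm[n] - sm[n - 1]) / (t[n] - t[n - 1])
  data.frame(time = t, rmsd = r, smoothed = sm, smoothed_derivative = deriv)
}
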