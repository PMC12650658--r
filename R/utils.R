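# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Rotation matrix from intrinsic Z-Y-X Euler angles (radians).
rotation_from_euler <- function(angles) {
  stopifnot(length(angles) == 3L)
  a <- angles[1]; b <- angles[2]; g <- angles[3]
  Rz <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cos(g), -sin(g), 0, sin(g), cos(g)), 3, 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

as_points_matrix <- function(x) {
  if (inherits(x, "structure_model")) {
    return(unname(as.matrix(x$atoms[, c("x", "y", "z")])))
  }
  m <- as.matrix(x)
  if (ncol(m) != 3L) stopf("expected an n x 3 coordinate matrix, got %d columns", ncol(m))
  storage.mode(m) <- "double"
  unname(m)
}
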