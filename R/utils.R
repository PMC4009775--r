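# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Boltzmann constant in kcal/mol/K
#'
#' Used to convert entropies in nats to TS terms in kcal/mol.
#' @export
KB_KCALMOL <- 0.0019872041

vec_norm <- function(v) sqrt(sum(v * v))

unit_vec <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# row-wise cross product for n x 3 matrices
cross3_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

rowdot <- function(a, b) rowSums(a * b)

# wrap angle in degrees into (-180, 180]
wrap_angle <- function(theta) {
  out <- ((theta + 180) %% 360) - 180
  out[out <= -180] <- out[out <= -180] + 360
  # map exact -180 to +180 (identified on the circle)
  out[abs(out + 180) < 1e-12] <- 180
  out
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name))
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name))
  invisible(x)
}
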