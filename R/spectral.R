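#' Eigenvalues of the drift generator
#'
#' The spectrum of the Wright-Fisher forward generator is
#' \eqn{\lambda_m = (m+1)(m+2)/2}, \eqn{m \ge 0}; the interior series of the
#' global solution decays as \eqn{e^{-\lambda_m t}} in diffusion time (units of
#' \eqn{2N} generations).
#'
#' @param m vector of non-negative integer degrees.
#' @return Numeric vector \eqn{(m+1)(m+2)/2}.
#' @examples
#' drift_eigenvalue(0:5)
#' @export
drift_eigenvalue <- function(m) {
  if (any(m < 0 | m != round(m))) stop("'m' must be non-negative integers", call. = FALSE)
  (m + 1) * (m + 2) / 2
}

.check_p <- function(p) {
  if (length(p) != 1L || !is.finite(p) || p < 0 || p > 1)
    stop("initial frequency 'p' must be a single value in [0, 1]", call. = FALSE)
  p
}

.check_t <- function(t) {
  if (!is.numeric(t) || anyNA(t) || any(t < 0))
    stop("diffusion time 't' must be non-negative", call. = FALSE)
  t
}

#' Spectral coefficients of the global drift solution
#'
#' Assembles every parameter of the global solution started from the point
#' mass at frequency `p`:
#' \deqn{u(x,t) = \sum_{m=0}^{M} c_m X_m(x) e^{-\lambda_m t}
#'  + \Big\{1-p+\sum_m c_m a_{m,0} e^{-\lambda_m t}\Big\}\delta_0
#'  + \Big\{p+\sum_m c_m a_{m,1} e^{-\lambda_m t}\Big\}\delta_1,}
#' with \eqn{\lambda_m = (m+1)(m+2)/2}, boundary coefficients
#' \eqn{a_{m,0} = -1/2}, \eqn{a_{m,1} = (-1)^{m+1}/2}, atom baselines
#' \eqn{b_0 = 1-p}, \eqn{b_1 = p}, and spectral weights
#' \deqn{c_m = \frac{w(p) X_m(p)}{(X_m, wX_m)}
#'   = \frac{8\,w(p) X_m(p) (m + 3/2)}{(m+1)(m+2)},\quad w(p)=p(1-p).}
#' For `p` of 0 or 1 all \eqn{c_m} vanish and the solution is the constant
#' boundary atom.
#'
#' @param p initial frequency of allele \eqn{A_1}, in \eqn{[0, 1]}.
#' @param M truncation order (highest retained degree), non-negative integer.
#' @return An object of class `spectral_coefficients`: a list with fields
#'   `p`, `M`, `lambda`, `c`, `a0`, `a1`, `b0`, `b1` (arrays indexed by
#'   degree `m = 0..M`).
#' @examples
#' sc <- spectral_coefficients(0.4, M = 50)
#' sc$c[1]  # c_0 = 8 * w(p) * 1.5 / 2
#' @export
spectral_coefficients <- function(p, M = 100L) {
  p <- .check_p(p)
  if (length(M) != 1L || M < 0 || M != round(M))
    stop("truncation order 'M' must be a non-negative integer", call. = FALSE)
  M <- as.integer(M)
  m <- 0:M
  Xp <- drop(gegenbauer_x_all(M, p))
  wp <- p * (1 - p)
  structure(list(
    p = p,
    M = M,
    lambda = drift_eigenvalue(m),
    c = 8 * wp * Xp * (m + 1.5) / ((m + 1) * (m + 2)),
    a0 = rep.int(-0.5, M + 1L),
    a1 = (-1)^(m + 1) / 2,
    b0 = 1 - p,
    b1 = p
  ), class = "spectral_coefficients")
}

#' @export
print.spectral_coefficients <- function(x, ...) {
  cat("Spectral coefficients of the global Wright-Fisher drift solution\n")
  cat("  initial frequency p:", format(x$p), "\n")
  cat("  truncation order M :", x$M, "\n")
  cat("  leading weights c_m:", paste(format(utils::head(x$c, 4), digits = 4),
                                      collapse = ", "),
      if (x$M > 3) "...\n" else "\n")
  invisible(x)
}

# Crude tail bound of the interior series: first omitted term, with
# max |X_{M+1}| on [0,1] attained at the endpoints, = (M+2)(M+3)/2.
.truncation_tail <- function(coeffs, t) {
  M1 <- coeffs$M + 1L
  wp <- coeffs$p * (1 - coeffs$p)
  cmax <- 8 * wp * (M1 + 1.5) * (M1 + 1) * (M1 + 2) /
    (2 * (M1 + 1) * (M1 + 2))  # |c_{M+1}| bound * max|X_{M+1}|
  cmax * exp(-drift_eigenvalue(M1) * min(t))
}

.warn_truncation <- function(coeffs, t, tol = 1e-10) {
  small_t <- any(t < 0.01)
  tail <- .truncation_tail(coeffs, t)
  if (small_t || tail > tol)
    warning("spectral series converges slowly at t < 0.01 or truncation ",
            "tail ", format(tail, digits = 3), " exceeds ", tol,
            "; increase M for small times", call. = FALSE)
  invisible(tail)
}

#' Evaluate the global drift solution
#'
#' Evaluates the global solution at one diffusion time `t`: the smooth interior
#' density on the query points `xs` together with the two Dirac atom masses at
#' the absorbing boundaries.  The atoms are carried as explicit scalar masses
#' (never grid spikes); pairing with a test function \eqn{\phi} adds
#' \eqn{\mathrm{atom}_0\,\phi(0) + \mathrm{atom}_1\,\phi(1)}.
#'
#' At `t = 0` the solution is the point mass \eqn{\delta_p}; the returned
#' object carries the flag `initial_delta_at = p` alongside the (slowly
#' convergent) series values rather than attempting pointwise evaluation of a
#' delta function.  Small negative interior values are a truncation (Gibbs)
#' artifact and are returned as computed unless `clamp = TRUE`, which zeroes
#' them for plotting.
#'
#' @param coeffs a [spectral_coefficients()] object.
#' @param t single diffusion time, \eqn{t \ge 0} (units of 2N generations).
#' @param xs numeric vector of interior query points in \eqn{(0, 1)}.
#' @param clamp logical; zero out negative interior values (plotting aid).
#' @return An object of class `mixed_density`: list with `x`, `interior`,
#'   `atom0`, `atom1`, `t`, `p`, `M`, and `initial_delta_at` (`NA` unless
#'   `t == 0`).
#' @examples
#' sc <- spectral_coefficients(0.4, M = 80)
#' d <- drift_density(sc, t = 1, xs = seq(0.05, 0.95, by = 0.05))
#' d$atom0 + d$atom1 + sum(d$interior) * 0  # atoms are explicit masses
#' @export
drift_density <- function(coeffs, t, xs = seq(0.01, 0.99, by = 0.01),
                          clamp = FALSE) {
  stopifnot(inherits(coeffs, "spectral_coefficients"))
  .check_t(t)
  if (length(t) != 1L) stop("'t' must be a single time; map over a grid externally", call. = FALSE)
  if (length(xs) && (any(xs <= 0) || any(xs >= 1)))
    stop("'xs' must lie strictly inside (0, 1); boundary mass is in the atoms", call. = FALSE)
  if (t > 0) .warn_truncation(coeffs, t)
  decay <- coeffs$c * exp(-coeffs$lambda * t)
  interior <- if (length(xs)) {
    drop(crossprod(gegenbauer_x_all(coeffs$M, xs), decay))
  } else numeric(0)
  if (clamp) interior <- pmax(interior, 0)
  structure(list(
    x = xs,
    interior = interior,
    atom0 = coeffs$b0 + sum(decay * coeffs$a0),
    atom1 = coeffs$b1 + sum(decay * coeffs$a1),
    t = t,
    p = coeffs$p,
    M = coeffs$M,
    initial_delta_at = if (t == 0) coeffs$p else NA_real_
  ), class = "mixed_density")
}

#' @export
print.mixed_density <- function(x, ...) {
  cat("Mixed density of the Wright-Fisher drift diffusion\n")
  cat(sprintf("  p = %s, t = %s, M = %d\n", format(x$p), format(x$t), x$M))
  cat(sprintf("  atom at 0: %.6f   atom at 1: %.6f\n", x$atom0, x$atom1))
  if (!is.na(x$initial_delta_at))
    cat("  t = 0: exact state is the point mass at p =", x$initial_delta_at, "\n")
  cat("  interior evaluated at", length(x$x), "points\n")
  invisible(x)
}

#' @export
plot.mixed_density <- function(x, ...) {
  graphics::plot(x$x, x$interior, type = "l", xlab = "allele frequency x",
                 ylab = "interior density u(x, t)",
                 main = sprintf("p = %s, t = %s (atoms: %.3f, %.3f)",
                                format(x$p), format(x$t), x$atom0, x$atom1), ...)
  invisible(x)
}

#' Interior (local) part of the solution
#'
#' The classical local solution: the interior spectral series
#' \eqn{u_0(x,t) = \sum_m c_m X_m(x) e^{-\lambda_m t}} without boundary atoms.
#' Its total mass over \eqn{(0,1)} is the coexistence probability, strictly
#' less than 1 for \eqn{t > 0} — the defect that the global solution's atoms
#' absorb.
#'
#' @inheritParams drift_density
#' @return Numeric vector of interior density values at `xs`.
#' @export
local_density <- function(coeffs, t, xs) {
  drift_density(coeffs, t, xs)$interior
}

#' Mollified global solution for plotting
#'
#' Replaces the two boundary atoms by narrow half-Gaussian bumps
#' \eqn{\frac{k}{\sqrt{2\pi}} e^{-x^2 k^2/2}} and
#' \eqn{\frac{k}{\sqrt{2\pi}} e^{-(1-x)^2 k^2/2}} with smoothing index
#' \eqn{k}, yielding a smooth curve that converges weakly to the mixed density
#' as \eqn{k \to \infty}.  Each bump integrates to about 1/2 over
#' \eqn{[0, 1]} (a half Gaussian), so the plotted bump area is half the atom
#' mass; the mollifier is kept in this classical form for figure reproduction.
#'
#' @inheritParams drift_density
#' @param smoothing_index positive integer \eqn{k}; larger is narrower.
#' @param xs numeric vector of query points in \eqn{[0, 1]} (boundaries allowed).
#' @return Numeric vector of smoothed density values at `xs`.
#' @export
mollified_density <- function(coeffs, smoothing_index, t, xs) {
  stopifnot(inherits(coeffs, "spectral_coefficients"))
  if (length(smoothing_index) != 1L || smoothing_index < 1 ||
      smoothing_index != round(smoothing_index))
    stop("'smoothing_index' must be a positive integer", call. = FALSE)
  .check_t(t)
  k <- min(as.integer(smoothing_index), coeffs$M)
  decay <- coeffs$c[seq_len(k + 1L)] * exp(-coeffs$lambda[seq_len(k + 1L)] * t)
  interior <- drop(crossprod(gegenbauer_x_all(k, xs), decay))
  m0 <- coeffs$b0 + sum(decay * coeffs$a0[seq_len(k + 1L)])
  m1 <- coeffs$b1 + sum(decay * coeffs$a1[seq_len(k + 1L)])
  s <- as.integer(smoothing_index)
  bump0 <- s / sqrt(2 * pi) * exp(-xs^2 * s^2 / 2)
  bump1 <- s / sqrt(2 * pi) * exp(-(1 - xs)^2 * s^2 / 2)
  interior + m0 * bump0 + m1 * bump1
}

#' Pair the mixed density with a test function
#'
#' Weak pairing \eqn{(u, \phi)}: Gauss-Legendre quadrature of the interior
#' series against `phi` plus the atom contributions
#' \eqn{\mathrm{atom}_0 \phi(0) + \mathrm{atom}_1 \phi(1)}.  Exact (to
#' rounding) when `phi` is a polynomial of degree at most `phi_degree`.
#'
#' @param density a [drift_density()] result.
#' @param phi function of one argument (vectorised).
#' @param phi_degree polynomial degree of `phi` used to size the quadrature
#'   rule.
#' @param coeffs the [spectral_coefficients()] the density was built from.
#' @return Scalar value of the pairing.
#' @export
pair_density <- function(coeffs, density, phi, phi_degree = 12L) {
  stopifnot(inherits(density, "mixed_density"))
  decay <- coeffs$c * exp(-coeffs$lambda * density$t)
  interior_part <- gauss_integrate(function(x) {
    drop(crossprod(gegenbauer_x_all(coeffs$M, x), decay)) * phi(x)
  }, coeffs$M + phi_degree)
  interior_part + density$atom0 * phi(0) + density$atom1 * phi(1)
}

#' Verify the weak-solution identities
#'
#' Numerically checks, on a grid of times, the defining identities of the
#' global solution: conservation of mass \eqn{(u, 1) = 1}, the martingale
#' property \eqn{(u, x) = p}, and the spectral decay
#' \eqn{(u, wX_n) = w(p) X_n(p) e^{-\lambda_n t}} for \eqn{n \le n_{max}}.
#' The pairings include the atom contributions (the test function is evaluated
#' at 0 and 1 with the atom masses).
#'
#' @param coeffs a [spectral_coefficients()] object.
#' @param t_grid numeric vector of diffusion times.
#' @param n_max highest spectral test degree (default 10).
#' @return A data frame with columns `t`, `identity`, `residual` (absolute),
#'   of class `weak_identity_report`; `print()` shows the maxima.
#' @export
verify_weak_identities <- function(coeffs, t_grid = c(0.05, 0.1, 0.5, 1, 2, 5),
                                   n_max = 10L) {
  stopifnot(inherits(coeffs, "spectral_coefficients"))
  .check_t(t_grid)
  p <- coeffs$p
  wp <- p * (1 - p)
  rows <- lapply(t_grid, function(t) {
    d <- suppressWarnings(drift_density(coeffs, t, xs = numeric(0)))
    r_mass <- abs(pair_density(coeffs, d, function(x) rep.int(1, length(x)), 0L) - 1)
    r_mean <- abs(pair_density(coeffs, d, function(x) x, 1L) - p)
    r_spec <- vapply(0:n_max, function(n) {
      lhs <- pair_density(coeffs, d,
                          function(x) x * (1 - x) * gegenbauer_x(n, x),
                          as.integer(n + 2L))
      abs(lhs - wp * gegenbauer_x(n, p) * exp(-drift_eigenvalue(n) * t))
    }, numeric(1))
    data.frame(t = t,
               identity = c("mass", "mean", paste0("spectral_n", 0:n_max)),
               residual = c(r_mass, r_mean, r_spec))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("weak_identity_report", "data.frame")
  out
}

#' @export
print.weak_identity_report <- function(x, ...) {
  cat("Weak-identity residuals (max over time grid):\n")
  agg <- stats::aggregate(residual ~ identity, data = as.data.frame(x), FUN = max)
  print(format(agg, digits = 3), row.names = FALSE)
  invisible(x)
}
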