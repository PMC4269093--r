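# Practical cap on polynomial degree; forward recurrence is stable for this
# family but values grow with m, so warn past the cap rather than fail.
.wf_max_degree <- function() getOption("wfdrift.max_degree", 500L)

.check_degree <- function(m) {
  if (length(m) != 1L || !is.finite(m) || m < 0 || m != round(m))
    stop("polynomial degree 'm' must be a single non-negative integer", call. = FALSE)
  m <- as.integer(m)
  if (m > .wf_max_degree())
    warning("degree m = ", m, " exceeds the configured cap (",
            .wf_max_degree(), "); accuracy of double-precision recurrence ",
            "is untested at this order", call. = FALSE)
  m
}

#' Gegenbauer polynomials of the random-drift eigenbasis
#'
#' `gegenbauer_y()` evaluates the degree-`m` Gegenbauer polynomial
#' \eqn{Y_m(z)} of the \eqn{\alpha = 3/2} family on \eqn{[-1, 1]}, normalised
#' by \eqn{Y_0 = 1}, \eqn{Y_1 = 3z}.  `gegenbauer_x()` evaluates the same
#' polynomial transplanted to the allele-frequency interval,
#' \eqn{X_m(x) = Y_m(1 - 2x)} for \eqn{x \in [0, 1]}.  These are the
#' eigenfunctions of the Wright-Fisher forward generator
#' \eqn{L u = \tfrac12 \partial_x^2 (x(1-x)u)} with eigenvalues
#' \eqn{-\lambda_m = -(m+1)(m+2)/2}.
#'
#' Evaluation uses the forward three-term recurrence
#' \deqn{Y_n(z) = \frac{1}{n}\left[2z\left(n + \tfrac12\right)Y_{n-1}(z)
#'   - (n+1)Y_{n-2}(z)\right],}
#' which is stable on the orthogonality interval at the moderate degrees used
#' here (a warning is emitted above the cap set by
#' `options(wfdrift.max_degree = )`, default 500).
#'
#' @param m single non-negative integer, the polynomial degree.
#' @param z numeric vector of evaluation points in \eqn{[-1, 1]}.
#' @param x numeric vector of allele frequencies in \eqn{[0, 1]}.
#' @return Numeric vector of polynomial values, one per evaluation point.
#' @examples
#' gegenbauer_y(1, 0.5)        # 3 * 0.5
#' gegenbauer_x(2, c(0, 0.5, 1))
#' @export
gegenbauer_y <- function(m, z) {
  m <- .check_degree(m)
  if (!is.numeric(z) || anyNA(z)) stop("'z' must be finite numeric", call. = FALSE)
  y0 <- rep.int(1, length(z))
  if (m == 0L) return(y0)
  y1 <- 3 * z
  if (m == 1L) return(y1)
  for (n in 2:m) {
    yn <- (2 * z * (n + 0.5) * y1 - (n + 1) * y0) / n
    y0 <- y1
    y1 <- yn
  }
  y1
}

#' @rdname gegenbauer_y
#' @export
gegenbauer_x <- function(m, x) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1))
    stop("allele frequency 'x' must lie in [0, 1]", call. = FALSE)
  gegenbauer_y(m, 1 - 2 * x)
}

# All X_0..X_mmax at the points x, as an (mmax+1) x length(x) matrix.
# One pass of the recurrence; used by the series evaluators.
gegenbauer_x_all <- function(mmax, x) {
  mmax <- .check_degree(mmax)
  z <- 1 - 2 * x
  out <- matrix(0, nrow = mmax + 1L, ncol = length(z))
  out[1L, ] <- 1
  if (mmax >= 1L) out[2L, ] <- 3 * z
  if (mmax >= 2L) {
    for (n in 2:mmax) {
      out[n + 1L, ] <- (2 * z * (n + 0.5) * out[n, ] - (n + 1) * out[n - 1L, ]) / n
    }
  }
  out
}

## ---- exact polynomial representation (monomial basis in x on [0, 1]) ----

poly_eval <- function(coef, x) {
  # Horner; coef[1] is the constant term
  out <- rep.int(0, length(x))
  for (ci in rev(coef)) out <- out * x + ci
  out
}

poly_deriv <- function(coef) {
  n <- length(coef)
  if (n <= 1L) return(0)
  coef[-1L] * seq_len(n - 1L)
}

poly_mul <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

poly_add <- function(a, b) {
  n <- max(length(a), length(b))
  out <- numeric(n)
  out[seq_along(a)] <- a
  out[seq_along(b)] <- out[seq_along(b)] + b
  out
}

poly_trim <- function(coef, tol = 0) {
  n <- length(coef)
  while (n > 1L && abs(coef[n]) <= tol) n <- n - 1L
  coef[seq_len(n)]
}

.gegenbauer_coef_cache <- new.env(parent = emptyenv())

#' Monomial coefficients of the rescaled Gegenbauer polynomial
#'
#' Returns the exact monomial-basis coefficients of \eqn{X_m(x)} on
#' \eqn{[0, 1]} (constant term first), computed once per degree by running the
#' three-term recurrence on coefficient vectors and cached.
#'
#' @inheritParams gegenbauer_y
#' @return Numeric vector of length `m + 1`.
#' @export
gegenbauer_x_coef <- function(m) {
  m <- .check_degree(m)
  key <- as.character(m)
  if (!is.null(got <- .gegenbauer_coef_cache[[key]])) return(got)
  # X_m(x) = Y_m(1 - 2x); recurrence multiplies by z = 1 - 2x
  zpoly <- c(1, -2)
  if (is.null(.gegenbauer_coef_cache[["1"]])) {
    .gegenbauer_coef_cache[["0"]] <- 1
    .gegenbauer_coef_cache[["1"]] <- c(3, -6)
  }
  top <- max(as.integer(ls(.gegenbauer_coef_cache)))
  if (m > top) {
    for (n in (top + 1L):m) {
      prev1 <- .gegenbauer_coef_cache[[as.character(n - 1L)]]
      prev2 <- .gegenbauer_coef_cache[[as.character(n - 2L)]]
      cn <- poly_add(poly_mul(zpoly, prev1) * (2 * (n + 0.5) / n),
                     -(n + 1) / n * prev2)
      .gegenbauer_coef_cache[[as.character(n)]] <- cn
    }
  }
  .gegenbauer_coef_cache[[key]]
}

## ---- quadrature ----

.gauss_cache <- new.env(parent = emptyenv())

# Gauss-Legendre nodes/weights on [0,1], exact for polynomials of degree
# up to 2*nodes - 1; node count chosen from the integrand degree.
gauss_rule <- function(degree) {
  nodes <- ceiling((degree + 2) / 2) + 1L
  key <- as.character(nodes)
  if (is.null(.gauss_cache[[key]])) {
    .gauss_cache[[key]] <- pracma::gaussLegendre(nodes, 0, 1)
  }
  .gauss_cache[[key]]
}

# Integrate f over [0,1] exactly when f is polynomial of the stated degree.
gauss_integrate <- function(f, degree) {
  gl <- gauss_rule(degree)
  sum(gl$w * f(gl$x))
}

#' Weighted norm of the drift eigenfunctions
#'
#' Computes \eqn{(X_m, wX_m) = \int_0^1 x(1-x) X_m(x)^2\,dx}, the squared norm
#' of \eqn{X_m} under the drift weight \eqn{w(x) = x(1-x)}.  The default
#' evaluates the integral by Gauss-Legendre quadrature (exact for polynomials);
#' `method = "closed"` returns the closed form
#' \eqn{(m+1)(m+2) / (8(m + 3/2))} implied by the spectral-coefficient
#' normalisation.
#'
#' @inheritParams gegenbauer_y
#' @param method `"quadrature"` (default) or `"closed"`.
#' @return Positive scalar.
#' @export
weighted_norm <- function(m, method = c("quadrature", "closed")) {
  m <- .check_degree(m)
  method <- match.arg(method)
  if (method == "closed") return((m + 1) * (m + 2) / (8 * (m + 1.5)))
  gauss_integrate(function(x) x * (1 - x) * gegenbauer_x(m, x)^2, 2 * m + 2)
}

#' Basic integrals of the drift eigenfunctions
#'
#' Exact Gauss-Legendre integrals over \eqn{[0, 1]}:
#' `integral_x()` gives \eqn{\int X_m\,dx}, `integral_x_x()` gives
#' \eqn{\int x\,X_m\,dx} and `integral_1mx_x()` gives
#' \eqn{\int (1-x)\,X_m\,dx}.  These fix the boundary-atom coefficients of the
#' global solution: \eqn{a_{m,0} = -\int(1-x)X_m = -1/2} and
#' \eqn{a_{m,1} = -\int x X_m = (-1)^{m+1}/2} for every \eqn{m}.
#'
#' @inheritParams gegenbauer_y
#' @return Scalar integral value.
#' @export
integral_x <- function(m) {
  m <- .check_degree(m)
  gauss_integrate(function(x) gegenbauer_x(m, x), m)
}

#' @rdname integral_x
#' @export
integral_x_x <- function(m) {
  m <- .check_degree(m)
  gauss_integrate(function(x) x * gegenbauer_x(m, x), m + 1)
}

#' @rdname integral_x
#' @export
integral_1mx_x <- function(m) {
  m <- .check_degree(m)
  gauss_integrate(function(x) (1 - x) * gegenbauer_x(m, x), m + 1)
}

#' Moments of the drift eigenfunctions against monomials
#'
#' Closed form for \eqn{\int_0^1 x^n X_{m-1}(x)\,dx}, \eqn{n \ge 1},
#' \eqn{m \ge 1}:
#' \deqn{(-1)^m \tfrac12\left\{\frac{(n-1)\cdots(n-m)}{(n+1)\cdots(n+m)}
#'   - 1\right\}.}
#' The product ratio is accumulated factor-by-factor so the expression is
#' well behaved for large `m`; when \eqn{m > n - 1} the numerator contains the
#' factor zero and the value collapses to \eqn{(-1)^{m+1}/2}.
#'
#' @param n integer moment order, `n >= 1`.
#' @param m integer index, `m >= 1` (the integrand uses \eqn{X_{m-1}}).
#' @return Scalar integral value.
#' @export
integral_xn_x <- function(n, m) {
  if (length(n) != 1L || n < 1 || n != round(n)) stop("'n' must be an integer >= 1", call. = FALSE)
  if (length(m) != 1L || m < 1 || m != round(m)) stop("'m' must be an integer >= 1", call. = FALSE)
  k <- seq_len(m)
  ratio <- prod((n - k) / (n + k))
  (-1)^m * 0.5 * (ratio - 1)
}

## ---- operators ----

#' Forward generator and its adjoint on polynomials
#'
#' Exact application of the Wright-Fisher forward operator
#' \eqn{L u = \tfrac12 \partial_x^2\left(x(1-x)u\right)} and of its formal
#' adjoint \eqn{L^* \phi = \tfrac12 x(1-x) \partial_x^2 \phi} to a polynomial
#' given by its monomial coefficients on \eqn{[0, 1]} (constant term first).
#' On the eigenbasis, \eqn{L X_m = -\lambda_m X_m} and
#' \eqn{L^*(w X_m) = -\lambda_m\, w X_m} with
#' \eqn{\lambda_m = (m+1)(m+2)/2}.
#'
#' @param coef numeric vector of polynomial coefficients, constant term first.
#' @return Coefficient vector of the resulting polynomial.
#' @examples
#' apply_generator(gegenbauer_x_coef(3))  # equals -10 * X_3
#' @export
apply_generator <- function(coef) {
  if (!is.numeric(coef) || length(coef) == 0L) stop("'coef' must be a numeric vector", call. = FALSE)
  wf <- poly_mul(c(0, 1, -1), coef)       # x(1-x) * f
  poly_trim(0.5 * poly_deriv(poly_deriv(wf)))
}

#' @rdname apply_generator
#' @export
apply_adjoint <- function(coef) {
  if (!is.numeric(coef) || length(coef) == 0L) stop("'coef' must be a numeric vector", call. = FALSE)
  d2 <- poly_deriv(poly_deriv(coef))
  poly_trim(0.5 * poly_mul(c(0, 1, -1), d2))
}
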