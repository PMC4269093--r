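# Kahan compensated summation; the absorption-time series alternate in sign
# through X_{2m}(p) so naive accumulation loses a few digits at large M.
kahan_sum <- function(x) {
  s <- 0
  comp <- 0
  for (xi in x) {
    y <- xi - comp
    tt <- s + y
    comp <- (tt - s) - y
    s <- tt
  }
  s
}

#' Loss, fixation and coexistence probabilities under pure drift
#'
#' Series expressions read off the global solution started at frequency `p`:
#' the loss probability of allele \eqn{A_1} (fixation of \eqn{A_2}) is the
#' mass of the atom at 0,
#' \deqn{P(X_t = 0 \mid X_0 = p) = 1 - p - \tfrac12 \sum_{m=0}^{M}
#'   c_m e^{-\lambda_m t},}
#' the fixation probability of \eqn{A_1} is the atom at 1,
#' \deqn{P(X_t = 1 \mid X_0 = p) = p - \tfrac12 \sum_{m=0}^{M}
#'   (-1)^m c_m e^{-\lambda_m t},}
#' and the coexistence probability is the interior mass
#' \deqn{P(X_t \in (0,1) \mid X_0 = p) = \sum_{2m \le M} c_{2m}
#'   e^{-\lambda_{2m} t}}
#' (odd terms vanish on integration).  The three sum to 1 at every time.
#'
#' @param p initial frequency of allele \eqn{A_1}, in \eqn{[0, 1]}.
#' @param t numeric vector of diffusion times (units of 2N generations).
#' @param M truncation order, default 100.
#' @return Numeric vector of probabilities, one per element of `t`.
#' @examples
#' loss_probability(0.3, 1) + fixation_probability(0.3, 1) +
#'   coexistence_probability(0.3, 1)
#' @export
loss_probability <- function(p, t, M = 100L) {
  .atom_series(p, t, M, boundary = 0L)
}

#' @rdname loss_probability
#' @export
fixation_probability <- function(p, t, M = 100L) {
  .atom_series(p, t, M, boundary = 1L)
}

.atom_series <- function(p, t, M, boundary) {
  p <- .check_p(p)
  .check_t(t)
  if (p %in% c(0, 1)) {
    base <- if (boundary == 0L) 1 - p else p
    return(rep.int(base, length(t)))
  }
  sc <- spectral_coefficients(p, M)
  .warn_truncation(sc, t)
  a <- if (boundary == 0L) sc$a0 else sc$a1
  base <- if (boundary == 0L) sc$b0 else sc$b1
  vapply(t, function(ti) base + sum(sc$c * a * exp(-sc$lambda * ti)), numeric(1))
}

#' @rdname loss_probability
#' @export
coexistence_probability <- function(p, t, M = 100L) {
  p <- .check_p(p)
  .check_t(t)
  if (p %in% c(0, 1)) return(rep.int(0, length(t)))
  sc <- spectral_coefficients(p, M)
  .warn_truncation(sc, t)
  even <- seq(1L, M + 1L, by = 2L)   # degrees 0, 2, 4, ...
  vapply(t, function(ti) sum(sc$c[even] * exp(-sc$lambda[even] * ti)), numeric(1))
}

#' Mean time to absorption (loss or fixation)
#'
#' Expected diffusion time until one allele is lost, started from frequency
#' `p`.  `absorption_mean_series()` sums the spectral series
#' \deqn{E(T) = \sum_{m \ge 0} \frac{16\, p(1-p)\,(2m + 3/2)}
#'   {(2m+1)^2 (2m+2)^2}\, X_{2m}(p),}
#' truncated after `M` terms; `absorption_mean_closed()` returns the closed
#' form \eqn{-2\{p \ln p + (1-p)\ln(1-p)\}} (with \eqn{0 \ln 0 := 0}), the
#' solution of \eqn{Lv = -1}, \eqn{v(0)=v(1)=0}.  Multiply by \eqn{2N} for
#' generations.
#'
#' @inheritParams loss_probability
#' @param M number of (even-degree) series terms, default 200.
#' @return Scalar expected absorption time in diffusion units.
#' @examples
#' absorption_mean_closed(0.5)           # 2 log 2
#' absorption_mean_series(0.5, M = 200)
#' @export
absorption_mean_series <- function(p, M = 200L) {
  p <- .check_p(p)
  if (p %in% c(0, 1)) return(0)
  m <- 0:(M - 1L)
  X2m <- gegenbauer_x_all(2L * (M - 1L), p)[2L * m + 1L, 1L]
  terms <- 16 * p * (1 - p) * (2 * m + 1.5) / ((2 * m + 1)^2 * (2 * m + 2)^2) * X2m
  kahan_sum(terms)
}

#' @rdname absorption_mean_series
#' @export
absorption_mean_closed <- function(p) {
  p <- .check_p(p)
  xlx <- function(q) if (q > 0) q * log(q) else 0
  -2 * (xlx(p) + xlx(1 - p))
}

#' Second moment and variance of the absorption time
#'
#' The spectral series for the second moment,
#' \deqn{E(T^2) = \sum_{m \ge 0} \frac{64\, p(1-p)\,(2m + 3/2)}
#'   {(2m+1)^3 (2m+2)^3}\, X_{2m}(p)
#'   = \sum_{m} \frac{2\,c_{2m}}{\lambda_{2m}^2},}
#' truncated after `M` terms, and the variance
#' \eqn{E(T^2) - E(T)^2}.
#'
#' @inheritParams absorption_mean_series
#' @return Scalar moment (squared diffusion-time units).
#' @export
absorption_second_moment <- function(p, M = 200L) {
  p <- .check_p(p)
  if (p %in% c(0, 1)) return(0)
  m <- 0:(M - 1L)
  X2m <- gegenbauer_x_all(2L * (M - 1L), p)[2L * m + 1L, 1L]
  terms <- 64 * p * (1 - p) * (2 * m + 1.5) / ((2 * m + 1)^3 * (2 * m + 2)^3) * X2m
  kahan_sum(terms)
}

#' @rdname absorption_second_moment
#' @export
absorption_variance <- function(p, M = 200L) {
  absorption_second_moment(p, M) - absorption_mean_series(p, M)^2
}

#' Absorption-time summary
#'
#' Bundles the mean (series and closed form), second moment and variance of
#' the absorption time at one initial frequency.
#'
#' @inheritParams absorption_mean_series
#' @return Object of class `absorption_summary`: list with `p`, `M`,
#'   `mean_series`, `mean_closed`, `second_moment`, `variance`.
#' @export
absorption_summary <- function(p, M = 200L) {
  structure(list(
    p = p, M = as.integer(M),
    mean_series = absorption_mean_series(p, M),
    mean_closed = absorption_mean_closed(p),
    second_moment = absorption_second_moment(p, M),
    variance = absorption_variance(p, M)
  ), class = "absorption_summary")
}

#' @export
print.absorption_summary <- function(x, ...) {
  cat("Absorption time of the drift diffusion, p =", format(x$p), "\n")
  cat(sprintf("  mean (series, %d terms): %.8f\n", x$M, x$mean_series))
  cat(sprintf("  mean (closed form)     : %.8f\n", x$mean_closed))
  cat(sprintf("  second moment          : %.8f\n", x$second_moment))
  cat(sprintf("  variance               : %.8f\n", x$variance))
  invisible(x)
}

#' Probability density of the absorption time
#'
#' Density of the first hitting time of \eqn{\{0, 1\}},
#' \eqn{\phi(t, p) = \frac{d}{dt}\,P(X_t \in \{0,1\})}, computed term-wise:
#' \deqn{\phi(t,p) = -\sum_{m=0}^{M} \lambda_m c_m (a_{m,0} + a_{m,1})
#'   e^{-\lambda_m t} = \sum_{2m \le M} \lambda_{2m} c_{2m}
#'   e^{-\lambda_{2m} t}}
#' (odd terms drop since \eqn{a_{m,0} + a_{m,1} = 0} for odd \eqn{m}).  It is
#' nonnegative and integrates to 1 over \eqn{(0, \infty)} for interior `p`.
#'
#' @inheritParams loss_probability
#' @param t numeric vector of positive diffusion times.
#' @return Numeric vector of density values.
#' @export
absorption_time_density <- function(p, t, M = 100L) {
  p <- .check_p(p)
  if (!is.numeric(t) || any(t <= 0)) stop("'t' must be positive", call. = FALSE)
  if (p %in% c(0, 1)) return(rep.int(0, length(t)))
  sc <- spectral_coefficients(p, M)
  .warn_truncation(sc, t)
  keep <- -sc$lambda * sc$c * (sc$a0 + sc$a1)   # zero for odd degrees
  vapply(t, function(ti) sum(keep * exp(-sc$lambda * ti)), numeric(1))
}

#' n-th moment of the allele frequency
#'
#' The moment \eqn{m_n(t) = (u, x^n)} of the global solution, via the exact
#' integrals of monomials against the eigenbasis:
#' \deqn{m_n(t) = p + \sum_{i=1}^{M} c_{i-1}\left(\int_0^1 x^n X_{i-1}\,dx
#'   + a_{i-1,1}\right) e^{-\lambda_{i-1} t},}
#' where \eqn{\int x^n X_{i-1} = (-1)^i\tfrac12\{\prod_{k=1}^{i}
#' \frac{n-k}{n+k} - 1\}} and \eqn{a_{i-1,1} = (-1)^i/2}, so each term
#' carries the factor \eqn{(-1)^i \prod_k \frac{n-k}{n+k}/2} and the series
#' effectively terminates once the product contains a zero factor in the
#' symmetric tail.  \eqn{m_1(t) = p} for all \eqn{t} (martingale), and
#' \eqn{m_n(t) \to p} as \eqn{t \to \infty} (only the atom at 1 contributes).
#'
#' @param n integer moment order, `n >= 1`.
#' @inheritParams loss_probability
#' @param M number of series terms, default 200.
#' @return Numeric vector of moment values, one per element of `t`.
#' @examples
#' frequency_moment(2, 0.3, t = 1)      # p + (p^2 - p) e^{-t}
#' @export
frequency_moment <- function(n, p, t, M = 200L) {
  if (length(n) != 1L || n < 1 || n != round(n))
    stop("'n' must be an integer >= 1", call. = FALSE)
  p <- .check_p(p)
  .check_t(t)
  if (p %in% c(0, 1)) return(rep.int(p, length(t)))
  if (n == 1) return(rep.int(p, length(t)))
  i <- seq_len(M)
  sc <- spectral_coefficients(p, M - 1L)
  wcoef <- vapply(i, function(ii) integral_xn_x(n, ii), numeric(1)) + sc$a1
  rates <- sc$lambda
  vapply(t, function(ti) p + sum(sc$c * wcoef * exp(-rates * ti)), numeric(1))
}

#' Expected heterozygosity under drift
#'
#' \eqn{H_t = \int_0^1 2x(1-x)\,u(x,t)\,dx = 2p(1-p)\,e^{-t}}: the drift
#' weight is (up to the factor 2) the lowest eigenfunction times the weight,
#' so exactly one spectral term survives and the decay rate is
#' \eqn{\lambda_0 = 1} — no truncation error.
#'
#' @inheritParams loss_probability
#' @return Numeric vector \eqn{2p(1-p)e^{-t}}.
#' @examples
#' heterozygosity(0.5, 1)   # 0.5 * exp(-1)
#' @export
heterozygosity <- function(p, t) {
  p <- .check_p(p)
  .check_t(t)
  2 * p * (1 - p) * exp(-t)
}

#' Time series of drift quantities
#'
#' Tabulates the named drift quantities on a time grid (geometric spacing by
#' default, covering the window where absorption probabilities rise fastest).
#'
#' @inheritParams loss_probability
#' @param t_grid numeric vector of diffusion times; default 60 geometrically
#'   spaced points on \eqn{[0.01, 20]}.
#' @param moments integer vector of moment orders to include (may be empty).
#' @return Object of class `quantity_series`: a long-format data frame with
#'   columns `t`, `quantity`, `value` and attributes `p`, `M`.
#' @export
quantity_series <- function(p, t_grid = exp(seq(log(0.01), log(20), length.out = 60)),
                            M = 100L, moments = integer(0)) {
  p <- .check_p(p)
  .check_t(t_grid)
  qs <- list(
    loss_prob = suppressWarnings(loss_probability(p, t_grid, M)),
    fix_prob = suppressWarnings(fixation_probability(p, t_grid, M)),
    coexist_prob = suppressWarnings(coexistence_probability(p, t_grid, M)),
    heterozygosity = heterozygosity(p, t_grid)
  )
  for (n in moments) {
    qs[[paste0("moment_", n)]] <- suppressWarnings(frequency_moment(n, p, t_grid, M))
  }
  out <- data.frame(
    t = rep(t_grid, times = length(qs)),
    quantity = rep(names(qs), each = length(t_grid)),
    value = unlist(qs, use.names = FALSE)
  )
  attr(out, "p") <- p
  attr(out, "M") <- as.integer(M)
  class(out) <- c("quantity_series", "data.frame")
  out
}

#' @export
print.quantity_series <- function(x, ...) {
  cat("Drift quantity series: p =", format(attr(x, "p")),
      "M =", attr(x, "M"), "\n")
  cat("  quantities:", paste(unique(x$quantity), collapse = ", "), "\n")
  cat("  time grid :", length(unique(x$t)), "points in [",
      format(min(x$t)), ",", format(max(x$t)), "]\n")
  invisible(x)
}

#' @export
plot.quantity_series <- function(x, ...) {
  qs <- split(as.data.frame(x), x$quantity)
  graphics::plot(NULL, xlim = range(x$t), ylim = c(0, 1),
                 xlab = "diffusion time t", ylab = "value",
                 main = sprintf("Drift quantities, p = %s", format(attr(x, "p"))), ...)
  for (i in seq_along(qs)) {
    graphics::lines(qs[[i]]$t, qs[[i]]$value, col = i, lty = i)
  }
  graphics::legend("right", legend = names(qs), col = seq_along(qs),
                   lty = seq_along(qs), bty = "n", cex = 0.8)
  invisible(x)
}
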