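#' Discrete Wright-Fisher chain
#'
#' The exact two-allele Wright-Fisher Markov chain: a diploid population of
#' size `N` carries `2N` gene copies; the count \eqn{Y_n} of allele \eqn{A_1}
#' evolves by binomial resampling,
#' \deqn{P(Y_{n+1} = j \mid Y_n = i) = \binom{2N}{j}
#'   \left(\frac{i}{2N}\right)^j \left(1 - \frac{i}{2N}\right)^{2N - j},}
#' with absorbing states 0 and \eqn{2N}.  Diffusion time relates to
#' generations by \eqn{t = n / 2N}.
#'
#' @param N diploid population size (so `2N` gene copies), `N >= 1`.
#' @param i0 initial count of allele \eqn{A_1}, in `0..2N`.
#' @return Object of class `wf_chain` with fields `N`, `i0`, `p = i0/(2N)`.
#' @examples
#' ch <- wf_chain(N = 16, i0 = 16)  # p = 0.5
#' @export
wf_chain <- function(N, i0) {
  if (length(N) != 1L || N < 1 || N != round(N))
    stop("'N' must be a positive integer", call. = FALSE)
  if (length(i0) != 1L || i0 < 0 || i0 > 2 * N || i0 != round(i0))
    stop("'i0' must be an integer in 0..2N", call. = FALSE)
  structure(list(N = as.integer(N), i0 = as.integer(i0),
                 p = i0 / (2 * N)), class = "wf_chain")
}

#' @export
print.wf_chain <- function(x, ...) {
  cat(sprintf("Wright-Fisher chain: N = %d (2N = %d copies), i0 = %d (p = %s)\n",
              x$N, 2L * x$N, x$i0, format(x$p)))
  invisible(x)
}

#' Binomial transition matrix of the chain
#'
#' Row-stochastic \eqn{(2N+1)\times(2N+1)} matrix of the one-generation
#' binomial resampling kernel; rows 0 and \eqn{2N} are point masses
#' (absorbing).  The pmf is evaluated on the log scale internally
#' (`stats::dbinom`), so large `N` does not overflow.
#'
#' @param N diploid population size.
#' @return Numeric matrix with rows/columns indexed by counts `0..2N`.
#' @examples
#' P <- transition_matrix(2)
#' P[3, 3]   # C(4,2) (1/2)^4 = 0.375
#' @export
transition_matrix <- function(N) {
  if (length(N) != 1L || N < 1 || N != round(N))
    stop("'N' must be a positive integer", call. = FALSE)
  n2 <- 2L * as.integer(N)
  states <- 0:n2
  t(vapply(states, function(i) stats::dbinom(states, n2, i / n2),
           numeric(n2 + 1L)))
}

#' Exact distribution after a number of generations
#'
#' Propagates the point mass at `i0` through the binomial kernel for the given
#' number of generations, returning the exact distribution over counts
#' `0..2N`.  For small state spaces this uses repeated dense matrix-vector
#' products; above `2N + 1 > 10000` states the kernel rows are generated on
#' the fly with support truncated far in the binomial tail, bounding memory.
#'
#' @param chain a [wf_chain()] object.
#' @param generations non-negative integer.
#' @return Object of class `wf_distribution`: data frame with columns `state`,
#'   `prob` and attributes `N`, `generation`.
#' @examples
#' d <- propagate(wf_chain(2, 2), 3)
#' sum(d$prob * d$state) / 4   # martingale: still 0.5
#' @export
propagate <- function(chain, generations) {
  stopifnot(inherits(chain, "wf_chain"))
  if (length(generations) != 1L || generations < 0 || generations != round(generations))
    stop("'generations' must be a non-negative integer", call. = FALSE)
  n2 <- 2L * chain$N
  v <- numeric(n2 + 1L)
  v[chain$i0 + 1L] <- 1
  g <- as.integer(generations)
  if (g > 0L) {
    if (n2 + 1L <= 10000L) {
      P <- transition_matrix(chain$N)
      for (k in seq_len(g)) v <- drop(v %*% P)
    } else {
      states <- 0:n2
      for (k in seq_len(g)) {
        vn <- numeric(n2 + 1L)
        active <- which(v > 1e-300)
        for (ii in active) {
          i <- ii - 1L
          if (i == 0L || i == n2) { vn[ii] <- vn[ii] + v[ii]; next }
          q <- i / n2
          sd <- sqrt(n2 * q * (1 - q))
          lo <- max(0L, floor(n2 * q - 12 * sd - 1))
          hi <- min(n2, ceiling(n2 * q + 12 * sd + 1))
          js <- lo:hi
          vn[js + 1L] <- vn[js + 1L] + v[ii] * stats::dbinom(js, n2, q)
        }
        v <- vn / sum(vn)
      }
    }
  }
  out <- data.frame(state = 0:n2, prob = v)
  attr(out, "N") <- chain$N
  attr(out, "generation") <- g
  class(out) <- c("wf_distribution", "data.frame")
  out
}

# Stirling numbers of the second kind S(k, j), j = 0..k
stirling2_row <- function(k) {
  row <- c(1)                       # S(0, 0)
  if (k == 0L) return(row)
  for (n in seq_len(k)) {
    prev <- c(row, 0)
    row <- numeric(n + 1L)
    for (j in seq_len(n)) {
      row[j + 1L] <- prev[j] + j * prev[j + 1L]
    }
  }
  row
}

#' One-generation update of the frequency moments
#'
#' Updates the moments about zero \eqn{m_k = E(X^k)} of the allele frequency
#' across one generation of binomial resampling.  Two forms are available:
#'
#' * `exact = TRUE` (reference): the exact linear update from binomial
#'   moments, \eqn{m_k' = \sum_{j=1}^k S(k,j)\,(2N)_j\,(2N)^{-k} m_j}, with
#'   \eqn{S(k,j)} Stirling numbers of the second kind and \eqn{(2N)_j} the
#'   falling factorial.
#' * `exact = FALSE`: the drift approximation retaining terms to order
#'   \eqn{1/N}, \eqn{m_k' = \{1 - k(k-1)/(4N)\} m_k + \{k(k-1)/(4N)\}
#'   m_{k-1}}, the per-generation form of the moment ODE system (one
#'   generation is \eqn{\delta t = 1/2N} in diffusion time).
#'
#' @param N diploid population size.
#' @param moments numeric vector `c(m_1, ..., m_k)` (with `m_0 = 1` implicit).
#' @param exact logical; use the exact binomial update (default) or the
#'   order-`1/N` drift approximation.
#' @return Updated numeric vector of the same length.
#' @examples
#' exact_moment_step(10, c(0.5, 0.3))        # m_2' = m_2 (1 - 1/2N) + m_1/2N
#' @export
exact_moment_step <- function(N, moments, exact = TRUE) {
  if (length(N) != 1L || N < 1 || N != round(N))
    stop("'N' must be a positive integer", call. = FALSE)
  kmax <- length(moments)
  if (kmax < 1L) stop("'moments' must contain at least m_1", call. = FALSE)
  n2 <- 2 * N
  m_full <- c(1, moments)           # m_0..m_k
  out <- numeric(kmax)
  for (k in seq_len(kmax)) {
    if (exact) {
      S <- stirling2_row(k)         # S(k, 0..k)
      j <- 0:k
      ff <- c(1, cumprod(n2 - 0:(k - 1L)))   # (2N)_j falling factorial
      out[k] <- sum(S * ff / n2^k * m_full[j + 1L])
    } else {
      gam <- k * (k - 1) / (4 * N)
      out[k] <- (1 - gam) * m_full[k + 1L] + gam * m_full[k]
    }
  }
  out
}

#' Moment ODE system of the diffusion limit
#'
#' Solves the lower-triangular linear system
#' \eqn{\dot m_k = -\tfrac{k(k-1)}{2} m_k + \tfrac{k(k-1)}{2} m_{k-1}} with
#' initial moments \eqn{m_j(0) = p^j}, the \eqn{N \to \infty} limit of the
#' per-generation moment recursion in diffusion time, and returns
#' \eqn{m_k(t)}.  Uses a stiff-capable integrator (`deSolve::ode`) at tight
#' tolerance; agrees with the spectral moment series.
#'
#' @param k moment order, `k >= 1`.
#' @param p initial frequency in \eqn{[0, 1]}.
#' @param t numeric vector of diffusion times.
#' @return Numeric vector \eqn{m_k(t)}, one value per element of `t`.
#' @examples
#' solve_moment_ode(2, 0.3, 1)   # p + (p^2 - p) e^{-t}
#' @export
solve_moment_ode <- function(k, p, t) {
  if (length(k) != 1L || k < 1 || k != round(k))
    stop("'k' must be an integer >= 1", call. = FALSE)
  p <- .check_p(p)
  .check_t(t)
  if (k == 1L) return(rep.int(p, length(t)))
  times <- sort(unique(c(0, t)))
  y0 <- p^(2:k)
  sol <- deSolve::ode(y = y0, times = times, func = function(time, y, parms) {
    m_full <- c(p, y)
    kk <- 2:k
    list(kk * (kk - 1) / 2 * (m_full[kk - 1L] - m_full[kk]))
  }, parms = NULL, rtol = 1e-12, atol = 1e-12)
  mk <- sol[, k, drop = TRUE]       # column 1 is time; y columns 2..k
  mk[match(t, sol[, 1])]
}

#' Monte-Carlo trajectories of the chain
#'
#' Simulates `n_paths` independent trajectories of the chain for the given
#' number of generations by per-path binomial draws; paths are frozen once
#' absorbed at 0 or `2N`.  A seed is mandatory: identical configuration and
#' seed give a bit-identical ensemble (Mersenne-Twister stream).
#'
#' @param chain a [wf_chain()] object.
#' @param n_paths number of trajectories.
#' @param generations number of generations to simulate.
#' @param seed integer RNG seed (required).
#' @return Object of class `wf_ensemble`: list with `paths` (integer matrix,
#'   `n_paths` x `generations + 1`), `absorbed_at` (generation of absorption,
#'   `NA` if still segregating), and the run configuration.
#' @examples
#' ens <- wf_simulate(wf_chain(10, 10), n_paths = 100, generations = 50, seed = 1)
#' mean(ens$paths[, 51]) / 20   # close to p = 0.5
#' @export
wf_simulate <- function(chain, n_paths, generations, seed) {
  stopifnot(inherits(chain, "wf_chain"))
  if (missing(seed) || length(seed) != 1L || !is.finite(seed))
    stop("an integer 'seed' is required for reproducible ensembles", call. = FALSE)
  if (n_paths < 1 || generations < 0) stop("invalid ensemble size", call. = FALSE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  n2 <- 2L * chain$N
  n_paths <- as.integer(n_paths)
  g <- as.integer(generations)
  paths <- matrix(NA_integer_, nrow = n_paths, ncol = g + 1L)
  paths[, 1L] <- chain$i0
  cur <- rep.int(chain$i0, n_paths)
  absorbed_at <- rep.int(if (chain$i0 %in% c(0L, n2)) 0L else NA_integer_, n_paths)
  for (k in seq_len(g)) {
    alive <- which(cur > 0L & cur < n2)
    if (length(alive)) {
      cur[alive] <- stats::rbinom(length(alive), n2, cur[alive] / n2)
      hit <- alive[cur[alive] == 0L | cur[alive] == n2]
      absorbed_at[hit] <- k
    }
    paths[, k + 1L] <- cur
  }
  structure(list(paths = paths, absorbed_at = absorbed_at,
                 N = chain$N, i0 = chain$i0, p = chain$p,
                 n_paths = n_paths, generations = g,
                 seed = as.integer(seed)), class = "wf_ensemble")
}

#' @export
print.wf_ensemble <- function(x, ...) {
  n2 <- 2L * x$N
  final <- x$paths[, ncol(x$paths)]
  cat(sprintf("Wright-Fisher ensemble: N = %d, p = %s, %d paths x %d generations (seed %d)\n",
              x$N, format(x$p), x$n_paths, x$generations, x$seed))
  cat(sprintf("  fixed at 2N: %.4f   lost: %.4f   segregating: %.4f\n",
              mean(final == n2), mean(final == 0L),
              mean(final > 0L & final < n2)))
  invisible(x)
}

#' Expected generations to absorption (exact)
#'
#' Solves the transient linear system \eqn{(I - Q)\tau = 1} over the
#' non-absorbing states of the chain (`Q` the kernel restricted to
#' `1..2N-1`) and returns \eqn{\tau(i_0)}, the exact expected number of
#' generations until loss or fixation.  For large `N` this approaches
#' \eqn{-4N\{p\ln p + (1-p)\ln(1-p)\}} generations (the diffusion closed
#' form times \eqn{2N}).
#'
#' @param chain a [wf_chain()] object.
#' @return Scalar expected number of generations (0 if `i0` starts absorbed).
#' @examples
#' mean_absorption_generations(wf_chain(1, 1))  # 2 generations
#' @export
mean_absorption_generations <- function(chain) {
  stopifnot(inherits(chain, "wf_chain"))
  n2 <- 2L * chain$N
  if (chain$i0 %in% c(0L, n2)) return(0)
  P <- transition_matrix(chain$N)
  idx <- 2:n2                      # transient states 1..2N-1
  Q <- P[idx, idx, drop = FALSE]
  tau <- solve(diag(length(idx)) - Q, rep.int(1, length(idx)))
  unname(tau[chain$i0])
}
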