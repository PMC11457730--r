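#' Kraskov k-nearest-neighbour mutual information estimate
#'
#' Estimates the mutual information I(X; Y) in nats between two (possibly
#' multivariate) continuous variables from paired samples, using the
#' Kraskov-Stoegbauer-Grassberger k-NN estimator (their algorithm 1) with the
#' max-norm metric: for each point the distance \eqn{\epsilon_i} to its k-th
#' nearest neighbour in the joint space is found, the numbers \eqn{n_x, n_y}
#' of points strictly within \eqn{\epsilon_i} in each marginal space are
#' counted, and
#' \deqn{\hat I = \psi(k) + \psi(n) - \langle \psi(n_x + 1) + \psi(n_y + 1) \rangle}
#' with \eqn{\psi} the digamma function.
#'
#' Exact ties in the coordinates break the neighbour counting; duplicated
#' coordinate values are therefore perturbed by an additive uniform jitter of
#' `1e-10` times the coordinate scale (seeded, reproducible) with a warning.
#'
#' The raw estimator can be slightly negative for independent data; the
#' returned value is floored at zero, with the unfloored estimate kept in the
#' `"raw"` attribute.
#'
#' @param x,y numeric vectors or matrices (rows = paired observations).
#' @param k number of nearest neighbours (default 4).
#' @return estimated mutual information in nats (>= 0), with attribute `"raw"`
#'   holding the unfloored estimate.
#' @references Kraskov, Stoegbauer and Grassberger (2004), Phys. Rev. E 69,
#'   066138.
#' @examples
#' x <- rnorm(500)
#' y <- x + rnorm(500)
#' kraskov_mi(x, y)
#' @export
kraskov_mi <- function(x, y, k = 4L) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  n <- nrow(x)
  if (nrow(y) != n) stop("x and y must have the same number of observations")
  if (anyNA(x) || anyNA(y)) stop("NA values not allowed; drop invalid windows first")
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (n <= k + 1L) stop("need n > k + 1 observations (n = ", n, ", k = ", k, ")")

  xy <- cbind(x, y)
  if (anyDuplicated(round(xy, 12))) {
    warning("tied coordinates detected; applying 1e-10-scale jitter for neighbour counting")
    jitter1 <- function(m) {
      scale <- pmax(apply(m, 2, function(c) diff(range(c))), 1e-300)
      m + sweep(matrix(stats::runif(length(m), -0.5, 0.5), nrow(m)), 2, 1e-10 * scale, `*`)
    }
    x <- jitter1(x)
    y <- jitter1(y)
  }
  raw <- .ksg_mi_cpp(x, y, k)
  structure(max(raw, 0), raw = raw)
}

#' Permutation null distribution for a mutual-information estimate
#'
#' Re-estimates the mutual information after randomly permuting the rows of
#' `y`, destroying any dependence while preserving both marginals. The
#' resulting null distribution calibrates observed values: cooperation-free
#' surrogate pairings should land inside it.
#'
#' @param x,y numeric vectors or matrices (rows = paired observations).
#' @param k nearest-neighbour count passed to [kraskov_mi()].
#' @param n_perm number of permutations (>= 20).
#' @param seed integer seed for the permutations.
#' @return a list with `observed` (the unpermuted estimate), `null` (vector of
#'   `n_perm` permuted estimates) and `percentile` (the observed value's
#'   percentile within the null, 0-100).
#' @export
permutation_null <- function(x, y, k = 4L, n_perm = 100L, seed = 1L) {
  if (n_perm < 20L) stop("n_perm must be >= 20")
  x <- as.matrix(x)
  y <- as.matrix(y)
  observed <- as.numeric(kraskov_mi(x, y, k))
  null <- with_preserved_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      as.numeric(kraskov_mi(x, y[sample.int(nrow(y)), , drop = FALSE], k))
    }, numeric(1))
  })
  list(observed = observed, null = null,
       percentile = 100 * mean(null <= observed))
}

#' MI-cooperation index (MICI) over time for a crew session
#'
#' Splits the session into consecutive blocks and, within each block, computes
#' the Kraskov mutual information between the two operators' joint
#' cognitive-emotional state: X = (W1, AW1) and Y = (W2, AW2), the windowed
#' mental-workload and approach-withdrawal features of operators 1 and 2.
#' Features are z-scored per block before estimation (the estimator is
#' invariant to monotone rescaling in the large-sample limit; standardising
#' removes scale pathologies at finite n). Only windows valid in all four
#' series enter a block. MICI is defined on full-band features only: W and AW
#' already commit to fixed frequency bands, so no per-band MICI exists.
#'
#' @param w1,aw1,w2,aw2 [feature_series] objects on a common window grid:
#'   workload and approach-withdrawal for operators 1 and 2.
#' @param block_s block length in seconds (default 300); must span enough
#'   windows for the estimator (`> k + 1`, and at least 30 for stability).
#' @param k nearest-neighbour count (default 4).
#' @param min_windows minimum jointly valid windows per block (default 30).
#' @return a [feature_series] of kind `"MICI"` with one value per block (nats);
#'   blocks with too few valid windows are marked invalid.
#' @export
mici_series <- function(w1, aw1, w2, aw2, block_s = 300, k = 4L,
                        min_windows = 30L) {
  series <- list(w1, aw1, w2, aw2)
  stopifnot(all(vapply(series, inherits, logical(1), "feature_series")))
  n <- length(w1$values)
  if (!all(vapply(series, function(s) length(s$values) == n, logical(1))) ||
      !all(vapply(series, function(s) isTRUE(all.equal(s$start_times, w1$start_times)),
                  logical(1)))) {
    stop("the four feature series must share one window grid")
  }
  window_s <- w1$window_s
  per_block <- floor(block_s / window_s)
  if (per_block <= k + 1L) stop("block_s spans too few windows for k = ", k)
  n_blocks <- floor(n / per_block)
  if (n_blocks < 1L) stop("session shorter than one block")

  valid_all <- Reduce(`&`, lapply(series, function(s) s$valid_mask))
  vals <- rep(NA_real_, n_blocks)
  ok <- logical(n_blocks)
  starts <- numeric(n_blocks)
  for (b in seq_len(n_blocks)) {
    idx <- ((b - 1L) * per_block + 1L):(b * per_block)
    starts[b] <- w1$start_times[idx[1L]]
    use <- idx[valid_all[idx]]
    if (length(use) < max(min_windows, k + 2L)) next
    zs <- function(v) {
      s <- stats::sd(v)
      if (s < 1e-12) return(v - mean(v))
      (v - mean(v)) / s
    }
    X <- cbind(zs(w1$values[use]), zs(aw1$values[use]))
    Y <- cbind(zs(w2$values[use]), zs(aw2$values[use]))
    vals[b] <- as.numeric(kraskov_mi(X, Y, k))
    ok[b] <- TRUE
  }
  feature_series(values = vals, window_s = per_block * window_s,
                 start_times = starts, kind = "MICI",
                 operator_id = paste(w1$operator_id, w2$operator_id, sep = "+"),
                 band = "full", valid_mask = ok)
}
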