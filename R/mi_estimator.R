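# Gaussian-kernel mutual information on the normal-scores scale.
#
# All estimation happens after a rank transform, so estimates are exactly
# invariant under strictly monotone transforms of either argument and the
# null distribution of the estimator depends on the sample size only.

.icnet_cache <- new.env(parent = emptyenv())

# fixed evaluation grid for the 2-D kernel density (normal-scores scale)
.mi_grid <- seq(-4.5, 4.5, length.out = 61L)

.mi_bandwidth <- function(n) n^(-1 / 6)

# run expr with a private RNG state, restoring the caller's stream
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# normal scores: ranks mapped through the standard normal quantile function
.normal_scores <- function(x) {
  n <- length(x)
  stats::qnorm(rank(x, ties.method = "average") / (n + 1))
}

# G x n matrix of unnormalised Gaussian kernel weights at the grid points
.score_kernel <- function(z, h) {
  exp(-outer(.mi_grid, z, "-")^2 / (2 * h * h))
}

# plug-in MI (nats) of the grid KDE built from two kernel-weight matrices
.mi_plugin <- function(A, B) {
  F <- tcrossprod(A, B)
  F <- F / sum(F)
  fu <- rowSums(F)
  fv <- colSums(F)
  sum(F * (log(F) - outer(log(fu), log(fv), "+")))
}

# expected plug-in MI under independence; distribution-free given n because
# only ranks enter the estimator.  Memoised; internal fixed RNG stream.
.mi_null_mean <- function(n, ndraws = 200L) {
  key <- paste0("nb", n)
  if (!is.null(.icnet_cache[[key]])) return(.icnet_cache[[key]])
  z <- stats::qnorm(seq_len(n) / (n + 1))
  A <- .score_kernel(z, .mi_bandwidth(n))
  b <- .with_seed(903017L + n, {
    mean(vapply(seq_len(ndraws),
                function(i) .mi_plugin(A[, sample.int(n), drop = FALSE], A),
                numeric(1)))
  })
  .icnet_cache[[key]] <- b
  b
}

# centre at the null expectation, then invert the kernel-smoothing shrinkage
# (a Gaussian smoothed with bandwidth h has its correlation shrunk by 1+h^2)
.mi_correct <- function(mi_plug, n) {
  h <- .mi_bandwidth(n)
  m <- pmax(mi_plug - .mi_null_mean(n), 0)
  rho2 <- pmin((1 - exp(-2 * m)) * (1 + h * h)^2, 0.9999)
  -0.5 * log(1 - rho2)
}

#' Estimate mutual information between two expression vectors
#'
#' Gaussian-kernel mutual information in nats. Both vectors are first mapped
#' to normal scores (a rank transform), so the estimate is symmetric and
#' exactly invariant under strictly monotone transforms of either argument.
#' A product-Gaussian kernel density is integrated on a fixed grid; the
#' plug-in value is centred at its expectation under independence (which
#' depends only on the sample size) and the kernel-smoothing shrinkage is
#' inverted in closed form under a bivariate-Gaussian reference, so that for
#' Gaussian dependence with correlation rho the estimate is consistent for
#' -0.5*log(1 - rho^2).
#'
#' @param x,y numeric vectors of equal length (at least 8 finite values).
#' @return a single non-negative number, mutual information in nats. A
#'   constant input yields 0 with a warning (degenerate input).
#' @examples
#' x <- rnorm(200); y <- 0.8 * x + 0.6 * rnorm(200)
#' estimate_mi(x, y)   # close to -0.5 * log(1 - 0.64)
#' @export
estimate_mi <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (length(x) < 8L) stop("need at least 8 observations to estimate MI")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("degenerate input: constant vector, returning MI = 0")
    return(0)
  }
  n <- length(x)
  h <- .mi_bandwidth(n)
  A <- .score_kernel(.normal_scores(x), h)
  B <- .score_kernel(.normal_scores(y), h)
  .mi_correct(.mi_plugin(A, B), n)
}

# --- batch machinery shared by network inference and dysregulation ----------

# list of per-gene kernel-weight matrices for the rows of a genes x samples
# matrix; constant rows get NULL (MI defined as 0 downstream)
.kernel_list <- function(values) {
  n <- ncol(values)
  h <- .mi_bandwidth(n)
  lapply(seq_len(nrow(values)), function(i) {
    v <- values[i, ]
    if (stats::sd(v) == 0) return(NULL)
    .score_kernel(.normal_scores(v), h)
  })
}

# corrected MI for index pairs (ii, jj) into a kernel list
.mi_pairs <- function(klist, ii, jj, n) {
  plug <- vapply(seq_along(ii), function(k) {
    A <- klist[[ii[k]]]
    B <- klist[[jj[k]]]
    if (is.null(A) || is.null(B)) return(NA_real_)
    .mi_plugin(A, B)
  }, numeric(1))
  out <- .mi_correct(plug, n)
  out[is.na(plug)] <- 0
  out
}

#' Calibrate the mutual-information significance threshold
#'
#' Builds an empirical null distribution of MI by drawing random gene pairs
#' from the dataset and permuting the sample order of one member of each
#' pair, then returns the empirical (1 - pvalue) quantile. An edge whose MI
#' reaches this threshold is significant at the given per-pair p-value.
#'
#' @param dataset an [expression_dataset()].
#' @param pvalue per-pair significance level; the default is
#'   0.001.
#' @param n_null number of permuted null pairs to draw.
#' @param seed integer seed; the calibration is deterministic given the seed.
#' @return the MI threshold (nats).
#' @export
calibrate_mi_threshold <- function(dataset, pvalue = 0.001, n_null = 1e5,
                                   seed = 1L) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (!(pvalue > 0 && pvalue < 1)) stop("pvalue must be in (0, 1)")
  if (n_null * pvalue < 5) {
    stop("n_null * pvalue < 5: the (1 - pvalue) quantile would be unstable; ",
         "increase n_null")
  }
  klist <- .kernel_list(dataset$values)
  .calibrate_from_kernels(klist, ncol(dataset$values), pvalue, n_null, seed)
}

.calibrate_from_kernels <- function(klist, n, pvalue, n_null, seed) {
  usable <- which(!vapply(klist, is.null, logical(1)))
  if (length(usable) < 2L) stop("fewer than two non-constant genes")
  nulls <- .with_seed(seed, {
    ii <- sample(usable, n_null, replace = TRUE)
    jj <- sample(usable, n_null, replace = TRUE)
    plug <- vapply(seq_len(n_null), function(k) {
      .mi_plugin(klist[[ii[k]]][, sample.int(n), drop = FALSE],
                 klist[[jj[k]]])
    }, numeric(1))
    .mi_correct(plug, n)
  })
  unname(stats::quantile(nulls, 1 - pvalue, type = 1))
}
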