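#' Percentile interval of a posterior sample
#'
#' Central interval leaving `(1 - mass)/2` of the sample in each tail,
#' computed with the type-7 quantile rule (linear interpolation between order
#' statistics) for bit-reproducibility.
#'
#' @param samples numeric vector of at least 2 draws.
#' @param mass interval mass, default 0.89.
#' @return Numeric `c(low, high)`.
#' @export
percentile_interval <- function(samples, mass = 0.89) {
  if (length(samples) < 2L) stop("need at least 2 samples")
  if (!(mass > 0 && mass < 1)) stop("`mass` must be in (0, 1)")
  tail <- (1 - mass) / 2
  stats::quantile(samples, c(tail, 1 - tail), type = 7, names = FALSE)
}

#' Highest posterior density interval
#'
#' The narrowest contiguous window of the sorted sample containing
#' `ceiling(mass * n)` draws; ties between equally narrow windows are broken
#' in favour of the earliest (lowest-start) window. For a given mass its width
#' never exceeds the percentile interval's.
#'
#' @inheritParams percentile_interval
#' @return Numeric `c(low, high)`.
#' @export
hpdi <- function(samples, mass = 0.89) {
  n <- length(samples)
  if (n < 2L) stop("need at least 2 samples")
  if (!(mass > 0 && mass < 1)) stop("`mass` must be in (0, 1)")
  k <- ceiling(mass * n)
  s <- sort(samples)
  if (k >= n) return(c(s[1L], s[n]))
  starts <- seq_len(n - k + 1L)     # window = k points: s[i] .. s[i + k - 1]
  widths <- s[starts + k - 1L] - s[starts]
  i <- which.min(widths)
  c(s[i], s[i + k - 1L])
}

#' Split R-hat convergence diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, so within-chain drift inflates the statistic. Values near 1 indicate
#' the chains sample the same distribution.
#'
#' @param draws numeric matrix, iterations x chains (or a vector treated as
#'   one chain, which is split into two).
#' @return R-hat, or `NA` when the draws are constant.
#' @export
split_rhat <- function(draws) {
  if (is.vector(draws)) draws <- matrix(draws, ncol = 1L)
  niter <- nrow(draws)
  half <- floor(niter / 2)
  if (half < 2L) return(NA_real_)
  split <- cbind(draws[seq_len(half), , drop = FALSE],
                 draws[seq.int(niter - half + 1L, niter), , drop = FALSE])
  m <- ncol(split); nn <- nrow(split)
  mu <- colMeans(split)
  s2 <- apply(split, 2, stats::var)
  w <- mean(s2)
  b <- nn * stats::var(mu)
  if (!is.finite(w) || w == 0) return(NA_real_)
  sqrt(((nn - 1) / nn * w + b / nn) / w)
}

#' Summarise a posterior sample
#'
#' Mean, 89% percentile interval, 89% HPDI, and (when chain structure is
#' supplied) split R-hat and effective sample size.
#'
#' @param samples numeric vector of draws, or an iterations x chains matrix.
#' @param chains optional vector of chain ids aligned with `samples` when
#'   `samples` is a vector; ignored when `samples` is a matrix.
#' @param mass interval mass, default 0.89.
#' @return A one-row data frame: `mean`, `pi_low`, `pi_high`, `hpdi_low`,
#'   `hpdi_high`, `n_draws`, `ess`, `rhat` (`NA` when no chain structure is
#'   available).
#' @export
summarize_draws <- function(samples, chains = NULL, mass = 0.89) {
  if (is.matrix(samples)) {
    mat <- samples
    vec <- as.vector(samples)
  } else {
    vec <- samples
    mat <- NULL
    if (!is.null(chains)) {
      if (length(chains) != length(samples)) {
        stop("`chains` must align with `samples`")
      }
      byc <- split(samples, chains)
      len <- unique(lengths(byc))
      if (length(len) == 1L) mat <- do.call(cbind, byc)
    }
  }
  if (length(vec) < 2L) stop("need at least 2 samples")
  pi <- percentile_interval(vec, mass)
  hp <- hpdi(vec, mass)
  rhat <- ess <- NA_real_
  if (!is.null(mat)) {
    rhat <- split_rhat(mat)
    ess <- tryCatch(
      sum(coda::effectiveSize(coda::as.mcmc.list(
        lapply(seq_len(ncol(mat)), function(j) coda::mcmc(mat[, j]))))),
      error = function(e) NA_real_)
  }
  data.frame(mean = mean(vec), pi_low = pi[1], pi_high = pi[2],
             hpdi_low = hp[1], hpdi_high = hp[2],
             n_draws = length(vec), ess = ess, rhat = rhat)
}
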