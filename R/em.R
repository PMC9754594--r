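#' Fit signature activities by expectation-maximization
#'
#' Models the channel counts of a segment as a mixture of multinomials whose
#' components are the catalog signatures; the mixture coefficients are the
#' signature activities. The E-step computes the responsibility of signature
#' s for channel k, `pi_s mu_sk / sum_t pi_t mu_tk`; the M-step sets each
#' activity to the count-weighted mean responsibility. The likelihood is the
#' categorical form (the multinomial coefficient is constant in the
#' activities and dropped), which is concave in the activities for fixed
#' emissions, so the uniform start suffices.
#'
#' @param counts length-96 numeric vector of channel counts (sum >= 1).
#' @param catalog a [signature_catalog()].
#' @param init optional initial activity vector (defaults to uniform).
#' @param tol convergence tolerance on the log-likelihood increase.
#' @param max_iter iteration cap.
#' @return List of class `em_fit`: `activity` (named, sums to 1),
#'   `log_likelihood`, `n_iterations`, `converged`, and `trace` (the
#'   per-iteration log-likelihood, non-decreasing).
#' @export
em_fit <- function(counts, catalog, init = NULL, tol = 1e-6,
                   max_iter = 1000) {
  stopifnot(inherits(catalog, "signature_catalog"))
  counts <- as.numeric(counts)
  stopifnot(length(counts) == 96, sum(counts) >= 1, all(counts >= 0))
  S <- nrow(catalog)
  pos <- which(counts > 0)
  mu <- unclass(catalog)[, pos, drop = FALSE] # S x K'
  cc <- counts[pos]
  if (any(colSums(mu) == 0))
    stop("observed channel has zero probability under every signature")
  N <- sum(cc)
  pi_ <- if (is.null(init)) rep(1 / S, S) else {
    stopifnot(length(init) == S)
    init / sum(init)
  }
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    mix <- as.vector(crossprod(mu, pi_)) # K'
    ll <- sum(cc * log(mix))
    trace[it] <- ll
    if (is.finite(ll_old) && ll - ll_old < tol) {
      converged <- TRUE
      break
    }
    if (it >= max_iter) break
    ll_old <- ll
    # E+M collapsed: pi_s <- pi_s * sum_k c_k mu_sk / mix_k / N
    pi_ <- pi_ * as.vector(mu %*% (cc / mix)) / N
    pi_ <- pi_ / sum(pi_)
  }
  if (any(diff(trace) < -1e-8))
    stop("EM log-likelihood decreased; this indicates a numerical fault")
  names(pi_) <- rownames(catalog)
  structure(list(activity = pi_, log_likelihood = trace[it],
                 n_iterations = it, converged = converged, trace = trace),
            class = "em_fit")
}

#' Mixture log-likelihood of channel counts
#'
#' `sum_k counts_k log(sum_s pi_s mu_sk)` — the categorical log-likelihood
#' of the counts under the given activities; additive over disjoint count
#' vectors. A channel with positive count but zero mixture probability
#' yields -Inf with a warning.
#'
#' @param counts length-96 count vector.
#' @param catalog a [signature_catalog()].
#' @param activity activity vector over the catalog's signatures.
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(counts, catalog, activity) {
  stopifnot(inherits(catalog, "signature_catalog"),
            length(activity) == nrow(catalog))
  counts <- as.numeric(counts)
  mix <- as.vector(crossprod(unclass(catalog), activity / sum(activity)))
  pos <- counts > 0
  if (any(mix[pos] == 0)) {
    warning("channel with positive count has zero mixture probability")
    return(-Inf)
  }
  sum(counts[pos] * log(mix[pos]))
}

#' Cosine distance between two activity vectors
#'
#' The magnitude of a changepoint is the cosine distance,
#' `1 - <l, r> / (|l| |r|)`, between the activity vectors fitted on either
#' side; it lies in `[0, 1]` for non-negative activities.
#'
#' @param left,right activity vectors of equal length, not all-zero.
#' @return Scalar cosine distance.
#' @export
changepoint_magnitude <- function(left, right) {
  if (length(left) != length(right))
    stop("activity vectors have different lengths")
  nl <- sqrt(sum(left^2)); nr <- sqrt(sum(right^2))
  if (nl == 0 || nr == 0) stop("all-zero activity vector")
  1 - sum(left * right) / (nl * nr)
}

#' Select the active signatures for a sample
#'
#' Fits the full catalog on the pooled channel counts of the whole sample
#' and keeps signatures whose fitted activity reaches `threshold` (default
#' 5%), mirroring per-tissue active-signature selection. Alternatively an
#' explicit signature list (e.g. a published per-tissue set) bypasses the
#' fit.
#'
#' @param counts_total pooled length-96 count vector for the sample.
#' @param catalog the full [signature_catalog()].
#' @param threshold minimum activity to call a signature active.
#' @param signatures optional character vector of signature names (lookup
#'   mode); when given, `counts_total` is ignored.
#' @return The sub-catalog of active signatures.
#' @export
select_active_signatures <- function(counts_total, catalog, threshold = 0.05,
                                     signatures = NULL) {
  stopifnot(inherits(catalog, "signature_catalog"))
  if (!is.null(signatures)) {
    miss <- setdiff(signatures, rownames(catalog))
    if (length(miss) > 0)
      stop("unknown signature(s): ", paste(miss, collapse = ", "))
    return(signature_catalog(unclass(catalog)[signatures, , drop = FALSE]))
  }
  fit <- em_fit(counts_total, catalog)
  keep <- fit$activity >= threshold
  if (!any(keep))
    stop("no signature reaches an activity of ", threshold,
         "; lower the threshold")
  signature_catalog(unclass(catalog)[keep, , drop = FALSE])
}
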