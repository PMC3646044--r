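#' Binomial qualification of presence and absence
#'
#' At a sequencing depth of `n` reads, a taxon at true proportion `p` is
#' detected (at least one read) with probability `1 - (1 - p)^n`. Presence
#' calls for low-abundance taxa are therefore qualified probabilistically: a
#' taxon counts as present only if, upon resampling to the same depth, it
#' would be redetected with high confidence.
#'
#' @param p Detection probability per read (the taxon's abundance), in
#'   \[0, 1\]. Vectorized.
#' @param n Read depth (number of trials), a non-negative integer.
#' @return `prob_no_detection()`: the probability `(1 - p)^n` of seeing zero
#'   reads of the taxon.
#' @examples
#' prob_no_detection(0.001, 1000) # ~ 0.368: too rare to call present
#' @export
prob_no_detection <- function(p, n) {
  check_prob(p)
  check_depth(n, min = 0)
  (1 - p)^n
}

#' @rdname prob_no_detection
#' @param k Number of reads observed for the taxon, `0 <= k <= n`.
#' @return `binomial_pmf()`: the binomial probability mass
#'   `C(n, k) p^k (1 - p)^(n - k)`.
#' @export
binomial_pmf <- function(k, n, p) {
  check_prob(p)
  check_depth(n, min = 0)
  if (any(k < 0 | k > n | k != round(k))) {
    abort("k must be an integer in [0, n]", class = "ubicore_domain_error")
  }
  dbinom(k, size = n, prob = p)
}

#' @rdname prob_no_detection
#' @param miss_threshold Largest acceptable probability of missing the taxon
#'   on resampling (default 0.05, i.e. redetection in at least 95% of
#'   resampled profiles).
#' @return `qualify_presence()`: logical; `TRUE` when
#'   `prob_no_detection(p, n) <= miss_threshold`.
#' @export
qualify_presence <- function(p, n, miss_threshold = 0.05) {
  check_prob(miss_threshold)
  prob_no_detection(p, n) <= miss_threshold
}

check_prob <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("probabilities must lie in [0, 1]", class = "ubicore_domain_error")
  }
  invisible(p)
}

check_depth <- function(n, min = 1) {
  if (any(is.na(n)) || any(n < min | n != round(n))) {
    abort(sprintf("n must be an integer >= %d", min),
          class = "ubicore_domain_error")
  }
  invisible(n)
}
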