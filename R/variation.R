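#' Theoretical variance of a sample proportion
#'
#' Under simple random sampling (no amplification bias) the variance of an
#' observed proportion `p` estimated from `n` reads is `p * (1 - p) / (n - 1)`.
#' It peaks at `p = 0.5` and shrinks with depth, independent of any biological
#' variation — which is why observed taxon variance is visualized rather than
#' corrected by this expectation.
#'
#' @param p Proportion in \[0, 1\]. Vectorized.
#' @param n Number of reads per sample, `n >= 2`.
#' @return The sampling variance `p (1 - p) / (n - 1)`.
#' @export
proportion_variance <- function(p, n) {
  check_prob(p)
  check_depth(n, min = 2)
  p * (1 - p) / (n - 1)
}

#' Variance-abundance (Var-Ab) summary per taxon
#'
#' For each taxon, summarises the spread of its log10 abundance across the
#' donors that carry it. Donors with abundance below `floor` are treated as
#' "non-response" and excluded (rather than substituting a pseudo-value for
#' log10(0)); the floor defaults to 1e-4, the lower bound for presence given
#' typical read depths. Stable, abundant taxa — the core — land in the
#' high-mean / low-sd corner of the resulting scatter.
#'
#' @inheritParams ubiquity
#' @param floor Minimum abundance counted as a response (default 1e-4).
#' @return A tibble with one row per taxon responding in at least one donor:
#'   `taxon`, `mean_log_abundance`, `sd_log_abundance` (sample sd, `n - 1`
#'   denominator; `NA` when only one donor responds), `ubiquity` (responding
#'   fraction) and `n_responding`.
#' @export
varab_table <- function(profile, floor = 1e-4) {
  if (floor <= 0) {
    abort("floor must be > 0", class = "ubicore_domain_error")
  }
  profile <- validate_profile(profile)
  n_donors <- length(unique(profile$donor))
  profile |>
    filter(.data$abundance >= floor) |>
    group_by(.data$taxon) |>
    summarise(
      mean_log_abundance = mean(log10(.data$abundance)),
      sd_log_abundance = if (n() >= 2) sd(log10(.data$abundance)) else NA_real_,
      n_responding = n(),
      .groups = "drop"
    ) |>
    mutate(ubiquity = .data$n_responding / n_donors) |>
    select("taxon", "mean_log_abundance", "sd_log_abundance", "ubiquity",
           "n_responding") |>
    arrange(.data$taxon)
}
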