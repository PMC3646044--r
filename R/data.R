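#' First-versus-second-visit AWKS comparisons (genera-based profiles)
#'
#' The published per-habitat comparison of a healthy cohort's first and
#' second visits: the AWKS statistic, its one-tailed bootstrap p-value
#' (censored entries printed as `"<0.001"`), and the number of donors, for
#' all 18 body habitats. Shipped as a worked input for [bh_adjust()]: at a
#' false discovery rate of 0.05 over the 18 genera-based tests, 10 habitats
#' reject the no-change null.
#'
#' @return A tibble with columns `body_region`, `body_habitat`, `awks`,
#'   `p_value` (character, possibly censored), `n_donors`.
#' @examples
#' visits <- visit_awks_genera()
#' bh_adjust(visits$p_value, alpha = 0.05)
#' @export
visit_awks_genera <- function() {
  readr::read_tsv(
    system.file("extdata", "visit_awks_genera.tsv", package = "ubicore"),
    col_types = readr::cols(
      body_region = readr::col_character(),
      body_habitat = readr::col_character(),
      awks = readr::col_double(),
      p_value = readr::col_character(),
      n_donors = readr::col_integer()
    )
  )
}
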