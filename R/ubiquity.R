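#' Ubiquity at an abundance cutoff
#'
#' The ubiquity of a taxon at abundance cutoff `a` is the fraction of the
#' cohort's donors whose abundance of that taxon *strictly exceeds* `a`. As a
#' function of `a` it is the survival function of the per-donor abundance
#' distribution: monotone non-increasing, 1 near zero for taxa present in all
#' donors, and 0 at the largest observed abundance.
#'
#' @param profile A cohort profile (see [normalize_profile()]).
#' @param abundance Abundance cutoff `a >= 0`.
#' @param taxa Character vector of taxa to evaluate; default all taxa in the
#'   profile. Unknown taxa are an error.
#' @return A tibble with columns `taxon`, `abundance`, `ubiquity`.
#' @examples
#' prof <- normalize_profile(tibble::tibble(
#'   donor = rep(c("d1", "d2"), each = 2),
#'   taxon = rep(c("A", "B"), 2),
#'   count = c(3, 1, 1, 3)
#' ))
#' ubiquity(prof, abundance = 0.5)
#' @export
ubiquity <- function(profile, abundance = 0, taxa = NULL) {
  profile <- validate_profile(profile)
  if (abundance < 0) {
    abort("abundance cutoff must be >= 0", class = "ubicore_domain_error")
  }
  m <- abundance_matrix(profile)
  taxa <- resolve_taxa(taxa, colnames(m))
  ub <- colMeans(m[, taxa, drop = FALSE] > abundance)
  tibble(taxon = taxa, abundance = abundance, ubiquity = unname(ub))
}

resolve_taxa <- function(taxa, known) {
  if (is.null(taxa)) return(known)
  missing <- setdiff(taxa, known)
  if (length(missing) > 0) {
    abort(paste0("unknown taxa: ", paste(head(missing, 5), collapse = ", ")),
          class = "ubicore_key_error")
  }
  taxa
}

#' Ubiquity-abundance (Ub-Ab) step curves
#'
#' Exact step-function representation of each taxon's ubiquity as a function
#' of the abundance cutoff: one row per distinct observed abundance
#' (breakpoint), carrying the ubiquity evaluated *at* that breakpoint (strict
#' `>`). Between breakpoints the curve is right-continuous: the value at any
#' cutoff `a` is the value at the largest breakpoint `<= a`, and 1 below the
#' smallest breakpoint.
#'
#' @inheritParams ubiquity
#' @return A tibble with columns `taxon`, `abundance` (breakpoint),
#'   `ubiquity`, sorted by taxon and abundance.
#' @seealso [ubiquity_at()] to evaluate the step curves at arbitrary cutoffs.
#' @export
ubiquity_curve <- function(profile, taxa = NULL) {
  profile <- validate_profile(profile)
  m <- abundance_matrix(profile)
  taxa <- resolve_taxa(taxa, colnames(m))
  purrr::map_dfr(taxa, function(t) {
    v <- m[, t]
    bp <- sort(unique(v))
    tibble(taxon = t, abundance = bp,
           ubiquity = vapply(bp, function(a) mean(v > a), numeric(1)))
  })
}

#' Evaluate Ub-Ab step curves at abundance cutoffs
#'
#' @param curve A curve tibble from [ubiquity_curve()].
#' @param abundance Numeric vector of cutoffs at which to evaluate.
#' @return A tibble with columns `taxon`, `abundance`, `ubiquity` (one row
#'   per taxon and cutoff).
#' @export
ubiquity_at <- function(curve, abundance) {
  curve <- as_tibble(curve)
  purrr::map_dfr(split(curve, curve$taxon), function(cv) {
    cv <- arrange(cv, .data$abundance)
    idx <- findInterval(abundance, cv$abundance)
    tibble(taxon = cv$taxon[[1]], abundance = abundance,
           ubiquity = ifelse(idx == 0, 1, cv$ubiquity[pmax(idx, 1)]))
  })
}
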