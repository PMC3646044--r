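#' Specify a synthetic cohort with planted structure
#'
#' Describes a cohort whose taxa fall into three planted classes mirroring
#' the structure the core-election analyses assume:
#'
#' * *major core*: high base abundance, present in (essentially) every donor;
#' * *minor core*: base abundance in the 1e-4 to 1e-2 band, present in a
#'   majority of donors but never abundant;
#' * *sporadic*: power-law base abundances (rank r proportional to
#'   `r^-gamma`), each present in a donor with probability
#'   `sporadic_presence`.
#'
#' Per donor, class presences are Bernoulli draws, base abundances receive a
#' lognormal multiplicative perturbation (`sigma` on the log10 scale), the
#' composition is renormalized to closure, and reads are drawn as a single
#' multinomial of the donor's depth — simple random sampling, with no
#' amplification-bias model.
#'
#' Default base abundances: majors 0.25/0.15/0.10/0.06/0.04 (presence 1),
#' minors log-spaced from 2e-3 down to 2e-4 (presence 0.8), and the sporadic
#' mass is whatever remains (about 0.38), spread over ranks by the power law.
#'
#' @param n_donors Number of donors (default 100).
#' @param depth Reads per donor: a single value or a `c(min, max)` range
#'   sampled uniformly per donor (default 5000).
#' @param n_major,major_base,major_presence Major-core class: count, base
#'   abundances (recycled/truncated to `n_major`), presence probability.
#' @param n_minor,minor_range,minor_presence Minor-core class: count, base
#'   abundance range (log-spaced within it), presence probability.
#' @param n_sporadic,sporadic_presence,gamma Sporadic class: count, per-donor
#'   presence probability, power-law exponent.
#' @param sigma Standard deviation of the per-donor lognormal noise on log10
#'   abundances (default 0.1).
#' @return A `cohort_spec` list with the per-taxon `taxon`, `base` and
#'   `presence` vectors plus the scalar parameters.
#' @export
cohort_spec <- function(n_donors = 100, depth = 5000,
                        n_major = 5,
                        major_base = c(0.25, 0.15, 0.10, 0.06, 0.04),
                        major_presence = 1.0,
                        n_minor = 10, minor_range = c(2e-4, 2e-3),
                        minor_presence = 0.8,
                        n_sporadic = 50, sporadic_presence = 0.3,
                        gamma = 1.5, sigma = 0.1) {
  if (n_donors < 1) abort("n_donors must be >= 1", class = "ubicore_domain_error")
  if (n_major + n_minor + n_sporadic < 1) {
    abort("the spec must plant at least one taxon", class = "ubicore_domain_error")
  }
  check_prob(c(major_presence, minor_presence, sporadic_presence))
  if (length(depth) > 2 || any(depth < 1) || any(depth != round(depth))) {
    abort("depth must be a positive integer or a c(min, max) range",
          class = "ubicore_domain_error")
  }
  major <- if (n_major > 0) rep_len(major_base, n_major) else numeric(0)
  minor <- if (n_minor > 0) {
    10^seq(log10(max(minor_range)), log10(min(minor_range)),
           length.out = n_minor)
  } else {
    numeric(0)
  }
  sporadic_mass <- 1 - sum(major) - sum(minor)
  if (n_sporadic > 0 && sporadic_mass <= 0) {
    abort("major and minor base abundances leave no mass for sporadic taxa",
          class = "ubicore_domain_error")
  }
  sporadic <- if (n_sporadic > 0) {
    raw <- seq_len(n_sporadic)^(-gamma)
    sporadic_mass * raw / sum(raw)
  } else {
    numeric(0)
  }
  pad <- function(stub, n) sprintf("%s_%03d", stub, seq_len(n))
  spec <- list(
    taxon = c(pad("major_core", n_major), pad("minor_core", n_minor),
              pad("sporadic", n_sporadic)),
    base = c(major, minor, sporadic),
    presence = c(rep(major_presence, n_major), rep(minor_presence, n_minor),
                 rep(sporadic_presence, n_sporadic)),
    class = c(rep("major_core", n_major), rep("minor_core", n_minor),
              rep("sporadic", n_sporadic)),
    n_donors = n_donors, depth = depth, sigma = sigma, gamma = gamma
  )
  structure(spec, class = "cohort_spec")
}

#' Planted taxa of a class
#'
#' @param spec A `cohort_spec`.
#' @param class One of `"major_core"`, `"minor_core"`, `"sporadic"`.
#' @return Character vector of planted taxon labels.
#' @export
planted_taxa <- function(spec, class = c("major_core", "minor_core", "sporadic")) {
  class <- match.arg(class)
  spec$taxon[spec$class == class]
}

#' Generate a synthetic cohort
#'
#' Draws one count table from a [cohort_spec()]: per donor, Bernoulli class
#' presences, lognormal perturbation of the base log10 abundances,
#' renormalization to closure, and a multinomial read draw at the donor's
#' depth. Deterministic under `seed`.
#'
#' A warning is raised when minor-core taxa are planted but the depth cannot
#' resolve the 1e-4 detection floor (roughly depth >= 10 / floor is needed
#' for their presence to be observable).
#'
#' @param spec A `cohort_spec`.
#' @param seed Optional integer seed.
#' @return A count table tibble (complete donor-by-taxon grid).
#' @export
generate_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) set.seed(seed)
  min_depth <- min(spec$depth)
  if (any(spec$class == "minor_core") && min_depth < 10 / 1e-4) {
    warn(paste0("depth ", min_depth, " cannot reliably resolve minor-core ",
                "taxa at the 1e-4 detection floor (need >= 1e5 reads)"))
  }
  n_taxa <- length(spec$taxon)
  depths <- if (length(spec$depth) == 2) {
    sample(seq(spec$depth[[1]], spec$depth[[2]]), spec$n_donors, replace = TRUE)
  } else {
    rep(spec$depth, spec$n_donors)
  }
  m <- matrix(0, nrow = spec$n_donors, ncol = n_taxa,
              dimnames = list(sprintf("donor_%03d", seq_len(spec$n_donors)),
                              spec$taxon))
  for (i in seq_len(spec$n_donors)) {
    repeat {
      present <- runif(n_taxa) < spec$presence
      if (any(present)) break
    }
    a <- spec$base * 10^rnorm(n_taxa, 0, spec$sigma) * present
    m[i, ] <- as.numeric(rmultinom(1, size = depths[[i]], prob = a / sum(a)))
  }
  long_counts(m)
}

#' Generate a pair of cohorts with a planted effect
#'
#' Cohort X is drawn from `spec`; cohort Y from a copy of `spec` whose named
#' taxa have their base abundances multiplied by the given fold-changes
#' before renormalization. With an identity effect (all folds 1, or empty)
#' the two cohorts are exchangeable draws, which is the basis of type-I
#' studies of [awks_test()]. The two draws use independent seeds derived from
#' the master `seed`.
#'
#' @param spec A `cohort_spec`.
#' @param effect Named numeric vector of fold-changes, e.g.
#'   `c(major_core_001 = 10)`. Names must be planted taxa.
#' @param seed Optional master seed.
#' @return A list with count tables `x` and `y`.
#' @export
generate_pair <- function(spec, effect = numeric(0), seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (length(effect) > 0) {
    unknown <- setdiff(names(effect), spec$taxon)
    if (length(unknown) > 0) {
      abort(paste0("effect names are not planted taxa: ",
                   paste(unknown, collapse = ", ")),
            class = "ubicore_key_error")
    }
  }
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, 2)
  spec_y <- spec
  if (length(effect) > 0) {
    j <- match(names(effect), spec_y$taxon)
    spec_y$base[j] <- spec_y$base[j] * effect
  }
  list(x = generate_cohort(spec, seed = seeds[[1]]),
       y = generate_cohort(spec_y, seed = seeds[[2]]))
}
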