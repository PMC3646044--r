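#' Elect core taxa with the two-parameter model
#'
#' A taxon is a core member of the cohort when its ubiquity evaluated at the
#' abundance cutoff strictly exceeds the ubiquity cutoff — i.e. strictly more
#' than `ubiquity_cutoff` of the donors carry the taxon at an abundance
#' strictly above `abundance_cutoff`. Both comparisons are strict, so ties
#' exclude: a taxon at exactly 75% ubiquity is not core at a 75% cutoff.
#'
#' The conventional cutoff pairs explored in practice are
#' (abundance | ubiquity) = 10%|75%, 1%|80%, 0.1%|85% and 0.01%|90%.
#'
#' @inheritParams ubiquity
#' @param abundance_cutoff Abundance cutoff, strictly in (0, 1).
#' @param ubiquity_cutoff Ubiquity cutoff, in (0, 1].
#' @return A tibble of elected taxa with columns `taxon`, `ubiquity` (at the
#'   abundance cutoff), sorted by decreasing ubiquity.
#' @export
elect_core <- function(profile, abundance_cutoff, ubiquity_cutoff) {
  check_cutoff(abundance_cutoff, ubiquity_cutoff)
  ubiquity(profile, abundance = abundance_cutoff) |>
    filter(.data$ubiquity > ubiquity_cutoff) |>
    arrange(desc(.data$ubiquity), .data$taxon) |>
    select("taxon", "ubiquity")
}

check_cutoff <- function(a, u) {
  if (!is.numeric(a) || length(a) != 1 || a <= 0 || a >= 1) {
    abort("abundance_cutoff must lie strictly in (0, 1)",
          class = "ubicore_domain_error")
  }
  if (!is.numeric(u) || length(u) != 1 || u <= 0 || u > 1) {
    abort("ubiquity_cutoff must lie in (0, 1]",
          class = "ubicore_domain_error")
  }
  invisible(NULL)
}

#' Elect minor-core taxa
#'
#' The minor core inverts the abundance restriction of the two-parameter
#' model: taxa carried by a *majority* of the cohort (presence at or above a
#' detection floor in strictly more than `ubiquity_floor` of donors) that
#' never rise above a low abundance ceiling in any donor. On a Ub-Ab plot
#' these are the curves that originate high on the ubiquity axis at the
#' detection floor yet terminate below the ceiling.
#'
#' Presence at the floor uses `>= detection_floor` (the curve *originates* at
#' the floor), while the ceiling uses strict `> abundance_ceiling`;
#' `ceiling_tolerance` is the fraction of donors allowed above the ceiling
#' (default 0: none).
#'
#' @inheritParams ubiquity
#' @param detection_floor Minimum abundance counted as presence (default
#'   1e-4, one part in ten thousand).
#' @param ubiquity_floor Majority threshold on presence (default 0.5).
#' @param abundance_ceiling Low-abundance ceiling (default 0.01).
#' @param ceiling_tolerance Allowed fraction of donors above the ceiling
#'   (default 0).
#' @return A tibble with columns `taxon`, `max_ubiquity` (presence fraction
#'   at the detection floor) and `max_abundance` (largest observed abundance),
#'   sorted by decreasing `max_ubiquity`.
#' @export
elect_minor_core <- function(profile, detection_floor = 1e-4,
                             ubiquity_floor = 0.5, abundance_ceiling = 0.01,
                             ceiling_tolerance = 0) {
  if (detection_floor <= 0 || detection_floor >= abundance_ceiling) {
    abort("detection_floor must satisfy 0 < floor < abundance_ceiling",
          class = "ubicore_domain_error")
  }
  m <- abundance_matrix(validate_profile(profile))
  present <- colMeans(m >= detection_floor)
  over <- colMeans(m > abundance_ceiling)
  keep <- present > ubiquity_floor & over <= ceiling_tolerance
  tibble(taxon = colnames(m)[keep],
         max_ubiquity = unname(present[keep]),
         max_abundance = unname(apply(m[, keep, drop = FALSE], 2, max))) |>
    arrange(desc(.data$max_ubiquity), .data$taxon)
}

#' Body-region ubiquity across habitats
#'
#' Combines per-habitat ubiquities of a taxon at a common abundance cutoff
#' into a region-level value, answering one of two questions. `mode = "mean"`
#' (arithmetic mean over habitats): how likely is a habitat drawn from this
#' region to carry the taxon above the cutoff? `mode = "and"` (product over
#' habitats): how likely is the taxon to be carried above the cutoff in
#' *every* habitat of the region — the stricter reading of a region core,
#' which can only shrink as habitats are added. A taxon absent from a habitat
#' contributes ubiquity 0 (and so annihilates the product).
#'
#' @param profiles A list of cohort profiles (one per habitat), or a single
#'   profile tibble with an extra `habitat` column.
#' @param abundance Abundance cutoff at which ubiquities are evaluated.
#' @param mode `"mean"` or `"and"`.
#' @param taxa Taxa to report; default the union over habitats.
#' @return A tibble with columns `taxon`, `ubiquity`, sorted by decreasing
#'   ubiquity.
#' @export
region_ubiquity <- function(profiles, abundance = 1e-4,
                            mode = c("mean", "and"), taxa = NULL) {
  mode <- match.arg(mode)
  if (is.data.frame(profiles)) {
    if (!"habitat" %in% names(profiles)) {
      abort("a single data frame needs a `habitat` column; otherwise pass a list of profiles",
            class = "ubicore_domain_error")
    }
    profiles <- split(select(profiles, -"habitat"), profiles$habitat)
  }
  if (length(profiles) == 0) {
    abort("at least one habitat profile is required",
          class = "ubicore_domain_error")
  }
  per <- purrr::map(profiles, function(p) {
    u <- ubiquity(p, abundance = abundance)
    setNames(u$ubiquity, u$taxon)
  })
  if (is.null(taxa)) taxa <- unique(unlist(lapply(per, names)))
  vals <- vapply(per, function(u) {
    out <- u[taxa]
    out[is.na(out)] <- 0 # absent from this habitat
    out
  }, numeric(length(taxa)))
  vals <- matrix(vals, nrow = length(taxa)) # robust when one taxon/habitat
  combined <- if (mode == "mean") rowMeans(vals) else apply(vals, 1, prod)
  tibble(taxon = taxa, ubiquity = combined) |>
    arrange(desc(.data$ubiquity), .data$taxon)
}

#' Bootstrap confidence intervals on core counts
#'
#' The observed core count at each cutoff pair is computed directly on the
#' unperturbed table. Uncertainty is estimated by resampling with replacement
#' from both the donors and each donor's read counts: per replicate, donors
#' are drawn with replacement, each drawn donor's reads are redrawn as a
#' multinomial of the donor's depth over its observed proportions, and the
#' core is re-elected. Median and confidence bounds are nearest-rank
#' percentiles of the replicate counts (no interpolation).
#'
#' @param counts A count table.
#' @param cutoffs A data frame with columns `abundance` and `ubiquity`, one
#'   row per cutoff pair. Default: the four conventional pairs 10%|75%,
#'   1%|80%, 0.1%|85%, 0.01%|90%.
#' @param B Number of bootstrap iterations (default 160).
#' @param ci Confidence level (default 0.95).
#' @param seed Optional integer seed for reproducibility.
#' @return A `core_report` tibble with columns `abundance_cutoff`,
#'   `ubiquity_cutoff`, `observed`, `boot_median`, `lb`, `ub`; attributes
#'   carry `B`, `ci`, `seed` and the replicate draws.
#' @export
bootstrap_core_counts <- function(counts,
                                  cutoffs = conventional_cutoffs(),
                                  B = 160, ci = 0.95, seed = NULL) {
  if (!is.numeric(B) || B < 2) {
    abort("B must be >= 2", class = "ubicore_domain_error")
  }
  cutoffs <- as_tibble(cutoffs)
  if (!all(c("abundance", "ubiquity") %in% names(cutoffs)) || nrow(cutoffs) == 0) {
    abort("cutoffs needs columns `abundance` and `ubiquity`",
          class = "ubicore_domain_error")
  }
  purrr::walk2(cutoffs$abundance, cutoffs$ubiquity, check_cutoff)
  counts <- validate_count_table(counts)
  m <- counts_matrix(counts)
  depth <- rowSums(m)
  if (any(depth < 1)) stop_validation("zero-depth donor in count table")
  if (!is.null(seed)) set.seed(seed)

  core_sizes <- function(a_mat) {
    vapply(seq_len(nrow(cutoffs)), function(k) {
      sum(colMeans(a_mat > cutoffs$abundance[[k]]) > cutoffs$ubiquity[[k]])
    }, numeric(1))
  }
  observed <- core_sizes(m / depth)
  prob <- m / depth
  nd <- nrow(m)
  draws <- matrix(NA_real_, nrow = B, ncol = nrow(cutoffs))
  for (b in seq_len(B)) {
    idx <- sample.int(nd, nd, replace = TRUE)
    rm <- resample_reads(prob, depth, idx)
    draws[b, ] <- core_sizes(rm / rowSums(rm))
  }
  qs <- apply(draws, 2, nearest_rank, probs = c(0.5, (1 - ci) / 2, 1 - (1 - ci) / 2))
  out <- cutoffs |>
    transmute(abundance_cutoff = .data$abundance,
              ubiquity_cutoff = .data$ubiquity) |>
    mutate(observed = observed, boot_median = qs[1, ], lb = qs[2, ], ub = qs[3, ])
  structure(out, B = B, ci = ci, seed = seed, draws = draws,
            n_donors = nd,
            class = c("core_report", class(out)))
}

#' The four conventional cutoff pairs
#'
#' @return A tibble of (abundance, ubiquity) pairs: 10%|75%, 1%|80%,
#'   0.1%|85%, 0.01%|90%.
#' @export
conventional_cutoffs <- function() {
  tibble(abundance = c(0.1, 0.01, 0.001, 0.0001),
         ubiquity = c(0.75, 0.80, 0.85, 0.90))
}

# Redraw each selected donor's reads as a multinomial over its observed
# proportions; rows of the result are the resampled donors.
resample_reads <- function(prob, depth, idx) {
  out <- vapply(idx, function(i) {
    as.numeric(rmultinom(1, size = depth[[i]], prob = prob[i, ]))
  }, numeric(ncol(prob)))
  # vapply collapses the taxa dimension when there is a single taxon
  if (is.null(dim(out))) out <- matrix(out, nrow = 1)
  t(out)
}

# Nearest-rank percentile: the value at position ceiling(q * B) of the sorted
# draws (B is small, so interpolation is avoided).
nearest_rank <- function(x, probs) {
  s <- sort(x)
  s[pmax(1L, ceiling(probs * length(s)))]
}

#' @export
print.core_report <- function(x, ...) {
  cat(sprintf("Core count bootstrap: %d cutoff pair(s), B = %d, %.0f%% CI\n",
              nrow(x), attr(x, "B"), 100 * attr(x, "ci")))
  NextMethod()
}

#' Tidy a core bootstrap report
#'
#' @param x A `core_report` from [bootstrap_core_counts()].
#' @param ... Unused.
#' @return The per-cutoff tibble (observed, median, bounds).
#' @export
tidy.core_report <- function(x, ...) {
  as_tibble(as.data.frame(x))
}

#' @rdname tidy.core_report
#' @export
glance.core_report <- function(x, ...) {
  tibble(B = attr(x, "B"), ci = attr(x, "ci"),
         n_donors = attr(x, "n_donors"),
         seed = attr(x, "seed") %||% NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")
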