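#' Per-taxon Kolmogorov-Smirnov distance between two cohorts
#'
#' For one taxon, the KS distance between cohorts X and Y is the maximum
#' absolute difference between their ubiquities at matching abundance
#' cutoffs. Since both ubiquity curves are step functions, the supremum is
#' attained on the finite set {0} union all observed abundances of the taxon
#' in either cohort, and is computed exactly on that set. A taxon absent from
#' one cohort contributes all-zero abundances there.
#'
#' @param x,y Cohort profiles (see [normalize_profile()]).
#' @param taxa Taxa to compare; default the union of both cohorts' taxa.
#'   A taxon found in neither cohort is an error.
#' @return A tibble with one row per taxon: `taxon`, `ks`, `at_abundance`
#'   (smallest cutoff attaining the maximum), `ubiquity_x`, `ubiquity_y`
#'   (the ubiquities at that cutoff), sorted by decreasing `ks`.
#' @export
ks_taxon <- function(x, y, taxa = NULL) {
  x <- validate_profile(x)
  y <- validate_profile(y)
  union_taxa <- union(unique(x$taxon), unique(y$taxon))
  if (is.null(taxa)) {
    taxa <- union_taxa
  } else {
    resolve_taxa(taxa, union_taxa)
  }
  mx <- abundance_matrix(x, taxa = union_taxa)
  my <- abundance_matrix(y, taxa = union_taxa)
  purrr::map_dfr(taxa, function(t) {
    r <- ks_survival(mx[, t], my[, t], argmax = TRUE)
    tibble(taxon = t, ks = r$ks, at_abundance = r$at,
           ubiquity_x = r$sx, ubiquity_y = r$sy)
  }) |>
    arrange(desc(.data$ks), .data$taxon)
}

# Exact sup |S_x - S_y| of two empirical survival functions (strict >),
# evaluated over {0} and all data values. With argmax = TRUE also returns the
# smallest evaluation point attaining the maximum and the two survival values
# there.
ks_survival <- function(xv, yv, argmax = FALSE) {
  nx <- length(xv)
  ny <- length(yv)
  g <- c(0, xv, yv)
  if (argmax) g <- sort(unique(g))
  sx <- (nx - findInterval(g, sort(xv))) / nx
  sy <- (ny - findInterval(g, sort(yv))) / ny
  d <- abs(sx - sy)
  if (!argmax) return(list(ks = max(d)))
  i <- which.max(d)
  list(ks = d[[i]], at = g[[i]], sx = sx[[i]], sy = sy[[i]])
}

#' Abundance-weighted Kolmogorov-Smirnov (AWKS) statistic
#'
#' The AWKS statistic between cohorts X and Y is the abundance-weighted
#' average, over the union of their taxa, of the per-taxon KS distances
#' between the two ubiquity curves. Each taxon's weight is the mean of its
#' two cohort-average abundances, `(mean_X + mean_Y) / 2`; by compositional
#' closure the weights sum to 1, so AWKS lies in \[0, 1\] and is 0 exactly
#' when every taxon's curves coincide.
#'
#' @inheritParams ks_taxon
#' @return `awks()`: the statistic as a single number.
#' @export
awks <- function(x, y) {
  sum_w_ks <- awks_components(x, y)
  sum(sum_w_ks$weight * sum_w_ks$ks)
}

#' @rdname awks
#' @return `awks_components()`: a tibble with `taxon`, `ks`, `weight` over
#'   the union taxa set, sorted by decreasing weighted contribution.
#' @export
awks_components <- function(x, y) {
  x <- validate_profile(x)
  y <- validate_profile(y)
  if (nrow(x) == 0 || nrow(y) == 0) {
    abort("both cohorts must be non-empty", class = "ubicore_domain_error")
  }
  union_taxa <- union(unique(x$taxon), unique(y$taxon))
  mx <- abundance_matrix(x, taxa = union_taxa)
  my <- abundance_matrix(y, taxa = union_taxa)
  w <- (colMeans(mx) + colMeans(my)) / 2
  ks <- vapply(seq_along(union_taxa),
               function(j) ks_survival(mx[, j], my[, j])$ks, numeric(1))
  tibble(taxon = union_taxa, ks = ks, weight = unname(w)) |>
    arrange(desc(.data$weight * .data$ks), .data$taxon)
}

# AWKS on aligned abundance matrices (internal fast path for the bootstrap).
awks_matrix <- function(ax, ay) {
  w <- (colMeans(ax) + colMeans(ay)) / 2
  ks <- vapply(seq_len(ncol(ax)),
               function(j) ks_survival(ax[, j], ay[, j])$ks, numeric(1))
  sum(w * ks)
}

#' Bootstrap AWKS test between two cohorts
#'
#' Computes the observed AWKS statistic on the unperturbed profiles and a
#' bootstrap null distribution under the hypothesis that the two cohorts
#' share one taxonomic profile. Per replicate, pseudo-cohorts of the original
#' sizes are drawn with replacement from the pooled donors (`null =
#' "pooled"`, exchangeability under H0) or from the first cohort only
#' (`null = "within_first"`); each drawn donor's reads are redrawn as a
#' multinomial of its depth over its observed proportions, and AWKS is
#' recomputed. The empirical null is used directly — no normal approximation.
#'
#' The one-tailed p-value is the fraction of null draws at or above the
#' observed statistic; when no draw reaches it the p-value is reported as
#' `< 1/B` (with `p_value = 0`). `p_method = "add_one"` uses the
#' `(count + 1) / (B + 1)` convention instead.
#'
#' @param counts_x,counts_y Count tables for the two cohorts.
#' @param B Number of bootstrap replicates (default 1000; at least 100 is
#'   recommended for stable tail estimates).
#' @param seed Optional integer seed.
#' @param null Null construction, `"pooled"` (default) or `"within_first"`.
#' @param p_method `"count"` (default) or `"add_one"`.
#' @return An `awks_test` object: a list with `statistic`, `p_value`,
#'   `p_display`, `null` (the B draws), `components` (per-taxon ks and
#'   weight), `B`, `n_x`, `n_y`, `null_mode`, `seed`.
#' @export
awks_test <- function(counts_x, counts_y, B = 1000, seed = NULL,
                      null = c("pooled", "within_first"),
                      p_method = c("count", "add_one")) {
  null <- match.arg(null)
  p_method <- match.arg(p_method)
  if (!is.numeric(B) || B < 2) {
    abort("B must be >= 2", class = "ubicore_domain_error")
  }
  counts_x <- validate_count_table(counts_x)
  counts_y <- validate_count_table(counts_y)
  if (nrow(counts_x) == 0 || nrow(counts_y) == 0) {
    abort("both cohorts must be non-empty", class = "ubicore_domain_error")
  }
  union_taxa <- union(unique(counts_x$taxon), unique(counts_y$taxon))
  mx <- wide_matrix(counts_x, "count", taxa = union_taxa)
  my <- wide_matrix(counts_y, "count", taxa = union_taxa)
  dx <- rowSums(mx)
  dy <- rowSums(my)
  if (any(dx < 1) || any(dy < 1)) stop_validation("zero-depth donor present")
  ax <- mx / dx
  ay <- my / dy
  observed <- awks_matrix(ax, ay)
  components <- awks_components(
    tibble(donor = rep(rownames(mx), each = ncol(mx)),
           taxon = rep(union_taxa, nrow(mx)), abundance = as.numeric(t(ax))),
    tibble(donor = rep(rownames(my), each = ncol(my)),
           taxon = rep(union_taxa, nrow(my)), abundance = as.numeric(t(ay)))
  )

  pool <- if (null == "pooled") rbind(mx, my) else mx
  dpool <- rowSums(pool)
  ppool <- pool / dpool
  n_x <- nrow(mx)
  n_y <- nrow(my)
  npool <- nrow(pool)
  if (!is.null(seed)) set.seed(seed)
  null_draws <- vapply(seq_len(B), function(b) {
    ix <- sample.int(npool, n_x, replace = TRUE)
    iy <- sample.int(npool, n_y, replace = TRUE)
    rx <- resample_reads(ppool, dpool, ix)
    ry <- resample_reads(ppool, dpool, iy)
    awks_matrix(rx / rowSums(rx), ry / rowSums(ry))
  }, numeric(1))
  exceed <- sum(null_draws >= observed)
  p <- if (p_method == "add_one") (exceed + 1) / (B + 1) else exceed / B
  p_display <- if (p_method == "count" && exceed == 0) {
    paste0("< ", format(1 / B))
  } else {
    format(p)
  }
  structure(
    list(statistic = observed, p_value = p, p_display = p_display,
         null = null_draws, components = components, B = B,
         n_x = n_x, n_y = n_y, null_mode = null, seed = seed,
         p_method = p_method),
    class = "awks_test"
  )
}

#' @export
print.awks_test <- function(x, ...) {
  cat("Abundance-weighted Kolmogorov-Smirnov test\n")
  cat(sprintf("  AWKS = %.4f, one-tailed p = %s (B = %d %s bootstrap replicates)\n",
              x$statistic, x$p_display, x$B, x$null_mode))
  cat(sprintf("  cohort sizes: n_x = %d, n_y = %d donors\n", x$n_x, x$n_y))
  invisible(x)
}

#' Tidy an AWKS test
#'
#' @param x An `awks_test` object.
#' @param ... Unused.
#' @return `tidy()`: the per-taxon `taxon`/`ks`/`weight` tibble;
#'   `glance()`: a one-row summary (statistic, p-value, B, cohort sizes).
#' @export
tidy.awks_test <- function(x, ...) x$components

#' @rdname tidy.awks_test
#' @export
glance.awks_test <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value,
         p_display = x$p_display, B = x$B, n_x = x$n_x, n_y = x$n_y,
         null_mode = x$null_mode, seed = x$seed %||% NA_integer_)
}

#' Ubiquity-ubiquity (U-U) curves
#'
#' For each taxon, pairs the two cohorts' ubiquities evaluated over the
#' merged breakpoint set ({0} union observed abundances in either cohort).
#' Identical cohorts trace the diagonal; the point of greatest vertical
#' departure from the diagonal is the taxon's KS distance.
#'
#' @inheritParams ks_taxon
#' @return A tibble with columns `taxon`, `abundance`, `ubiquity_x`,
#'   `ubiquity_y`, ordered by taxon and abundance.
#' @seealso [ks_taxon()] for the argmax points, [plot_uu()] to draw them.
#' @export
uu_curve <- function(x, y, taxa = NULL) {
  x <- validate_profile(x)
  y <- validate_profile(y)
  union_taxa <- union(unique(x$taxon), unique(y$taxon))
  if (is.null(taxa)) taxa <- union_taxa else resolve_taxa(taxa, union_taxa)
  mx <- abundance_matrix(x, taxa = union_taxa)
  my <- abundance_matrix(y, taxa = union_taxa)
  purrr::map_dfr(taxa, function(t) {
    xv <- mx[, t]
    yv <- my[, t]
    g <- sort(unique(c(0, xv, yv)))
    tibble(taxon = t, abundance = g,
           ubiquity_x = (length(xv) - findInterval(g, sort(xv))) / length(xv),
           ubiquity_y = (length(yv) - findInterval(g, sort(yv))) / length(yv))
  })
}

#' Benjamini-Hochberg step-up decisions
#'
#' Ranks p-values ascending, computes the per-rank thresholds
#' `rank * alpha / m`, and applies the step-up rule: reject every hypothesis
#' with rank at or below the largest rank whose p-value does not exceed its
#' threshold. Decisions are made on unrounded thresholds;
#' `threshold_reported` carries the 3-decimal display convention.
#'
#' Censored inputs such as `"<0.001"` are accepted and resolved to the
#' midpoint of the censoring interval (0.0005) for ranking — any value below
#' the smallest threshold yields identical decisions.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\], or a character
#'   vector that may contain `"<x"` entries.
#' @param alpha Target false discovery rate (default 0.05).
#' @return A tibble in rank order with columns `index` (input position),
#'   `p_value`, `rank`, `threshold`, `threshold_reported`, `reject`.
#' @export
bh_adjust <- function(pvalues, alpha = 0.05) {
  if (length(pvalues) == 0) {
    abort("pvalues must be non-empty", class = "ubicore_domain_error")
  }
  if (is.character(pvalues)) {
    pvalues <- vapply(pvalues, parse_censored_p, numeric(1), USE.NAMES = FALSE)
  }
  check_prob(pvalues)
  check_prob(alpha)
  m <- length(pvalues)
  ord <- order(pvalues)
  p_sorted <- pvalues[ord]
  thr <- seq_len(m) * alpha / m
  below <- which(p_sorted <= thr)
  kmax <- if (length(below) > 0) max(below) else 0L
  tibble(index = ord, p_value = p_sorted, rank = seq_len(m),
         threshold = thr, threshold_reported = round(thr, 3),
         reject = seq_len(m) <= kmax)
}

parse_censored_p <- function(s) {
  s <- trimws(s)
  if (startsWith(s, "<")) {
    bound <- suppressWarnings(as.numeric(sub("^<", "", s)))
    if (is.na(bound)) {
      abort(paste0("cannot parse p-value: ", s), class = "ubicore_parse_error")
    }
    return(bound / 2)
  }
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v)) {
    abort(paste0("cannot parse p-value: ", s), class = "ubicore_parse_error")
  }
  v
}
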