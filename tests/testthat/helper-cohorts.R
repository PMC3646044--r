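# Shared fixtures built in code.

# Four-donor, three-taxon profile used across the election examples:
# taxon A clears 10%|75% strictly, B ties the ubiquity cutoff at exactly
# 0.75, C is rare.
toy_profile <- function() {
  tibble::tibble(
    donor = rep(paste0("d", 1:4), each = 3),
    taxon = rep(c("A", "B", "C"), 4),
    abundance = c(
      0.6, 0.3, 0.1,
      0.5, 0.5, 0,
      0.9, 0.05, 0.05,
      0.2, 0.8, 0
    )
  )
}

# Single-taxon profiles holding given abundance vectors (one per donor),
# for KS / ubiquity checks that only look at one taxon.
one_taxon_profile <- function(values, taxon = "T", prefix = "d") {
  tibble::tibble(
    donor = paste0(prefix, seq_along(values)),
    taxon = taxon,
    abundance = values
  )
}

# Random small count table: multinomial reads over power-law-ish taxa.
random_counts <- function(n_donors, n_taxa, depth_max = 200) {
  base <- seq_len(n_taxa)^-1
  base <- base / sum(base)
  counts <- t(vapply(seq_len(n_donors), function(i) {
    as.numeric(stats::rmultinom(1, sample(10:depth_max, 1), prob = base))
  }, numeric(n_taxa)))
  rownames(counts) <- paste0("d", seq_len(n_donors))
  colnames(counts) <- paste0("t", seq_len(n_taxa))
  tibble::tibble(
    donor = rep(rownames(counts), each = n_taxa),
    taxon = rep(colnames(counts), n_donors),
    count = as.numeric(t(counts))
  )
}

random_profile <- function(n_donors, n_taxa, depth_max = 200) {
  ct <- random_counts(n_donors, n_taxa, depth_max)
  ct <- dplyr::filter(ct,
    donor %in% donor_depths(ct)$donor[donor_depths(ct)$depth > 0])
  normalize_profile(ct)
}

# Brute-force dense-grid KS oracle: scans |S_x - S_y| over an even grid of
# abundance values (plus 0), computing each survival value from scratch.
ks_grid_oracle <- function(xv, yv, grid_n = 1e5) {
  g <- c(0, seq(0, 1, length.out = grid_n + 1))
  sx <- rowMeans(outer(g, xv, FUN = function(a, v) v > a))
  sy <- rowMeans(outer(g, yv, FUN = function(a, v) v > a))
  max(abs(sx - sy))
}

# Abundance vectors (zeros included) of one taxon from a profile.
taxon_values <- function(profile, taxon) {
  donors <- unique(profile$donor)
  v <- rep(0, length(donors))
  sub <- profile[profile$taxon == taxon, ]
  v[match(sub$donor, donors)] <- sub$abundance
  v
}

write_toy_counts <- function(path = tempfile(fileext = ".tsv")) {
  counts <- tibble::tibble(
    donor = rep(paste0("d", 1:4), each = 3),
    taxon = rep(c("A", "B", "C"), 4),
    count = c(60, 30, 10, 50, 50, 0, 90, 5, 5, 20, 80, 0)
  )
  write_count_table(counts, path)
  path
}
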