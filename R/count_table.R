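#' Taxonomic count tables and cohort profiles
#'
#' A *count table* is a long tibble with columns `donor`, `taxon` and `count`
#' holding non-negative integer read counts for one cohort (one row per
#' donor/taxon pair; absent pairs are zero). A *cohort profile* is the
#' compositional version: columns `donor`, `taxon`, `abundance` and `depth`,
#' where `abundance` is the proportion of the donor's reads assigned to the
#' taxon (per-donor values sum to 1) and `depth` is the donor's total read
#' count, carried forward for bootstrap resampling.
#'
#' @name count-tables
NULL

# ---- validation ------------------------------------------------------------

stop_validation <- function(msg) {
  abort(msg, class = "ubicore_validation_error")
}

#' Validate a long count table
#'
#' Checks the `donor`/`taxon`/`count` contract: counts must be non-negative
#' integers, and each donor/taxon pair may appear at most once. Returns the
#' table with identifier columns coerced to character, ready for the rest of
#' the package.
#'
#' @param counts A data frame with columns `donor`, `taxon`, `count`.
#' @return A validated tibble with columns `donor`, `taxon`, `count`.
#' @export
validate_count_table <- function(counts) {
  counts <- as_tibble(counts)
  need <- c("donor", "taxon", "count")
  miss <- setdiff(need, names(counts))
  if (length(miss) > 0) {
    stop_validation(paste0("count table is missing column(s): ",
                           paste(miss, collapse = ", ")))
  }
  counts <- counts |>
    mutate(donor = as.character(.data$donor), taxon = as.character(.data$taxon))
  if (any(is.na(counts$count))) stop_validation("count table contains NA counts")
  if (!is.numeric(counts$count)) stop_validation("counts must be numeric")
  if (any(counts$count < 0)) stop_validation("counts must be non-negative")
  if (any(counts$count != round(counts$count))) {
    stop_validation("counts must be integers (fractional read counts are not meaningful)")
  }
  if (anyDuplicated(paste(counts$donor, counts$taxon, sep = "\r"))) {
    stop_validation("duplicate donor/taxon pairs in count table")
  }
  counts$count <- as.numeric(counts$count)
  counts
}

# Dense donor x taxon matrix from a long count table or profile column.
# Donor and taxon order follow first appearance unless given explicitly.
wide_matrix <- function(df, value_col, donors = NULL, taxa = NULL) {
  if (is.null(donors)) donors <- unique(df$donor)
  if (is.null(taxa)) taxa <- unique(df$taxon)
  m <- matrix(0, nrow = length(donors), ncol = length(taxa),
              dimnames = list(donors, taxa))
  m[cbind(match(df$donor, donors), match(df$taxon, taxa))] <- df[[value_col]]
  m
}

counts_matrix <- function(counts) wide_matrix(counts, "count")

long_counts <- function(m) {
  tibble(
    donor = rep(rownames(m), each = ncol(m)),
    taxon = rep(colnames(m), times = nrow(m)),
    count = as.numeric(t(m))
  )
}

#' Per-donor sequencing depths
#'
#' @param counts A count table (see [validate_count_table()]).
#' @return A tibble with columns `donor` and `depth` (total reads).
#' @export
donor_depths <- function(counts) {
  counts <- validate_count_table(counts)
  counts |>
    group_by(.data$donor) |>
    summarise(depth = sum(.data$count), .groups = "drop")
}

# ---- I/O -------------------------------------------------------------------

#' Read a taxonomic count table
#'
#' Reads a tab-delimited count matrix into the long `donor`/`taxon`/`count`
#' form. In the `"tsv_donors_by_taxa"` dialect the first column holds donor
#' ids and the header row holds taxon labels; `"tsv_taxa_by_donors"` is the
#' transpose. `"biom"` delegates to the biomformat package (dense or sparse
#' BIOM, observations = taxa).
#'
#' Donors whose total read count is zero carry no compositional information
#' and are dropped with a warning (a zero row cannot be normalized).
#'
#' @param path Path to the input file.
#' @param dialect One of `"tsv_donors_by_taxa"` (default),
#'   `"tsv_taxa_by_donors"`, `"biom"`.
#' @return A count table tibble.
#' @export
read_count_table <- function(path,
                             dialect = c("tsv_donors_by_taxa",
                                         "tsv_taxa_by_donors", "biom")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(paste0("count table file not found: ", path),
          class = "ubicore_io_error")
  }
  if (dialect == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      abort("the biomformat package is required to read BIOM files",
            class = "ubicore_io_error")
    }
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b)) # taxa x samples
    counts <- long_counts(t(m))
    return(drop_zero_depth(validate_count_table(counts)))
  }
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) {
    abort(paste0("malformed count table (need a header and at least one row): ", path),
          class = "ubicore_parse_error")
  }
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  labels <- header[-1]
  if (length(labels) == 0 || any(!nzchar(labels)) || anyDuplicated(labels)) {
    abort("malformed header at line 1: column labels must be unique and non-empty",
          class = "ubicore_parse_error")
  }
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  ncol_expected <- length(header)
  m <- matrix(0, nrow = length(rows), ncol = length(labels))
  ids <- character(length(rows))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) != ncol_expected) {
      abort(sprintf("malformed row at line %d: expected %d fields, found %d",
                    i + 1L, ncol_expected, length(r)),
            class = "ubicore_parse_error")
    }
    ids[[i]] <- r[[1]]
    vals <- suppressWarnings(as.numeric(r[-1]))
    if (any(is.na(vals))) {
      abort(sprintf("non-numeric count at line %d", i + 1L),
            class = "ubicore_parse_error")
    }
    m[i, ] <- vals
  }
  if (anyDuplicated(ids)) {
    abort("row identifiers are not unique", class = "ubicore_parse_error")
  }
  rownames(m) <- ids
  colnames(m) <- labels
  if (dialect == "tsv_taxa_by_donors") m <- t(m)
  counts <- validate_count_table(long_counts(m))
  drop_zero_depth(counts)
}

drop_zero_depth <- function(counts) {
  dep <- donor_depths(counts)
  bad <- dep$donor[dep$depth == 0]
  if (length(bad) > 0) {
    warn(paste0("dropping ", length(bad), " donor(s) with zero read depth: ",
                paste(head(bad, 5), collapse = ", ")))
    counts <- filter(counts, !(.data$donor %in% bad))
  }
  counts
}

#' Write a count table in the canonical dialect
#'
#' Canonical form: donors as rows (input order preserved), taxa as columns in
#' lexicographic order, tab-delimited, UTF-8, Unix newlines. Reading a
#' canonical file back and writing it again is byte-identical.
#'
#' @param counts A count table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  counts <- validate_count_table(counts)
  taxa <- sort(unique(counts$taxon), method = "radix")
  m <- wide_matrix(counts, "count", taxa = taxa)
  body <- apply(m, 1, function(r) paste(format(r, scientific = FALSE, trim = TRUE),
                                        collapse = "\t"))
  out <- c(paste(c("donor", taxa), collapse = "\t"),
           paste(rownames(m), body, sep = "\t"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

# ---- transforms ------------------------------------------------------------

#' Collapse taxa to a coarser rank
#'
#' Sums counts within groups defined by a caller-supplied label extractor
#' (e.g. mapping OTU ids to genera, or lineage strings to families). Donor
#' depths are unchanged; total reads are conserved.
#'
#' @param counts A count table.
#' @param rank_extractor Function mapping each taxon label to a group label.
#' @return A count table at the collapsed rank.
#' @export
collapse_rank <- function(counts, rank_extractor) {
  counts <- validate_count_table(counts)
  taxa <- unique(counts$taxon)
  groups <- vapply(taxa, function(t) as.character(rank_extractor(t)[[1]]),
                   character(1))
  if (any(is.na(groups)) || any(!nzchar(groups))) {
    stop_validation("rank_extractor returned an empty or missing group label")
  }
  counts |>
    mutate(taxon = unname(groups[match(.data$taxon, taxa)])) |>
    group_by(.data$donor, .data$taxon) |>
    summarise(count = sum(.data$count), .groups = "drop")
}

#' Normalize a count table to a compositional cohort profile
#'
#' Divides each donor's counts by the donor's depth so that per-donor
#' abundances sum to 1 (compositional closure). The profile is a complete
#' donor-by-taxon grid: zero counts become explicit zero abundances, which the
#' ubiquity machinery relies on.
#'
#' @param counts A count table; every donor must have depth >= 1.
#' @return A profile tibble with columns `donor`, `taxon`, `abundance`,
#'   `depth`.
#' @export
normalize_profile <- function(counts) {
  counts <- validate_count_table(counts)
  m <- counts_matrix(counts)
  depth <- rowSums(m)
  if (any(depth < 1)) {
    stop_validation("zero-depth donor present; drop it before normalizing")
  }
  a <- m / depth
  tibble(
    donor = rep(rownames(m), each = ncol(m)),
    taxon = rep(colnames(m), times = nrow(m)),
    abundance = as.numeric(t(a)),
    depth = rep(as.numeric(depth), each = ncol(m))
  )
}

validate_profile <- function(profile) {
  profile <- as_tibble(profile)
  need <- c("donor", "taxon", "abundance")
  miss <- setdiff(need, names(profile))
  if (length(miss) > 0) {
    stop_validation(paste0("profile is missing column(s): ",
                           paste(miss, collapse = ", ")))
  }
  profile |>
    mutate(donor = as.character(.data$donor), taxon = as.character(.data$taxon))
}

abundance_matrix <- function(profile, donors = NULL, taxa = NULL) {
  wide_matrix(validate_profile(profile), "abundance", donors = donors, taxa = taxa)
}
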