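#' Ub-Ab plot: all taxa's ubiquity curves for one cohort
#'
#' Draws every taxon's ubiquity-versus-log10-abundance step curve, from the
#' plotted floor (default 1e-4, i.e. x = -4) up to abundance 1. When a
#' two-parameter cutoff is supplied it is marked with a red bull's-eye; taxa
#' whose curve passes above it (the elected core) are colored and labeled
#' while the rest are greyed out. Colors are assigned to at most `n_colored`
#' taxa, chosen by cohort-average abundance.
#'
#' @inheritParams ubiquity
#' @param abundance_cutoff,ubiquity_cutoff Optional two-parameter cutoff to
#'   mark; both must be given together.
#' @param floor Lower plotted abundance (default 1e-4).
#' @param n_colored Maximum number of colored taxa (default 50).
#' @param file Optional output path (svg/png/pdf inferred from extension);
#'   the ggplot object is returned either way.
#' @return A ggplot object.
#' @export
plot_ubab <- function(profile, abundance_cutoff = NULL, ubiquity_cutoff = NULL,
                      floor = 1e-4, n_colored = 50, file = NULL) {
  if (floor <= 0) abort("floor must be > 0", class = "ubicore_domain_error")
  profile <- validate_profile(profile)
  curves <- ubiquity_curve(profile)
  if (nrow(curves) == 0) {
    abort("no curves to plot", class = "ubicore_domain_error")
  }
  mean_ab <- profile |>
    group_by(.data$taxon) |>
    summarise(mean_abundance = mean(.data$abundance), .groups = "drop")
  # extend each curve to the floor and clamp below-floor breakpoints
  at_floor <- ubiquity_at(curves, floor) |> mutate(origin = TRUE)
  seg <- curves |>
    filter(.data$abundance > floor) |>
    mutate(origin = FALSE) |>
    bind_rows(at_floor) |>
    arrange(.data$taxon, .data$abundance) |>
    mutate(log_abundance = log10(.data$abundance))

  if (!is.null(abundance_cutoff) || !is.null(ubiquity_cutoff)) {
    check_cutoff(abundance_cutoff, ubiquity_cutoff)
    elected <- elect_core(profile, abundance_cutoff, ubiquity_cutoff)$taxon
  } else {
    elected <- unique(curves$taxon)
  }
  colored <- mean_ab |>
    filter(.data$taxon %in% elected) |>
    arrange(desc(.data$mean_abundance)) |>
    head(n_colored) |>
    pull("taxon")
  seg$group <- ifelse(seg$taxon %in% colored, seg$taxon, NA_character_)

  p <- ggplot(seg, aes(x = .data$log_abundance, y = 100 * .data$ubiquity,
                       group = .data$taxon)) +
    geom_step(data = ~ filter(.x, is.na(.data$group)),
              color = "grey70", linewidth = 0.3) +
    geom_step(data = ~ filter(.x, !is.na(.data$group)),
              aes(color = .data$group), linewidth = 0.5) +
    scale_x_continuous(limits = c(log10(floor), 0)) +
    scale_y_continuous(limits = c(0, 100)) +
    labs(x = expression(log[10] ~ "abundance"), y = "ubiquity (%)",
         color = "taxon") +
    theme_minimal()
  if (!is.null(abundance_cutoff)) {
    p <- p +
      annotate("point", x = log10(abundance_cutoff), y = 100 * ubiquity_cutoff,
               shape = 21, size = 5, color = "red", stroke = 1.2) +
      annotate("point", x = log10(abundance_cutoff), y = 100 * ubiquity_cutoff,
               shape = 19, size = 1.5, color = "red")
  }
  maybe_save(p, file)
}

#' Var-Ab plot: taxon stability across the cohort
#'
#' Scatter of the standard deviation versus the mean of each taxon's log10
#' abundances over responding donors, glyphs sized by ubiquity. Core taxa are
#' filled blue, minor-core taxa green, all others unfilled; the two sets must
#' be disjoint. Taxa whose sd is undefined (one responding donor) are
#' dropped from the panel.
#'
#' @param records A tibble from [varab_table()].
#' @param core_taxa,minor_core_taxa Character vectors of taxa to highlight
#'   (e.g. from [elect_core()] and [elect_minor_core()]).
#' @inheritParams plot_ubab
#' @return A ggplot object.
#' @export
plot_varab <- function(records, core_taxa = character(),
                       minor_core_taxa = character(), file = NULL) {
  overlap <- intersect(core_taxa, minor_core_taxa)
  if (length(overlap) > 0) {
    abort(paste0("core and minor-core sets must be disjoint; both contain: ",
                 paste(overlap, collapse = ", ")),
          class = "ubicore_domain_error")
  }
  records <- as_tibble(records) |>
    filter(!is.na(.data$sd_log_abundance)) |>
    mutate(class = dplyr::case_when(
      .data$taxon %in% core_taxa ~ "core",
      .data$taxon %in% minor_core_taxa ~ "minor core",
      TRUE ~ "other"
    ))
  p <- ggplot(records, aes(x = .data$mean_log_abundance,
                           y = .data$sd_log_abundance,
                           size = .data$ubiquity, fill = .data$class)) +
    geom_point(shape = 21, color = "grey30", alpha = 0.8) +
    scale_size_area(max_size = 8, limits = c(0, 1)) +
    scale_fill_manual(values = c(core = "blue", `minor core` = "green3",
                                 other = "white")) +
    labs(x = expression(mean ~ log[10] ~ "abundance"),
         y = expression(sd ~ log[10] ~ "abundance"),
         size = "ubiquity", fill = NULL) +
    theme_minimal()
  maybe_save(p, file)
}

#' U-U plot: per-taxon ubiquity of one cohort against another
#'
#' Parametric curves of each taxon's ubiquity in cohort X (x-axis) against
#' cohort Y (y-axis) across matched abundance cutoffs, with the grey diagonal
#' as the no-difference reference. The argmax points (greatest ubiquity
#' difference) of the `label_top` most-deviating taxa are labeled.
#'
#' @param x,y Cohort profiles.
#' @param label_top Number of most-deviating taxa to label (default 5).
#' @param cohort_names Axis labels, length 2.
#' @inheritParams plot_ubab
#' @return A ggplot object.
#' @export
plot_uu <- function(x, y, label_top = 5,
                    cohort_names = c("cohort X", "cohort Y"), file = NULL) {
  uu <- uu_curve(x, y)
  km <- ks_taxon(x, y)
  lab <- head(filter(km, .data$ks > 0), label_top)
  p <- ggplot(uu, aes(x = 100 * .data$ubiquity_x, y = 100 * .data$ubiquity_y,
                      group = .data$taxon)) +
    annotate("segment", x = 0, y = 0, xend = 100, yend = 100,
             color = "grey60", linewidth = 1.2) +
    geom_path(linewidth = 0.3, color = "grey30") +
    labs(x = paste0("ubiquity in ", cohort_names[[1]], " (%)"),
         y = paste0("ubiquity in ", cohort_names[[2]], " (%)")) +
    coord_equal(xlim = c(0, 100), ylim = c(0, 100)) +
    theme_minimal()
  if (nrow(lab) > 0) {
    p <- p +
      geom_point(data = lab, aes(x = 100 * .data$ubiquity_x,
                                 y = 100 * .data$ubiquity_y),
                 inherit.aes = FALSE, color = "red", size = 1.5) +
      geom_text(data = lab, aes(x = 100 * .data$ubiquity_x,
                                y = 100 * .data$ubiquity_y,
                                label = .data$taxon),
                inherit.aes = FALSE, hjust = -0.1, vjust = -0.4, size = 3)
  }
  maybe_save(p, file)
}

#' Null-distribution plot for an AWKS test
#'
#' @param object An `awks_test` object.
#' @param ... Unused.
#' @return A ggplot of the bootstrap null with the observed statistic marked.
#' @method autoplot awks_test
#' @export
autoplot.awks_test <- function(object, ...) {
  ggplot(tibble(awks = object$null), aes(x = .data$awks)) +
    geom_histogram(bins = 40, fill = "grey70", color = "grey40") +
    geom_vline(xintercept = object$statistic, color = "red") +
    labs(x = "AWKS under the bootstrap null", y = "replicates",
         subtitle = sprintf("observed = %.4f, p = %s", object$statistic,
                            object$p_display)) +
    theme_minimal()
}

maybe_save <- function(p, file) {
  if (!is.null(file)) {
    ggsave(file, plot = p, width = 7, height = 5)
  }
  p
}
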