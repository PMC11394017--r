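#' Two-sigma significance flag
#'
#' A standardized effect size outside the open interval
#' (-threshold, +threshold) is flagged significant; at the default 1.96
#' this is the 5% level. The boundary itself is not significant.
#'
#' @param ses Numeric vector of standardized effect sizes.
#' @param threshold Positive threshold (default 1.96).
#' @return Logical vector.
#' @examples
#' significance_flag(c(-1.996, 0.295, 1.96)) # TRUE FALSE FALSE
#' @export
significance_flag <- function(ses, threshold = 1.96) {
  if (any(!is.finite(ses))) abort("ses must be finite")
  abs(ses) > threshold
}

#' Run the full dietary-shift analysis pipeline
#'
#' From a prey count table, survey metadata and a guild map, computes the
#' five paired dietary-shift tests and the taxon ordination, in order:
#' optional collapse of raw items to subfamilies; per-pellet abundances and
#' within-survey proportions; a two-sided permutation test of the Pielou
#' evenness difference (later - earlier); a left-sided permutation test of
#' the Petraitis niche overlap; two-sided permutation tests of the three
#' feeding-guild per-pellet abundance differences; and NMDS of the taxa on
#' Euclidean distances of their per-pellet abundances. Alternatives are
#' fixed per feature as listed; the null model is configured through
#' `null_cfg`.
#'
#' @param counts A dense long count table (from [read_counts()],
#'   [generate_dataset()] or built in code).
#' @param surveys A survey table (`survey`, `year`, `pellets`).
#' @param guilds A guild map tibble (`taxon`, `guild`).
#' @param later,earlier Survey ids; all differences are later - earlier.
#' @param subfamily_map Optional item-to-subfamily map applied first.
#' @param null_cfg A [null_config()]. When it carries a seed, each of the
#'   five tests and the NMDS derive their own seed from it
#'   deterministically, so a full run is reproducible end to end.
#' @param guild_randomize `"taxon"` (default) randomizes the taxon matrix
#'   and aggregates each replicate to guilds post hoc, so the guild null
#'   inherits the taxon-level shuffle-and-swap constraints; `"guild"`
#'   randomizes the 3-row guild matrix directly (a far coarser null with
#'   very little power — see the methods vignette).
#' @param overlap_mode Direction convention for the reported overlap, as in
#'   [petraitis_overlap()].
#' @param nmds_starts,nmds_max_iter Passed to [nmds()].
#' @param out_dir Optional directory; when given, writes `results.tsv`,
#'   `nmds_coords.csv`, `guild_abundance.csv` and `run.log` there.
#' @return A `dietshift_results` object with [tidy()], [glance()],
#'   [autoplot()] and print methods. Fields: `results` (five-row tibble),
#'   `tests` (named list of `perm_test`), `nmds` (an `nmds_fit`),
#'   `overlap_candidates` (both directed overlaps and their geometric
#'   mean), `guild_abundance`, `diversity`, and the run settings.
#' @examples
#' fx <- study_like_fixture(seed = 7)
#' res <- run_pipeline(fx$counts, fx$surveys, fx$guilds,
#'                     later = "2012", earlier = "2004",
#'                     null_cfg = null_config(n_perm = 99, seed = 1))
#' tidy(res)
#' @export
run_pipeline <- function(counts, surveys, guilds, later, earlier,
                         subfamily_map = NULL,
                         null_cfg = null_config(),
                         guild_randomize = c("taxon", "guild"),
                         overlap_mode = c("geometric_mean", "a_on_b",
                                          "b_on_a"),
                         nmds_starts = 20, nmds_max_iter = 500,
                         out_dir = NULL) {
  guild_randomize <- match.arg(guild_randomize)
  overlap_mode <- match.arg(overlap_mode)
  if (identical(later, earlier)) {
    abort("later and earlier must name different surveys")
  }
  missing <- setdiff(c(later, earlier), surveys$survey)
  if (length(missing) > 0) {
    abort(paste0("survey not in metadata: ", paste(missing, collapse = ", ")))
  }
  if (!is.null(subfamily_map)) {
    counts <- aggregate_to_subfamily(counts, subfamily_map)
  }
  # restrict to the two compared surveys; taxa unexploited in both drop out
  counts <- dplyr::filter(counts, .data$survey %in% c(earlier, later))
  used <- counts |>
    dplyr::summarise(total = sum(.data$count), .by = "taxon") |>
    dplyr::filter(.data$total > 0)
  counts <- dplyr::filter(counts, .data$taxon %in% used$taxon)
  validate_counts(counts)
  surveys <- dplyr::filter(surveys, .data$survey %in% c(earlier, later))
  pellets <- stats::setNames(surveys$pellets, surveys$survey)

  abund <- per_pellet_abundance(counts, surveys)
  guild_counts <- aggregate_guilds(counts, guilds)
  guild_abund <- per_pellet_abundance(guild_counts, surveys)
  taxon_m <- as_count_matrix(counts)
  guild_m <- as_count_matrix(guild_counts)

  derive_cfg <- function(offset) {
    cfg <- null_cfg
    if (!is.null(cfg$seed)) {
      cfg$seed <- cfg$seed + offset
    }
    cfg
  }
  evenness_stat <- function(m) {
    pielou_evenness(m[, later]) - pielou_evenness(m[, earlier])
  }
  overlap_stat <- function(m) {
    petraitis_overlap(m[, later] / sum(m[, later]),
                      m[, earlier] / sum(m[, earlier]),
                      mode = overlap_mode)
  }
  guild_stat <- function(g) {
    if (guild_randomize == "guild") {
      function(m) {
        m[g, later] / pellets[[later]] - m[g, earlier] / pellets[[earlier]]
      }
    } else {
      function(m) {
        by_guild <- rowsum(m, guilds$guild[match(rownames(m), guilds$taxon)])
        a <- function(s) {
          if (g %in% rownames(by_guild)) by_guild[g, s] else 0
        }
        a(later) / pellets[[later]] - a(earlier) / pellets[[earlier]]
      }
    }
  }

  tests <- list(
    "Prey taxon evenness" = paired_permutation_test(
      taxon_m, evenness_stat, derive_cfg(1L), "two_sided",
      "Prey taxon evenness"),
    "Food niche overlap" = paired_permutation_test(
      taxon_m, overlap_stat, derive_cfg(2L), "left", "Food niche overlap"),
    "Omnivorous prey" = paired_permutation_test(
      if (guild_randomize == "guild") guild_m else taxon_m,
      guild_stat("omnivore"), derive_cfg(3L), "two_sided",
      "Omnivorous prey"),
    "Herbivorous prey" = paired_permutation_test(
      if (guild_randomize == "guild") guild_m else taxon_m,
      guild_stat("herbivore"), derive_cfg(4L), "two_sided",
      "Herbivorous prey"),
    "Insectivorous prey" = paired_permutation_test(
      if (guild_randomize == "guild") guild_m else taxon_m,
      guild_stat("insectivore"), derive_cfg(5L), "two_sided",
      "Insectivorous prey")
  )
  results <- dplyr::bind_rows(lapply(tests, tidy))

  nmds_seed <- if (is.null(null_cfg$seed)) NULL else null_cfg$seed + 10L
  ord <- nmds(taxon_distances(abund), k = 2, n_starts = nmds_starts,
              max_iter = nmds_max_iter, seed = nmds_seed)

  out <- structure(
    list(results = results, tests = tests, nmds = ord,
         overlap_candidates = niche_overlap(counts, later, earlier,
                                            mode = "all"),
         guild_abundance = guild_abund,
         diversity = diet_diversity(counts),
         later = later, earlier = earlier, null_cfg = null_cfg),
    class = "dietshift_results"
  )
  if (!is.null(out_dir)) {
    write_pipeline_outputs(out, out_dir)
  }
  out
}

write_pipeline_outputs <- function(x, out_dir) {
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  write_results_table(x$results, file.path(out_dir, "results.tsv"))
  readr::write_csv(tidy(x$nmds), file.path(out_dir, "nmds_coords.csv"),
                   progress = FALSE)
  readr::write_csv(x$guild_abundance,
                   file.path(out_dir, "guild_abundance.csv"),
                   progress = FALSE)
  writeLines(c(
    "dietary-shift pipeline run",
    paste0("surveys: later=", x$later, " earlier=", x$earlier),
    paste0("null variant: ", x$null_cfg$variant),
    paste0("n_perm: ", x$null_cfg$n_perm),
    paste0("seed: ", x$null_cfg$seed %||% "none"),
    paste0("nmds stress: ", format(x$nmds$stress))
  ), file.path(out_dir, "run.log"))
  invisible(x)
}

#' @export
print.dietshift_results <- function(x, ...) {
  cat(sprintf("Dietary-shift analysis: %s vs %s (%s null, %d replicates)\n",
              x$later, x$earlier, x$null_cfg$variant, x$null_cfg$n_perm))
  print(as.data.frame(x$results), row.names = FALSE, digits = 4)
  cat(sprintf("NMDS stress-1: %.3g\n", x$nmds$stress))
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `dietshift_results` object.
#' @param ... Unused.
#' @export
tidy.dietshift_results <- function(x, ...) {
  x$results
}

#' @rdname run_pipeline
#' @export
glance.dietshift_results <- function(x, ...) {
  tibble::tibble(
    later = x$later,
    earlier = x$earlier,
    variant = x$null_cfg$variant,
    n_perm = x$null_cfg$n_perm,
    seed = x$null_cfg$seed %||% NA_integer_,
    nmds_stress = x$nmds$stress,
    n_significant = sum(x$results$significant)
  )
}

#' @rdname run_pipeline
#' @param object A `dietshift_results` object.
#' @export
autoplot.dietshift_results <- function(object, ...) {
  plot_guild_abundance(object)
}

#' Guild abundance bar chart
#'
#' Per-pellet abundance of each feeding guild in the two surveys, the
#' guild-level summary view of a dietary shift.
#'
#' @param x A `dietshift_results` object, or a guild abundance tibble
#'   (columns `survey`, `taxon`, `abundance`).
#' @return A ggplot object.
#' @export
plot_guild_abundance <- function(x) {
  df <- if (inherits(x, "dietshift_results")) x$guild_abundance else x
  ggplot2::ggplot(df, ggplot2::aes(x = .data$taxon, y = .data$abundance,
                                   fill = .data$survey)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "feeding guild", y = "prey individuals per pellet",
                  fill = "survey") +
    ggplot2::theme_minimal()
}
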