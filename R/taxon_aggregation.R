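#' Collapse mixed-rank prey items to a single taxonomic rank
#'
#' Pellet material often yields identifications at mixed ranks (species,
#' genus, family). Summing all items into the subfamily (or any single rank)
#' removes taxonomic nestedness — no output label is an ancestor of another —
#' at the expense of resolution. Counts are summed within each mapped label,
#' per survey.
#'
#' @param counts A dense long count table (`survey`, `taxon`, `count`), the
#'   `taxon` column holding raw item labels.
#' @param map A tibble with columns `item` and `subfamily` (see
#'   [read_subfamily_map()]); every raw label must have an entry.
#' @return A dense long count table whose `taxon` column holds the mapped
#'   labels, ordered by first appearance of their first member item.
#' @examples
#' counts <- tibble::tibble(
#'   survey = "2004",
#'   taxon = c("Apodemus sylvaticus", "Mus musculus"),
#'   count = c(3L, 4L)
#' )
#' map <- tibble::tibble(
#'   item = c("Apodemus sylvaticus", "Mus musculus"),
#'   subfamily = "Murinae"
#' )
#' aggregate_to_subfamily(counts, map) # Murinae, 7
#' @export
aggregate_to_subfamily <- function(counts, map) {
  if (nrow(map) == 0 && nrow(counts) > 0) {
    abort("empty subfamily map for a non-empty count table")
  }
  unmapped <- setdiff(unique(counts$taxon), map$item)
  if (length(unmapped) > 0) {
    abort(paste0("unmapped item label(s): ", paste(unmapped, collapse = ", ")))
  }
  out <- counts |>
    dplyr::mutate(taxon = map$subfamily[match(.data$taxon, map$item)]) |>
    dplyr::summarise(count = sum(.data$count),
                     .by = c("taxon", "survey"))
  densify_counts(out, taxa = unique(out$taxon),
                 survey_ids = unique(counts$survey))
}

#' Per-pellet prey abundance
#'
#' Divides each taxon's count by the number of pellets collected in that
#' survey. This normalisation makes paired surveys with very unequal
#' collection effort comparable; the result is referred to as "abundance"
#' throughout the package.
#'
#' @param counts A dense long count table (`survey`, `taxon`, `count`).
#' @param surveys A survey table with columns `survey` and `pellets`.
#' @return The input tibble with an added `abundance` column
#'   (prey individuals per pellet).
#' @examples
#' counts <- tibble::tibble(survey = "2012", taxon = "Murinae", count = 40L)
#' surveys <- tibble::tibble(survey = "2012", year = 2012L, pellets = 159L)
#' per_pellet_abundance(counts, surveys)$abundance # 0.2516
#' @export
per_pellet_abundance <- function(counts, surveys) {
  missing <- setdiff(unique(counts$survey), surveys$survey)
  if (length(missing) > 0) {
    abort(paste0("survey missing a pellet_count: ",
                 paste(missing, collapse = ", ")))
  }
  counts |>
    dplyr::mutate(
      abundance = .data$count /
        surveys$pellets[match(.data$survey, surveys$survey)]
    )
}

#' Within-survey prey proportions
#'
#' Divides each taxon's count by the survey total, giving the utilization
#' distribution consumed by [pielou_evenness()] and [petraitis_overlap()].
#'
#' @param counts A dense long count table (`survey`, `taxon`, `count`).
#' @return The input tibble with an added `proportion` column; proportions
#'   sum to 1 within each survey.
#' @export
prey_proportions <- function(counts) {
  totals <- tapply(counts$count, counts$survey, sum)
  if (any(totals < 1)) {
    abort(paste0("survey with no prey individuals: ",
                 paste(names(totals)[totals < 1], collapse = ", ")))
  }
  counts |>
    dplyr::mutate(proportion = .data$count / sum(.data$count),
                  .by = "survey")
}

#' Aggregate prey counts to feeding guilds
#'
#' Sums taxon counts into the three feeding guilds. All three guild rows are
#' always present, including guilds with no member taxa or all-zero counts,
#' so the per-guild tests are always defined.
#'
#' @param counts A dense long count table (`survey`, `taxon`, `count`).
#' @param guilds A guild map tibble (`taxon`, `guild`); every taxon in
#'   `counts` must have an entry.
#' @return A dense long count table whose `taxon` column holds the guild
#'   names, always all of insectivore, herbivore, omnivore, in that order.
#' @export
aggregate_guilds <- function(counts, guilds) {
  unmapped <- setdiff(unique(counts$taxon), guilds$taxon)
  if (length(unmapped) > 0) {
    abort(paste0("taxon missing from guild map: ",
                 paste(unmapped, collapse = ", ")))
  }
  bad <- setdiff(unique(guilds$guild), GUILDS)
  if (length(bad) > 0) {
    abort(paste0("unknown guild label(s): ", paste(bad, collapse = ", ")))
  }
  out <- counts |>
    dplyr::mutate(taxon = guilds$guild[match(.data$taxon, guilds$taxon)]) |>
    dplyr::summarise(count = sum(.data$count),
                     .by = c("taxon", "survey"))
  # guild rows are never dropped, even when all-zero
  densify_counts(out, taxa = GUILDS, survey_ids = unique(counts$survey))
}
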