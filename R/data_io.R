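#' Feeding-guild vocabulary
#'
#' The closed set of feeding guilds used to classify micromammal prey taxa.
#'
#' @format Character vector of length 3.
#' @export
GUILDS <- c("insectivore", "herbivore", "omnivore")

read_strict_csv <- function(path, col_types) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path))
  }
  x <- suppressWarnings(
    readr::read_csv(path, col_types = col_types, progress = FALSE)
  )
  missing <- setdiff(names(col_types$cols), names(x))
  if (length(missing) > 0) {
    abort(paste0("missing column(s) in ", basename(path), ": ",
                 paste(missing, collapse = ", ")))
  }
  probs <- readr::problems(x)
  if (nrow(probs) > 0) {
    abort(paste0("could not parse ", basename(path), ": ",
                 probs$expected[1], " expected at row ", probs$row[1]))
  }
  x
}

#' Read a survey metadata table
#'
#' Reads a CSV with header `survey,year,pellets` describing each pellet
#' survey: a short identifier, the calendar year, and the number of pellets
#' collected (the denominator of per-pellet abundances).
#'
#' @param path Path to a CSV file with columns `survey`, `year`, `pellets`.
#' @return A tibble with columns `survey` (character), `year` (integer) and
#'   `pellets` (integer), one row per survey, in file order.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("survey,year,pellets", "2004,2004,535", "2012,2012,159"), f)
#' read_surveys(f)
#' @export
read_surveys <- function(path) {
  x <- read_strict_csv(path, readr::cols(
    survey = readr::col_character(),
    year = readr::col_integer(),
    pellets = readr::col_double()
  ))
  x <- dplyr::select(x, "survey", "year", "pellets")
  if (anyDuplicated(x$survey)) {
    abort(paste0("duplicate survey id: ",
                 paste(unique(x$survey[duplicated(x$survey)]), collapse = ", ")))
  }
  if (nrow(x) > 0) {
    if (any(is.na(x$pellets)) || any(x$pellets != as.integer(x$pellets))) {
      abort("pellets must be an integer count")
    }
    if (any(x$pellets < 1)) {
      abort("pellet_count must be ≥ 1")
    }
  }
  x$pellets <- as.integer(x$pellets)
  x
}

#' Read a long-format prey count table
#'
#' Reads a CSV with header `survey,taxon,count` holding the number of prey
#' individuals of each taxon identified in each survey, and densifies it:
#' every (taxon, survey) pair absent from the file becomes an explicit zero
#' (an unexploited resource category). Taxa are ordered by first appearance
#' in the file; surveys follow the order of `surveys`.
#'
#' @param path Path to a CSV file with columns `survey`, `taxon`, `count`.
#' @param surveys A survey table as returned by [read_surveys()].
#' @return A tibble with columns `survey`, `taxon`, `count` (integer),
#'   dense over all taxon-survey pairs.
#' @details Duplicate (survey, taxon) rows are an error rather than being
#'   summed, and a taxon whose count is zero in every survey is rejected:
#'   both rules keep the per-survey count of unexploited categories (a
#'   conserved quantity of the null model) well defined.
#' @export
read_counts <- function(path, surveys) {
  x <- read_strict_csv(path, readr::cols(
    survey = readr::col_character(),
    taxon = readr::col_character(),
    count = readr::col_double()
  ))
  x <- dplyr::select(x, "survey", "taxon", "count")
  unknown <- setdiff(x$survey, surveys$survey)
  if (length(unknown) > 0) {
    abort(paste0("unknown survey id in counts: ",
                 paste(unknown, collapse = ", ")))
  }
  if (any(is.na(x$count)) || any(x$count < 0) ||
      any(x$count != as.integer(x$count))) {
    abort("count must be a non-negative integer")
  }
  dup <- duplicated(x[, c("survey", "taxon")])
  if (any(dup)) {
    abort(paste0("duplicated (survey, taxon) pair: ",
                 x$survey[dup][1], ", ", x$taxon[dup][1]))
  }
  x$count <- as.integer(x$count)
  out <- densify_counts(x, taxa = unique(x$taxon), survey_ids = surveys$survey)
  validate_counts(out)
  out
}

# Dense long table over taxa x survey_ids with zeros for absent pairs.
densify_counts <- function(x, taxa, survey_ids) {
  grid <- tidyr::expand_grid(taxon = taxa, survey = survey_ids)
  out <- dplyr::left_join(grid, x, by = c("survey", "taxon"))
  out$count[is.na(out$count)] <- 0L
  tibble::as_tibble(out[, c("survey", "taxon", "count")])
}

# Shared validation of a dense long count table.
validate_counts <- function(counts) {
  stopifnot(all(c("survey", "taxon", "count") %in% names(counts)))
  if (any(counts$count < 0)) abort("negative count")
  tot_taxon <- tapply(counts$count, counts$taxon, sum)
  if (any(tot_taxon == 0)) {
    abort(paste0("all-zero taxon: ",
                 paste(names(tot_taxon)[tot_taxon == 0], collapse = ", ")))
  }
  tot_survey <- tapply(counts$count, counts$survey, sum)
  if (any(tot_survey < 1)) {
    abort(paste0("survey with no prey individuals: ",
                 paste(names(tot_survey)[tot_survey < 1], collapse = ", ")))
  }
  invisible(counts)
}

#' Read a taxon-to-guild map
#'
#' Reads a CSV with header `taxon,guild` assigning each prey taxon to one of
#' the three feeding guilds: `insectivore`, `herbivore` or `omnivore`.
#' Guild labels are matched case-insensitively.
#'
#' @param path Path to a CSV file with columns `taxon`, `guild`.
#' @return A tibble with columns `taxon` and `guild` (lower case).
#' @export
read_guild_map <- function(path) {
  x <- read_strict_csv(path, readr::cols(
    taxon = readr::col_character(),
    guild = readr::col_character()
  ))
  x <- dplyr::select(x, "taxon", "guild")
  x$guild <- tolower(trimws(x$guild))
  bad <- setdiff(unique(x$guild), GUILDS)
  if (length(bad) > 0) {
    abort(paste0("unknown guild label(s): ", paste(bad, collapse = ", "),
                 "; allowed: ", paste(GUILDS, collapse = ", ")))
  }
  if (anyDuplicated(x$taxon)) {
    abort(paste0("duplicate taxon in guild map: ",
                 paste(unique(x$taxon[duplicated(x$taxon)]), collapse = ", ")))
  }
  x
}

#' Read a raw-item-to-subfamily map
#'
#' Reads a CSV with header `item,subfamily` mapping mixed-rank prey
#' identifications (species, genus, "sp." aggregates) to the subfamily each
#' belongs to, for use with [aggregate_to_subfamily()].
#'
#' @param path Path to a CSV file with columns `item`, `subfamily`.
#' @return A tibble with columns `item` and `subfamily`.
#' @export
read_subfamily_map <- function(path) {
  x <- read_strict_csv(path, readr::cols(
    item = readr::col_character(),
    subfamily = readr::col_character()
  ))
  x <- dplyr::select(x, "item", "subfamily")
  if (anyDuplicated(x$item)) {
    abort(paste0("duplicate item in subfamily map: ",
                 paste(unique(x$item[duplicated(x$item)]), collapse = ", ")))
  }
  x
}

#' Write a permutation-test results table
#'
#' Writes the results of the paired permutation tests as a TSV with one row
#' per dietary feature and columns `feature`, `observed`, `null_mean`,
#' `ses`, `p`, `significant`. Observed and null-mean statistics are printed
#' to 5 decimals, standardized effect sizes to 3 and p-values to 4,
#' following the usual print conventions for such tables.
#'
#' @param results A tibble of test results (e.g. from [tidy()] on a
#'   [run_pipeline()] bundle, or `dplyr::bind_rows()` of tidied
#'   [paired_permutation_test()] fits) with columns `feature`, `observed`,
#'   `null_mean`, `ses`, `p`; or a list of `perm_test` objects.
#' @param path Output file path.
#' @return Invisibly, the formatted tibble that was written.
#' @export
write_results_table <- function(results, path) {
  if (is.list(results) && !is.data.frame(results) &&
      all(vapply(results, inherits, logical(1), "perm_test"))) {
    results <- dplyr::bind_rows(lapply(results, tidy))
  }
  if (!is.data.frame(results) || nrow(results) == 0) {
    abort("nothing to write")
  }
  out <- tibble::tibble(
    feature = results$feature,
    observed = sprintf("%.5f", results$observed),
    null_mean = sprintf("%.5f", results$null_mean),
    ses = sprintf("%.3f", results$ses),
    p = sprintf("%.4f", results$p),
    significant = significance_flag(results$ses)
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(out)
}

# ---- internal converters between the tidy long table and the matrix form --

# taxa x surveys integer matrix from a dense long count table
as_count_matrix <- function(counts) {
  taxa <- unique(counts$taxon)
  survey_ids <- unique(counts$survey)
  m <- matrix(0L, nrow = length(taxa), ncol = length(survey_ids),
              dimnames = list(taxa, survey_ids))
  m[cbind(match(counts$taxon, taxa), match(counts$survey, survey_ids))] <-
    as.integer(counts$count)
  m
}

counts_from_matrix <- function(m) {
  tibble::tibble(
    survey = rep(colnames(m), each = nrow(m)),
    taxon = rep(rownames(m), times = ncol(m)),
    count = as.integer(m)
  )
}
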