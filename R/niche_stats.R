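check_proportions <- function(p, arg = "p", tol = 1e-8) {
  if (any(!is.finite(p)) || any(p < 0)) {
    abort(paste0(arg, " must be non-negative and finite"))
  }
  if (abs(sum(p) - 1) > tol) {
    abort(paste0(arg, " must sum to 1 (got ", format(sum(p)), ")"))
  }
  invisible(p)
}

#' Shannon entropy of a proportion vector
#'
#' \eqn{H = -\sum_{p_i > 0} p_i \ln p_i}, in nats. Zero proportions
#' contribute nothing.
#'
#' @param p Numeric vector of proportions summing to 1.
#' @return Entropy in nats.
#' @examples
#' shannon_entropy(rep(0.25, 4)) # log(4)
#' @export
shannon_entropy <- function(p) {
  check_proportions(p)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Pielou's J evenness of a count vector
#'
#' \eqn{J = H / \ln S} where \eqn{H} is the Shannon entropy of the count
#' proportions and \eqn{S} the number of taxa actually used (count > 0).
#' J lies in \[0, 1\], equals 1 for a perfectly even diet, weights common
#' and rare taxa equally, and is invariant to scaling all counts.
#'
#' @param x Numeric vector of non-negative counts with at least two
#'   positive entries.
#' @return Evenness in \[0, 1\].
#' @examples
#' pielou_evenness(c(10, 10, 10, 10)) # 1
#' pielou_evenness(c(2, 1, 1))
#' @export
pielou_evenness <- function(x) {
  if (any(x < 0)) abort("counts must be non-negative")
  s_used <- sum(x > 0)
  if (s_used <= 1) {
    abort("evenness undefined for a single used taxon")
  }
  shannon_entropy(x / sum(x)) / log(s_used)
}

#' Per-survey diet diversity summary
#'
#' Shannon entropy, used richness and Pielou evenness of each survey's prey
#' proportions.
#'
#' @param counts A dense long count table (`survey`, `taxon`, `count`).
#' @return A tibble with columns `survey`, `richness_used`, `shannon`,
#'   `evenness`, one row per survey. `evenness` is `NA` for a survey with a
#'   single used taxon (where J is undefined).
#' @export
diet_diversity <- function(counts) {
  counts |>
    dplyr::summarise(
      richness_used = sum(.data$count > 0),
      shannon = shannon_entropy(.data$count / sum(.data$count)),
      evenness = if (sum(.data$count > 0) >= 2) {
        pielou_evenness(.data$count)
      } else {
        NA_real_
      },
      .by = "survey"
    )
}

#' Paired difference in Pielou evenness
#'
#' \eqn{\Delta J = J_{later} - J_{earlier}} between two surveys of the same
#' count table; the observed statistic of the evenness permutation test.
#'
#' @param counts A dense long count table (`survey`, `taxon`, `count`).
#' @param later,earlier Survey ids; the difference is later minus earlier.
#' @return Numeric difference in evenness.
#' @export
evenness_difference <- function(counts, later, earlier) {
  m <- as_count_matrix(counts)
  check_survey_ids(m, c(later, earlier))
  pielou_evenness(m[, later]) - pielou_evenness(m[, earlier])
}

check_survey_ids <- function(m, ids) {
  missing <- setdiff(ids, colnames(m))
  if (length(missing) > 0) {
    abort(paste0("unknown survey id: ", paste(missing, collapse = ", ")))
  }
}

petraitis_directed <- function(p_a, p_b) {
  on <- p_a > 0
  if (any(p_b[on] == 0)) {
    return(0) # complete-separation limit
  }
  exp(sum(p_a[on] * log(p_b[on])) - sum(p_a[on] * log(p_a[on])))
}

#' Petraitis specific niche overlap
#'
#' The specific overlap of utilization distribution A on B is
#' \eqn{O_{A|B} = \exp(\sum_{p_{Ai}>0} p_{Ai} \ln p_{Bi} -
#' \sum_{p_{Ai}>0} p_{Ai} \ln p_{Ai}) = \exp(-KL(p_A \| p_B))},
#' the exponent of the mean log-likelihood ratio of A's utilization under
#' B's distribution. It ranges from 0 (no overlap or complete separation;
#' returned whenever A uses a category B does not) to 1 (identical
#' distributions). The default report is the geometric mean of the two
#' directed overlaps, which is symmetric in its arguments.
#'
#' @param p_a,p_b Proportion vectors over the same ordered taxon set, each
#'   summing to 1.
#' @param mode One of `"geometric_mean"` (default), `"a_on_b"`, `"b_on_a"`.
#' @return Overlap in \[0, 1\].
#' @examples
#' petraitis_overlap(c(0.5, 0.5), c(0.25, 0.75), mode = "a_on_b")
#' petraitis_overlap(c(1, 0), c(0, 1)) # 0: complete separation
#' @export
petraitis_overlap <- function(p_a, p_b,
                              mode = c("geometric_mean", "a_on_b", "b_on_a")) {
  mode <- match.arg(mode)
  if (length(p_a) != length(p_b)) {
    abort("proportion vectors must have the same length")
  }
  check_proportions(p_a, "p_a")
  check_proportions(p_b, "p_b")
  switch(mode,
    a_on_b = petraitis_directed(p_a, p_b),
    b_on_a = petraitis_directed(p_b, p_a),
    geometric_mean = sqrt(petraitis_directed(p_a, p_b) *
                            petraitis_directed(p_b, p_a))
  )
}

#' Niche overlap between two surveys of a count table
#'
#' Convenience wrapper: converts each survey's counts to proportions and
#' calls [petraitis_overlap()]. With `mode = "all"` a one-row tibble with
#' the two directed overlaps and their geometric mean is returned, since a
#' single printed overlap value can correspond to any of the three.
#'
#' @param counts A dense long count table (`survey`, `taxon`, `count`).
#' @param later,earlier Survey ids (A = later, B = earlier).
#' @param mode As in [petraitis_overlap()], or `"all"`.
#' @return A scalar overlap, or a one-row tibble for `mode = "all"`.
#' @export
niche_overlap <- function(counts, later, earlier,
                          mode = c("geometric_mean", "a_on_b", "b_on_a",
                                   "all")) {
  mode <- match.arg(mode)
  m <- as_count_matrix(counts)
  check_survey_ids(m, c(later, earlier))
  p_a <- m[, later] / sum(m[, later])
  p_b <- m[, earlier] / sum(m[, earlier])
  if (mode == "all") {
    tibble::tibble(
      later_on_earlier = petraitis_directed(p_a, p_b),
      earlier_on_later = petraitis_directed(p_b, p_a),
      geometric_mean = sqrt(petraitis_directed(p_a, p_b) *
                              petraitis_directed(p_b, p_a))
    )
  } else {
    petraitis_overlap(p_a, p_b, mode = mode)
  }
}

#' Paired difference in per-pellet guild abundance
#'
#' \eqn{\Delta a = a_{g,later} - a_{g,earlier}} in prey individuals per
#' pellet, for one feeding guild.
#'
#' @param abund An abundance table from [per_pellet_abundance()] applied to
#'   a guild-aggregated count table (columns `survey`, `taxon`,
#'   `abundance`; `taxon` holds guild names).
#' @param guild Guild label.
#' @param later,earlier Survey ids.
#' @return Numeric difference in per-pellet abundance.
#' @export
guild_abundance_difference <- function(abund, guild, later, earlier) {
  if (!guild %in% abund$taxon) {
    abort(paste0("unknown guild: ", guild))
  }
  pick <- function(s) {
    v <- abund$abundance[abund$taxon == guild & abund$survey == s]
    if (length(v) != 1) abort(paste0("unknown survey id: ", s))
    v
  }
  pick(later) - pick(earlier)
}

#' Change in a taxon's relative and per-pellet abundance
#'
#' A percentage change between surveys admits two readings, so both are
#' returned: the percentage-point change in the taxon's within-survey
#' proportion, \eqn{100 (p_{later} - p_{earlier})}, and the percent change
#' in its per-pellet abundance,
#' \eqn{100 (a_{later} - a_{earlier}) / a_{earlier}}.
#'
#' @param counts A dense long count table (`survey`, `taxon`, `count`).
#' @param surveys A survey table with columns `survey` and `pellets`.
#' @param taxon Taxon label.
#' @param later,earlier Survey ids.
#' @return A one-row tibble with columns `taxon`, `pp_change_proportion`
#'   and `pct_change_abundance`.
#' @export
relative_abundance_change <- function(counts, surveys, taxon, later, earlier) {
  if (!taxon %in% counts$taxon) {
    abort(paste0("unknown taxon: ", taxon))
  }
  props <- prey_proportions(counts)
  abund <- per_pellet_abundance(counts, surveys)
  get <- function(tbl, col, s) {
    tbl[[col]][tbl$taxon == taxon & tbl$survey == s]
  }
  a_earlier <- get(abund, "abundance", earlier)
  if (a_earlier == 0) {
    abort(paste0("relative change undefined: zero abundance of ", taxon,
                 " in survey ", earlier))
  }
  tibble::tibble(
    taxon = taxon,
    pp_change_proportion =
      100 * (get(props, "proportion", later) -
               get(props, "proportion", earlier)),
    pct_change_abundance =
      100 * (get(abund, "abundance", later) - a_earlier) / a_earlier
  )
}
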