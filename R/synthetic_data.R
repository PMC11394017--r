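default_guild_assignment <- function(n_taxa) {
  rep_len(c("insectivore", "omnivore", "insectivore", "omnivore",
            "herbivore"), n_taxa)
}

#' Configuration of the synthetic pellet-survey generator
#'
#' Describes a pair of pellet surveys over a common prey-taxon pool. Counts
#' are generated Dirichlet-multinomially: each survey's prey total is
#' Poisson with mean `lambda` prey per pellet times its pellet count, taxon
#' proportions are an independent Dirichlet draw per survey, and counts are
#' multinomial. `shift` tilts survey 2's Dirichlet weights by
#' `(1 + shift)` for omnivore taxa and `1 / (1 + shift)` for insectivore
#' taxa, emulating an omnivore-up / insectivore-down dietary shift;
#' `shift = 0` makes the two surveys exchangeable draws from one generating
#' distribution.
#'
#' @param n_taxa Number of prey taxa in the pool (default 9).
#' @param guilds Feeding guild per taxon; defaults to a mix of 4
#'   insectivores, 4 omnivores and 1 herbivore for `n_taxa = 9`.
#' @param pellets Integer vector of length 2: pellets collected per survey.
#'   Defaults to `c(535, 159)`, a strongly unequal paired effort.
#' @param lambda Mean prey individuals per pellet (default 1.3).
#' @param baseline Dirichlet concentration vector (default 1 per taxon: a
#'   flat Dirichlet, giving realistic uneven broken-stick-like profiles).
#' @param shift Non-negative guild-shift multiplier applied in survey 2.
#' @param zero_fraction Probability that a taxon is structurally
#'   unexploited in a given survey: its Dirichlet weight is removed before
#'   the survey's utilization distribution is drawn, emulating unexploited
#'   resource categories (default 0.1).
#' @param taxa Optional taxon labels.
#' @param survey_ids,years Survey labels and calendar years.
#' @param seed Optional integer seed.
#' @return A `synthetic_config` list, validated.
#' @export
synthetic_config <- function(n_taxa = 9,
                             guilds = default_guild_assignment(n_taxa),
                             pellets = c(535L, 159L),
                             lambda = 1.3,
                             baseline = rep(1, n_taxa),
                             shift = 0,
                             zero_fraction = 0.1,
                             taxa = sprintf("taxon_%02d", seq_len(n_taxa)),
                             survey_ids = c("S1", "S2"),
                             years = c(1L, 2L),
                             seed = NULL) {
  if (n_taxa < 2) abort("n_taxa must be at least 2")
  if (length(guilds) != n_taxa || !all(guilds %in% GUILDS)) {
    abort("guilds must assign each taxon to insectivore/herbivore/omnivore")
  }
  if (length(pellets) != 2 || any(pellets < 1)) {
    abort("pellets must be two counts, each at least 1")
  }
  if (lambda <= 0) abort("lambda must be positive")
  if (length(baseline) != n_taxa || any(baseline <= 0)) {
    abort("baseline must be a positive concentration per taxon")
  }
  if (shift < 0) abort("shift must be non-negative")
  if (zero_fraction < 0 || zero_fraction >= 1) {
    abort("zero_fraction must lie in [0, 1)")
  }
  if (length(taxa) != n_taxa || anyDuplicated(taxa)) {
    abort("taxa must be n_taxa unique labels")
  }
  structure(
    list(n_taxa = n_taxa, guilds = guilds,
         pellets = as.integer(pellets), lambda = lambda,
         baseline = baseline, shift = shift, zero_fraction = zero_fraction,
         taxa = taxa, survey_ids = survey_ids, years = as.integer(years),
         seed = seed),
    class = "synthetic_config"
  )
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha)
  g / sum(g)
}

#' Generate a synthetic paired pellet-survey dataset
#'
#' Draws one dataset under a [synthetic_config()] and returns it in the
#' same shape the readers produce, so it flows straight into the analysis
#' pipeline. Taxa that end up unexploited in both surveys are dropped; the
#' result always passes the count-table validators.
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `surveys` (tibble `survey`, `year`,
#'   `pellets`), `counts` (dense long tibble `survey`, `taxon`, `count`)
#'   and `guilds` (tibble `taxon`, `guild` for the retained taxa).
#' @examples
#' ds <- generate_dataset(synthetic_config(seed = 42))
#' dplyr::count(ds$guilds, guild)
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(config$seed)) {
    set.seed(config$seed)
  }
  n <- config$n_taxa
  tilt <- ifelse(config$guilds == "omnivore", 1 + config$shift,
                 ifelse(config$guilds == "insectivore",
                        1 / (1 + config$shift), 1))
  weights <- list(config$baseline, config$baseline * tilt)
  m <- matrix(0L, n, 2, dimnames = list(config$taxa, config$survey_ids))
  for (j in 1:2) {
    n_prey <- rpois(1, config$lambda * config$pellets[j])
    if (n_prey < 2) {
      abort("degenerate configuration: a survey drew fewer than 2 prey")
    }
    # structural zeros first: each taxon is unexploited in this survey with
    # probability zero_fraction, then the survey's utilization distribution
    # is drawn over the exploited taxa only
    exploited <- stats::runif(n) >= config$zero_fraction
    if (sum(exploited) < 2) {
      abort("degenerate configuration: fewer than 2 exploited taxa")
    }
    p <- numeric(n)
    p[exploited] <- rdirichlet1(weights[[j]][exploited])
    m[, j] <- rmultinom(1, n_prey, p)
  }
  m <- m[rowSums(m) > 0, , drop = FALSE]
  keep <- match(rownames(m), config$taxa)
  if (nrow(m) < 2 || any(colSums(m > 0) < 2) || any(colSums(m) < 1)) {
    abort("degenerate configuration: fewer than 2 used taxa in a survey")
  }
  counts <- counts_from_matrix(m)
  validate_counts(counts)
  list(
    surveys = tibble::tibble(survey = config$survey_ids,
                             year = config$years,
                             pellets = config$pellets),
    counts = counts,
    guilds = tibble::tibble(taxon = rownames(m),
                            guild = config$guilds[keep])
  )
}

#' A study-like synthetic fixture
#'
#' A ready-made synthetic dataset with the shape of a two-survey barn-owl
#' pellet study: surveys labelled 2004 (535 pellets) and 2012 (159
#' pellets), nine subfamily-style micromammal taxa spanning the three
#' feeding guilds (with *Murinae* the dominant omnivore and *Crocidurinae*
#' the dominant insectivore), an omnivore-up / insectivore-down shift in
#' the 2012 survey, and at least one resource category unexploited in the
#' low-effort survey.
#'
#' The counts are synthetic and illustrative only; they are generated from
#' the Dirichlet-multinomial model and are not data from any real survey.
#'
#' @param seed Integer seed (default 1).
#' @return A list with `surveys`, `counts` and `guilds` tibbles, as in
#'   [generate_dataset()].
#' @examples
#' fx <- study_like_fixture()
#' fx$surveys
#' @export
study_like_fixture <- function(seed = 1) {
  taxa <- c("Murinae", "Crocidurinae", "Soricinae", "Talpinae",
            "Erinaceinae", "Arvicolinae", "Leithiinae", "Glirinae",
            "Vespertilioninae")
  guilds <- c("omnivore", "insectivore", "insectivore", "insectivore",
              "insectivore", "herbivore", "omnivore", "omnivore",
              "insectivore")
  weights <- c(30, 25, 10, 3, 2, 6, 3, 2, 1.5)
  for (try in 0:100) {
    cfg <- synthetic_config(
      n_taxa = 9, guilds = guilds, pellets = c(535L, 159L), lambda = 1.3,
      baseline = weights, shift = 0.6, zero_fraction = 0, taxa = taxa,
      survey_ids = c("2004", "2012"), years = c(2004L, 2012L),
      seed = seed + try * 1000L
    )
    ds <- tryCatch(generate_dataset(cfg), error = function(e) NULL)
    if (!is.null(ds) && length(unique(ds$counts$taxon)) == 9) {
      break
    }
  }
  m <- as_count_matrix(ds$counts)
  if (all(m > 0)) {
    # force one unexploited resource category in the low-effort survey
    rare <- which(m[, "2012"] == min(m[, "2012"]))[1]
    m[rare, "2012"] <- 0L
  }
  ds$counts <- counts_from_matrix(m)
  validate_counts(ds$counts)
  ds
}
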