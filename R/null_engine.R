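#' Configuration of the permutation null model
#'
#' @param n_perm Number of null replicates (default 9999).
#' @param variant Randomization variant. `"shuffle_samp"` (default) permutes
#'   the observed non-zero cell values onto a re-drawn occupancy pattern;
#'   `"shuffle_both"` additionally redistributes the grand total of
#'   individuals uniformly over the occupied cells; `"multinomial"` re-draws,
#'   per survey, which taxa are used and splits the survey total uniformly
#'   among them. All variants conserve the grand total of prey individuals
#'   and the per-survey number of unexploited resource categories.
#' @param seed Integer seed for reproducible null distributions, or `NULL`.
#' @param sig_threshold Two-sigma significance threshold on the standardized
#'   effect size (default 1.96, the 5% level).
#' @return A `null_config` list.
#' @export
null_config <- function(n_perm = 9999,
                        variant = c("shuffle_samp", "shuffle_both",
                                    "multinomial"),
                        seed = NULL, sig_threshold = 1.96) {
  variant <- match.arg(variant)
  if (length(n_perm) != 1 || is.na(n_perm) || n_perm < 1 ||
      n_perm != as.integer(n_perm)) {
    abort("n_perm must be a positive integer")
  }
  structure(
    list(n_perm = as.integer(n_perm), variant = variant, seed = seed,
         sig_threshold = sig_threshold),
    class = "null_config"
  )
}

to_count_matrix <- function(x) {
  if (is.matrix(x)) x else as_count_matrix(x)
}

#' Draw a null occupancy pattern
#'
#' Draws a binary matrix uniformly from all matrices sharing the observed
#' incidence margins: the number of used taxa per survey and the number of
#' surveys using each taxon. This retains the consumer's niche breadth and
#' the per-survey count of unexploited resource categories while
#' randomizing which particular categories are used.
#'
#' For two surveys the draw is exact: taxa used in both (or neither) survey
#' are fixed, and the taxa used in exactly one survey are partitioned
#' uniformly at random subject to the two per-survey totals. For more
#' surveys a sequential trial-swap chain of 2x2 checkerboard swaps is used.
#'
#' @param x A count matrix (taxa x surveys), a dense long count table, or a
#'   logical/binary incidence matrix.
#' @param n_swaps Attempted checkerboard swaps for the >2-survey chain.
#' @return A logical incidence matrix with the same dimnames as `x`.
#' @export
sample_incidence <- function(x, n_swaps = 10000) {
  occ <- to_count_matrix(x) > 0
  if (ncol(occ) == 2) {
    sample_incidence_exact2(occ)
  } else {
    sample_incidence_swap(occ, n_swaps)
  }
}

# exact uniform draw for the 2-survey case
sample_incidence_exact2 <- function(occ) {
  singles <- which(rowSums(occ) == 1L)
  if (length(singles) > 1L) {
    n_first <- sum(occ[singles, 1L])
    to_first <- singles[sample.int(length(singles), n_first)]
    occ[singles, 1L] <- singles %in% to_first
    occ[singles, 2L] <- !occ[singles, 1L]
  }
  occ
}

# trial-swap chain: uniform stationary distribution over the margin class
sample_incidence_swap <- function(occ, n_swaps) {
  nr <- nrow(occ)
  nc <- ncol(occ)
  for (i in seq_len(n_swaps)) {
    r <- sample.int(nr, 2L)
    cc <- sample.int(nc, 2L)
    sub <- occ[r, cc]
    if (sub[1L, 1L] == sub[2L, 2L] && sub[1L, 2L] == sub[2L, 1L] &&
        sub[1L, 1L] != sub[1L, 2L]) {
      occ[r, cc] <- !sub
    }
  }
  occ
}

# uniform draw from compositions of `total` into `parts` positive integers
sample_composition <- function(total, parts) {
  if (parts == 1L) {
    return(total)
  }
  cuts <- sort.int(sample.int(total - 1L, parts - 1L))
  diff(c(0L, cuts, total))
}

#' Redistribute prey individuals over a null occupancy pattern
#'
#' The quantitative "shuffle" step: places prey individuals onto the
#' occupied cells of a (typically re-drawn) incidence matrix.
#' `"shuffle_samp"` permutes the multiset of observed non-zero cell counts
#' uniformly onto the occupied cells, conserving the value multiset;
#' `"shuffle_both"` redistributes the grand total uniformly at random over
#' the occupied cells, each receiving at least one individual. Both
#' conserve the grand total of individuals and the number of non-zero
#' cells.
#'
#' @param x A count matrix (taxa x surveys) or dense long count table.
#' @param incidence A logical incidence matrix with as many occupied cells
#'   as `x` has non-zero cells, e.g. from [sample_incidence()].
#' @param variant `"shuffle_samp"` or `"shuffle_both"`.
#' @return An integer count matrix supported exactly on `incidence`.
#' @export
redistribute_quantities <- function(x, incidence,
                                    variant = c("shuffle_samp",
                                                "shuffle_both")) {
  variant <- match.arg(variant)
  m <- to_count_matrix(x)
  occupied <- which(incidence)
  if (length(occupied) != sum(m > 0)) {
    abort(paste0("occupied-cell count mismatch: incidence has ",
                 length(occupied), ", counts have ", sum(m > 0)))
  }
  out <- m
  out[] <- 0L
  if (variant == "shuffle_samp") {
    values <- m[m > 0]
    out[occupied] <- values[sample.int(length(values))]
  } else {
    out[occupied] <- sample_composition(sum(m), length(occupied))
  }
  out
}

#' Draw one null replicate of a count matrix
#'
#' Composes [sample_incidence()] and [redistribute_quantities()] for the
#' shuffle-and-swap variants. The `"multinomial"` variant instead draws,
#' for each survey independently, which of the taxa are used (uniformly,
#' keeping the observed used-taxon count) and splits the survey's total
#' uniformly at random among them, conserving each survey's total exactly.
#'
#' @param x A count matrix (taxa x surveys) or dense long count table.
#' @param config A [null_config()].
#' @return An integer count matrix; a draw from the null model.
#' @export
null_replicate <- function(x, config = null_config()) {
  m <- to_count_matrix(x)
  if (config$variant == "multinomial") {
    out <- m
    out[] <- 0L
    for (j in seq_len(ncol(m))) {
      s_used <- sum(m[, j] > 0)
      if (s_used > 0) {
        support <- sample.int(nrow(m), s_used)
        out[support, j] <- sample_composition(sum(m[, j]), s_used)
      }
    }
    out
  } else {
    redistribute_quantities(m, sample_incidence(m), variant = config$variant)
  }
}

#' Null distribution of a statistic
#'
#' Evaluates a statistic on `n_perm` independent null replicates of the
#' count matrix. Reproducible for a fixed `config$seed`.
#'
#' @param x A count matrix (taxa x surveys) or dense long count table.
#' @param statistic A function taking a count matrix and returning a
#'   numeric scalar.
#' @param config A [null_config()].
#' @return Numeric vector of length `config$n_perm`.
#' @export
null_distribution <- function(x, statistic, config = null_config()) {
  m <- to_count_matrix(x)
  if (!is.null(config$seed)) {
    set.seed(config$seed)
  }
  vapply(seq_len(config$n_perm), function(i) {
    rep_i <- null_replicate(m, config)
    tryCatch(statistic(rep_i), error = function(e) {
      abort(paste0(
        "statistic failed on null replicate ", i, ": ", conditionMessage(e),
        "\nreplicate:\n",
        paste(utils::capture.output(print(rep_i)), collapse = "\n")
      ))
    })
  }, numeric(1))
}

#' Empirical permutation p-value
#'
#' Add-one convention: \eqn{p = (r + 1) / (n + 1)} where \eqn{r} counts
#' null replicates at least as extreme as the observed statistic among the
#' \eqn{n} replicates, so \eqn{p \in [1/(n+1), 1]} and ties count as
#' extreme. The two-sided version measures extremeness as absolute
#' deviation from the null mean, appropriate for the skewed null
#' distributions these randomizations produce.
#'
#' @param t_obs Observed statistic.
#' @param null Numeric vector of null statistics.
#' @param alternative `"two_sided"`, `"left"` or `"right"`.
#' @return Empirical p-value in (0, 1].
#' @export
empirical_p <- function(t_obs,
                        null,
                        alternative = c("two_sided", "left", "right")) {
  alternative <- match.arg(alternative)
  if (length(null) == 0) abort("null distribution is empty")
  n <- length(null)
  r <- switch(alternative,
    left = sum(null <= t_obs),
    right = sum(null >= t_obs),
    two_sided = {
      centre <- mean(null)
      sum(abs(null - centre) >= abs(t_obs - centre))
    }
  )
  (r + 1) / (n + 1)
}

#' Probit standardized effect size
#'
#' Non-parametric standardized effect size for a permutation test with a
#' skewed null: \eqn{SES = s \, |\Phi^{-1}(p/2)|} where \eqn{p} is the
#' empirical p-value, \eqn{\Phi^{-1}} the standard-normal quantile function
#' and \eqn{s} the sign of (observed - null mean). On this scale
#' \eqn{|SES| > 1.96} corresponds exactly to \eqn{p < 0.05}, so the usual
#' two-sigma reading of effect sizes applies regardless of the shape of the
#' null.
#'
#' @param p Empirical p-value in (0, 1].
#' @param direction Sign of (observed statistic - null mean); any numeric,
#'   only its sign is used.
#' @return Signed standardized effect size.
#' @examples
#' probit_ses(0.0459, -1) # -1.996
#' probit_ses(1, 1)       # 0
#' @export
probit_ses <- function(p, direction) {
  if (any(p <= 0 | p > 1)) {
    abort("p must lie in (0, 1]")
  }
  sign(direction) * abs(qnorm(p / 2))
}

#' Paired permutation test of a dietary statistic
#'
#' Evaluates a statistic on the observed count matrix and on `n_perm`
#' shuffle-and-swap null replicates, and summarises the comparison as an
#' empirical p-value and a probit standardized effect size. One call
#' produces one row of a dietary-shift results table.
#'
#' @param x A count matrix (taxa x surveys) or dense long count table.
#' @param statistic Function from a count matrix to a numeric scalar, e.g.
#'   an evenness difference or a guild abundance difference.
#' @param config A [null_config()].
#' @param alternative `"two_sided"` (differences), `"left"` (overlap: is
#'   the observed overlap smaller than expected?) or `"right"`.
#' @param label Feature label for reporting.
#' @return A `perm_test` object with [tidy()], [glance()], [autoplot()] and
#'   print methods. Fields: `feature`, `t_obs`, `null` (the replicate
#'   statistics), `null_mean`, `p`, `ses`, `alternative`, `config`.
#' @export
paired_permutation_test <- function(x, statistic, config = null_config(),
                                    alternative = c("two_sided", "left",
                                                    "right"),
                                    label = "statistic") {
  alternative <- match.arg(alternative)
  m <- to_count_matrix(x)
  t_obs <- statistic(m)
  null <- null_distribution(m, statistic, config)
  null_mean <- mean(null)
  p <- empirical_p(t_obs, null, alternative)
  structure(
    list(feature = label, t_obs = t_obs, null = null, null_mean = null_mean,
         p = p, ses = probit_ses(p, t_obs - null_mean),
         alternative = alternative, config = config),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat("Paired permutation test:", x$feature, "\n")
  cat(sprintf("  observed %.5f, null mean %.5f (%d replicates, %s)\n",
              x$t_obs, x$null_mean, length(x$null), x$config$variant))
  cat(sprintf("  SES %.3f, p %.4f (%s)%s\n", x$ses, x$p, x$alternative,
              if (significance_flag(x$ses, x$config$sig_threshold)) {
                "  *"
              } else {
                ""
              }))
  invisible(x)
}

#' @rdname paired_permutation_test
#' @param x A `perm_test` object.
#' @param ... Unused.
#' @export
tidy.perm_test <- function(x, ...) {
  tibble::tibble(
    feature = x$feature,
    observed = x$t_obs,
    null_mean = x$null_mean,
    ses = x$ses,
    p = x$p,
    alternative = x$alternative,
    significant = significance_flag(x$ses, x$config$sig_threshold)
  )
}

#' @rdname paired_permutation_test
#' @export
glance.perm_test <- function(x, ...) {
  tibble::tibble(
    n_perm = length(x$null),
    variant = x$config$variant,
    seed = x$config$seed %||% NA_integer_,
    sig_threshold = x$config$sig_threshold
  )
}

#' @rdname paired_permutation_test
#' @param object A `perm_test` object.
#' @export
autoplot.perm_test <- function(object, ...) {
  df <- tibble::tibble(stat = object$null)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stat)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$t_obs, colour = "firebrick",
                        linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = object$null_mean, colour = "grey20",
                        linetype = 2) +
    ggplot2::labs(
      x = object$feature,
      y = "null replicates",
      title = sprintf("%s: observed vs. %d null replicates",
                      object$feature, length(object$null)),
      subtitle = sprintf("SES %.3f, p %.4f (%s)", object$ses, object$p,
                         object$alternative)
    ) +
    ggplot2::theme_minimal()
}
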