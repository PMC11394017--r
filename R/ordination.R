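#' Euclidean distances between prey taxa
#'
#' Distances between taxa in the space spanned by the surveys, computed on
#' per-pellet abundances: \eqn{d_{ij} = \sqrt{\sum_s (a_{is} - a_{js})^2}}.
#' With two surveys each taxon is a point in the plane, so these distances
#' are exactly embeddable in two dimensions.
#'
#' @param abund An abundance table from [per_pellet_abundance()] (columns
#'   `survey`, `taxon`, `abundance`).
#' @return A [stats::dist] object over taxa.
#' @export
taxon_distances <- function(abund) {
  wide <- abund |>
    dplyr::select("taxon", "survey", "abundance") |>
    tidyr::pivot_wider(names_from = "survey", values_from = "abundance")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$taxon
  if (nrow(m) < 2) {
    abort("at least 2 taxa are required for a distance matrix")
  }
  dist(m)
}

# Pool-adjacent-violators: least-squares non-decreasing fit, unit weights.
pava <- function(y) {
  n <- length(y)
  if (n <= 1) {
    return(y)
  }
  means <- numeric(n)
  sizes <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    k <- k + 1L
    means[k] <- y[i]
    sizes[k] <- 1L
    while (k > 1L && means[k - 1L] > means[k]) {
      pooled <- means[k - 1L] * sizes[k - 1L] + means[k] * sizes[k]
      sizes[k - 1L] <- sizes[k - 1L] + sizes[k]
      means[k - 1L] <- pooled / sizes[k - 1L]
      k <- k - 1L
    }
  }
  rep.int(means[seq_len(k)], sizes[seq_len(k)])
}

# Monotone regression of configuration distances on the rank order of the
# input dissimilarities; primary approach to ties (tied dissimilarities are
# ordered by current configuration distance, so they do not constrain one
# another).
monotone_fit <- function(d_obs, d_conf) {
  ord <- order(d_obs, d_conf)
  fitted <- numeric(length(d_obs))
  fitted[ord] <- pava(d_conf[ord])
  fitted
}

# Kruskal stress-1 of a configuration-distance vector against its monotone
# fit.
stress1 <- function(d_conf, d_hat) {
  denom <- sum(d_conf^2)
  if (denom == 0) {
    return(0)
  }
  sqrt(sum((d_conf - d_hat)^2) / denom)
}

nmds_stress_at <- function(x, d_obs) {
  d_conf <- as.numeric(dist(x))
  stress1(d_conf, monotone_fit(d_obs, d_conf))
}

# gradient of stress-1 w.r.t. the configuration, d_hat held fixed
nmds_gradient <- function(x, d_obs) {
  n <- nrow(x)
  dm <- as.matrix(dist(x))
  d_conf <- dm[lower.tri(dm)]
  d_hat <- monotone_fit(d_obs, d_conf)
  s_star <- sum((d_conf - d_hat)^2)
  t_star <- sum(d_conf^2)
  s <- if (t_star > 0) sqrt(s_star / t_star) else 0
  if (s == 0 || s_star == 0) {
    return(list(stress = s, grad = matrix(0, n, ncol(x))))
  }
  hm <- matrix(0, n, n)
  hm[lower.tri(hm)] <- d_hat
  hm <- hm + t(hm)
  coef <- (dm - hm) / s_star - dm / t_star
  coef <- ifelse(dm > 0, coef / dm, 0)
  diag(coef) <- 0
  grad <- s * (rowSums(coef) * x - coef %*% x)
  list(stress = s, grad = grad)
}

# one start of the stress minimisation: gradient descent with step halving,
# so the recorded stress trace is non-increasing by construction
nmds_one_start <- function(x, d_obs, max_iter, tol) {
  stress <- nmds_stress_at(x, d_obs)
  trace <- stress
  step <- 0.2
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    if (stress < 1e-12) {
      converged <- TRUE
      break
    }
    g <- nmds_gradient(x, d_obs)$grad
    gnorm <- sqrt(sum(g^2))
    if (gnorm == 0) {
      converged <- TRUE
      break
    }
    scale <- sqrt(sum(x^2)) / gnorm
    improved <- FALSE
    for (h in 1:30) {
      cand <- x - step * scale * g
      cand_stress <- nmds_stress_at(cand, d_obs)
      if (cand_stress < stress) {
        improved <- TRUE
        break
      }
      step <- step / 2
    }
    if (!improved) {
      converged <- TRUE
      break
    }
    if (stress - cand_stress < tol * max(stress, 1e-12)) {
      converged <- TRUE
    }
    x <- cand
    stress <- cand_stress
    trace <- c(trace, stress)
    step <- min(step * 1.5, 1)
    if (converged) {
      break
    }
  }
  list(points = x, stress = stress, trace = trace, converged = converged)
}

#' Non-metric multidimensional scaling with Kruskal stress-1
#'
#' Ordains the items of a dissimilarity matrix in `k` dimensions by
#' minimising Kruskal's stress-1,
#' \eqn{\sqrt{\sum (D_{ij} - \hat d_{ij})^2 / \sum D_{ij}^2}},
#' where \eqn{D} are configuration distances and \eqn{\hat d} is the
#' least-squares monotone (pool-adjacent-violators) regression of \eqn{D}
#' on the rank order of the input dissimilarities (primary approach to
#' ties). Minimisation is by gradient descent with step halving, so stress
#' never increases within a start. One start is initialised from classical
#' metric scaling and the remainder from random configurations; the
#' best-stress solution is returned.
#'
#' @param d A [stats::dist] object or symmetric dissimilarity matrix, e.g.
#'   from [taxon_distances()].
#' @param k Number of ordination dimensions (default 2).
#' @param n_starts Number of starts (default 20).
#' @param max_iter Maximum iterations per start (default 500).
#' @param tol Relative stress-decrease tolerance for convergence.
#' @param seed Optional integer seed for the random starts.
#' @return An `nmds_fit` object with [tidy()] (coordinates), [glance()]
#'   (stress, convergence) and [autoplot()] methods. Fields: `points`
#'   (matrix, items x k), `stress`, `n_starts`, `converged`, `trace` (per-
#'   start non-increasing stress sequences), `metric_start_stress`.
#' @export
nmds <- function(d, k = 2, n_starts = 20, max_iter = 500, tol = 1e-6,
                 seed = NULL) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  labels <- attr(d, "Labels") %||% as.character(seq_len(n))
  if (n < 2) {
    abort("at least 2 items are required")
  }
  d_obs <- as.numeric(d)
  if (any(d_obs < 0) || any(!is.finite(d_obs))) {
    abort("dissimilarities must be finite and non-negative")
  }
  if (!is.null(seed)) {
    set.seed(seed)
  }
  # metric-scaling initialisation, zero-padded if rank-deficient
  x0 <- suppressWarnings(cmdscale(d, k = min(k, n - 1)))
  if (ncol(x0) < k) {
    x0 <- cbind(x0, matrix(0, n, k - ncol(x0)))
  }
  spread <- stats::sd(d_obs)
  if (!is.finite(spread) || spread == 0) {
    spread <- 1
  }
  starts <- c(list(x0), lapply(seq_len(max(0, n_starts - 1)), function(i) {
    matrix(stats::rnorm(n * k, sd = spread), n, k)
  }))
  fits <- lapply(starts, nmds_one_start, d_obs = d_obs,
                 max_iter = max_iter, tol = tol)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "stress"))]]
  points <- best$points
  dimnames(points) <- list(labels, paste0("NMDS", seq_len(k)))
  structure(
    list(points = points, stress = best$stress, n_starts = length(starts),
         converged = best$converged,
         trace = lapply(fits, `[[`, "trace"),
         metric_start_stress = fits[[1]]$trace[1]),
    class = "nmds_fit"
  )
}

#' @export
print.nmds_fit <- function(x, ...) {
  cat(sprintf("NMDS ordination: %d items in %d dimensions\n",
              nrow(x$points), ncol(x$points)))
  cat(sprintf("  stress-1 = %.6g over %d starts (converged: %s)\n",
              x$stress, x$n_starts, x$converged))
  invisible(x)
}

#' @rdname nmds
#' @param x An `nmds_fit` object.
#' @param ... Unused.
#' @export
tidy.nmds_fit <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(taxon = rownames(x$points)),
    tibble::as_tibble(x$points)
  )
}

#' @rdname nmds
#' @export
glance.nmds_fit <- function(x, ...) {
  tibble::tibble(
    stress = x$stress,
    n_starts = x$n_starts,
    converged = x$converged
  )
}

#' @rdname nmds
#' @param object An `nmds_fit` object.
#' @export
autoplot.nmds_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$NMDS1, y = .data$NMDS2,
                                   label = .data$taxon)) +
    ggplot2::geom_point(colour = "grey30") +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = "NMDS ordination of prey taxa",
      subtitle = sprintf("final stress = %.3g", object$stress)
    ) +
    ggplot2::theme_minimal()
}
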