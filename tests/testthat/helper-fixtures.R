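# small in-code fixtures shared across test files

two_surveys <- function() {
  tibble::tibble(survey = c("2004", "2012"), year = c(2004L, 2012L),
                 pellets = c(535L, 159L))
}

# dense long table from a named count matrix (taxa x surveys)
counts_tbl <- function(m) {
  tibble::tibble(
    survey = rep(colnames(m), each = nrow(m)),
    taxon = rep(rownames(m), times = ncol(m)),
    count = as.integer(m)
  )
}

mat <- function(x, taxa, surveys) {
  matrix(as.integer(x), nrow = length(taxa), byrow = TRUE,
         dimnames = list(taxa, surveys))
}

# a small realistic two-survey matrix with one unexploited category each way
demo_matrix <- function() {
  mat(c(120, 30,
        60, 5,
        10, 0,
        0, 8,
        25, 12), c("A", "B", "C", "D", "E"), c("s1", "s2"))
}

write_tmp_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

# independent KL divergence oracle (nats), support checks included
kl_oracle <- function(p, q) {
  on <- p > 0
  if (any(q[on] == 0)) {
    return(Inf)
  }
  sum(p[on] * log(p[on] / q[on]))
}

random_proportions <- function(n) {
  x <- rexp(n)
  x / sum(x)
}

# exhaustive least-squares monotone fit over all contiguous level partitions
exhaustive_monotone <- function(y) {
  n <- length(y)
  best <- NULL
  best_sse <- Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    bounds <- c(0, cuts, n)
    fit <- numeric(n)
    for (b in seq_len(length(bounds) - 1)) {
      idx <- (bounds[b] + 1):bounds[b + 1]
      fit[idx] <- mean(y[idx])
    }
    if (all(diff(fit) >= -1e-12)) {
      sse <- sum((y - fit)^2)
      if (sse < best_sse) {
        best_sse <- sse
        best <- fit
      }
    }
  }
  best
}

# paths a transcription of the published appendix would occupy; shipped data
# must be text, and no faithful transcription of the raw study counts is
# available, so these normally do not exist
study_counts_path <- function() {
  system.file("extdata", "study_appendix_counts.csv", package = "dietshift")
}

study_guilds_path <- function() {
  system.file("extdata", "study_guilds.csv", package = "dietshift")
}
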