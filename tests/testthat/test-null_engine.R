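test_that("null_config validates its fields", {
  expect_error(null_config(n_perm = 0), "positive integer")
  expect_error(null_config(variant = "ra3"), "arg")
  cfg <- null_config(99, "multinomial", seed = 3)
  expect_equal(cfg$n_perm, 99L)
  expect_equal(cfg$sig_threshold, 1.96)
})

test_that("the 2-survey incidence sampler preserves margins exactly", {
  set.seed(5)
  for (i in 1:30) {
    m <- matrix(rpois(12, 2), 6, 2, dimnames = list(paste0("t", 1:6),
                                                    c("a", "b")))
    m[1, ] <- m[1, ] + 1L
    occ <- m > 0
    inc <- sample_incidence(m)
    expect_equal(colSums(inc), colSums(occ))
    expect_equal(rowSums(inc), rowSums(occ))
    # taxa used in both or neither survey stay fixed
    fixed <- rowSums(occ) != 1
    expect_equal(inc[fixed, , drop = FALSE], occ[fixed, , drop = FALSE])
  }
})

test_that("the 2-survey incidence sampler is uniform on an enumerable case", {
  m <- mat(c(1, 0, 0, 1), c("t1", "t2"), c("a", "b"))
  set.seed(17)
  draws <- replicate(10000, sample_incidence(m)["t1", "a"])
  hits <- sum(draws)
  # two feasible matrices, each expected 5000 times
  expect_gt(hits, 5000 - 150)
  expect_lt(hits, 5000 + 150)
})

test_that("incidence sampling is the identity when there is no freedom", {
  m <- mat(c(3, 1, 2, 5), c("t1", "t2"), c("a", "b"))
  expect_equal(sample_incidence(m), m > 0)
})

test_that("the swap-chain sampler preserves both margins for >2 surveys", {
  set.seed(9)
  m <- matrix(rpois(15, 1.5), 5, 3,
              dimnames = list(paste0("t", 1:5), c("a", "b", "c")))
  m[1, ] <- m[1, ] + 1L
  occ <- m > 0
  for (i in 1:5) {
    inc <- sample_incidence(m, n_swaps = 500)
    expect_equal(rowSums(inc), rowSums(occ))
    expect_equal(colSums(inc), colSums(occ))
  }
})

test_that("redistribute_quantities conserves what each variant promises", {
  m <- demo_matrix()
  set.seed(23)
  inc <- sample_incidence(m)
  samp <- redistribute_quantities(m, inc, "shuffle_samp")
  expect_equal(sort(samp[samp > 0]), sort(m[m > 0])) # value multiset
  expect_equal(sum(samp), sum(m))
  expect_equal(unname(samp > 0), unname(inc))

  both <- redistribute_quantities(m, inc, "shuffle_both")
  expect_equal(sum(both), sum(m))
  expect_true(all(both[inc] >= 1))
  expect_equal(sum(both > 0), sum(m > 0))

  bad <- inc
  bad[m == 0] <- TRUE
  expect_error(redistribute_quantities(m, bad, "shuffle_samp"),
               "occupied-cell count mismatch")
})

test_that("shuffle_both reaches every composition of the total", {
  m <- mat(c(3, 0, 0, 1), c("t1", "t2"), c("a", "b")) # total 4, 2 cells
  set.seed(41)
  seen <- character(0)
  for (i in 1:200) {
    r <- redistribute_quantities(m, m > 0, "shuffle_both")
    expect_equal(sum(r), 4L)
    seen <- union(seen, paste(r[r > 0], collapse = "-"))
  }
  expect_setequal(seen, c("1-3", "2-2", "3-1"))
})

test_that("every null variant conserves the stated invariants", {
  m <- demo_matrix()
  unexploited <- colSums(m == 0)
  for (variant in c("shuffle_samp", "shuffle_both", "multinomial")) {
    cfg <- null_config(1, variant, seed = 7)
    set.seed(77)
    for (i in 1:50) {
      r <- null_replicate(m, cfg)
      expect_equal(sum(r), sum(m))
      expect_equal(sum(r > 0), sum(m > 0))
      expect_equal(colSums(r == 0), unexploited)
    }
  }
})

test_that("multinomial conserves survey totals; shuffle_samp does not", {
  m <- demo_matrix()
  set.seed(13)
  for (i in 1:20) {
    r <- null_replicate(m, null_config(1, "multinomial"))
    expect_equal(colSums(r), colSums(m))
  }
  # shuffle_samp lets individuals migrate between surveys
  set.seed(13)
  changed <- FALSE
  for (i in 1:50) {
    r <- null_replicate(m, null_config(1, "shuffle_samp"))
    expect_equal(sum(r), sum(m))
    if (!identical(colSums(r), colSums(m))) changed <- TRUE
  }
  expect_true(changed)
})

test_that("null_distribution is seed-reproducible and surfaces failures", {
  m <- demo_matrix()
  cfg <- null_config(50, "shuffle_samp", seed = 99)
  a <- null_distribution(m, function(x) sum(x[, 1]), cfg)
  b <- null_distribution(m, function(x) sum(x[, 1]), cfg)
  expect_identical(a, b)
  expect_length(a, 50)

  const <- null_distribution(m, function(x) 42, null_config(20, seed = 1))
  expect_equal(var(const), 0)

  expect_error(
    null_distribution(m, function(x) stop("boom"),
                      null_config(5, seed = 1)),
    "statistic failed on null replicate"
  )
})

test_that("empirical_p follows the add-one convention in every tail", {
  null <- c(1, 2, 3, 4)
  expect_equal(empirical_p(4, null, "two_sided"), 3 / 5)
  expect_equal(empirical_p(0, null, "left"), 1 / 5)
  expect_equal(empirical_p(5, null, "right"), 1 / 5)
  expect_equal(empirical_p(2.5, null, "left"), 3 / 5)

  # p is bounded below by 1/(n+1) and monotone in extremeness
  set.seed(55)
  null <- rnorm(200)
  grid <- seq(0, 4, by = 0.25)
  p_left <- vapply(-grid, empirical_p, numeric(1), null = null,
                   alternative = "left")
  p_two <- vapply(grid, empirical_p, numeric(1), null = null,
                  alternative = "two_sided")
  expect_true(all(diff(p_left) <= 0))
  expect_true(all(diff(p_two) <= 0))
  expect_true(all(p_left >= 1 / 201 & p_left <= 1))
})

test_that("probit_ses reproduces the two-sigma scale", {
  expect_equal(probit_ses(1, 1), 0)
  expect_equal(abs(probit_ses(0.05, 1)), 1.960, tolerance = 5e-4)
  expect_equal(probit_ses(0.05, -2), -probit_ses(0.05, 3))
  expect_error(probit_ses(0, 1), "0, 1")
  expect_error(probit_ses(1.2, 1), "0, 1")

  p <- seq(0.001, 1, by = 0.001)
  expect_true(all(diff(probit_ses(p, 1)) < 0)) # strictly decreasing
})

test_that("paired_permutation_test bundles a coherent result", {
  m <- demo_matrix()
  flat <- paired_permutation_test(m, function(x) 1,
                                  null_config(99, seed = 2), "two_sided",
                                  label = "constant")
  expect_equal(flat$p, 1)
  expect_equal(flat$ses, 0)
  expect_false(tidy(flat)$significant)

  tt <- paired_permutation_test(
    m, function(x) pielou_evenness(x[, 2]) - pielou_evenness(x[, 1]),
    null_config(199, "shuffle_samp", seed = 8), "two_sided",
    label = "Prey taxon evenness"
  )
  expect_equal(sign(tt$ses), sign(tt$t_obs - tt$null_mean))
  expect_gte(tt$p, 1 / 200)
  td <- tidy(tt)
  expect_equal(td$feature, "Prey taxon evenness")
  expect_equal(glance(tt)$n_perm, 199L)
  expect_s3_class(autoplot(tt), "ggplot")
})
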