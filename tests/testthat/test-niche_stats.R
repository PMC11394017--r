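test_that("shannon_entropy matches direct evaluation", {
  expect_equal(shannon_entropy(rep(0.25, 4)), log(4))
  expect_equal(shannon_entropy(1), 0)
  expect_equal(shannon_entropy(c(0.5, 0.25, 0.25)), 1.039721, tolerance = 1e-6)
  expect_equal(shannon_entropy(c(0.5, 0.5, 0)), log(2)) # zeros contribute 0
  expect_error(shannon_entropy(c(0.7, 0.7)), "sum to 1")
  expect_error(shannon_entropy(c(1.2, -0.2)), "non-negative")
})

test_that("pielou_evenness is scale-invariant and handles zeros", {
  expect_equal(pielou_evenness(c(10, 10, 10, 10)), 1)
  expect_equal(pielou_evenness(c(2, 1, 1)), 0.946395, tolerance = 1e-6)
  expect_equal(pielou_evenness(c(7, 0, 7)), 1) # zeros excluded from S_used
  expect_error(pielou_evenness(c(5, 0, 0)), "single used taxon")

  set.seed(21)
  for (i in 1:50) {
    x <- rpois(sample(3:10, 1), 5) + 1L
    scale <- sample(2:50, 1)
    expect_equal(pielou_evenness(x * scale), pielou_evenness(x),
                 tolerance = 1e-12)
  }
})

test_that("evenness_difference is later minus earlier", {
  same <- counts_tbl(mat(c(4, 4, 3, 3, 3, 3), paste0("t", 1:3),
                         c("a", "b")))
  expect_equal(evenness_difference(same, "b", "a"), 0)

  # frozen from an independent direct evaluation of J = H / ln(S_used)
  x <- counts_tbl(mat(c(4, 8, 3, 1, 3, 1), paste0("t", 1:3), c("a", "b")))
  expect_equal(evenness_difference(x, "b", "a"),
               0.5816718657 - 0.9911594714, tolerance = 1e-9)
  expect_error(evenness_difference(x, "b", "z"), "unknown survey")
})

test_that("petraitis_overlap equals exp(-KL) with the stated limits", {
  p <- c(0.5, 0.3, 0.2)
  expect_equal(petraitis_overlap(p, p), 1)
  expect_equal(petraitis_overlap(p, p, mode = "a_on_b"), 1)
  expect_equal(petraitis_overlap(c(0.5, 0.5), c(0.25, 0.75), mode = "a_on_b"),
               0.866025, tolerance = 1e-6)
  expect_equal(petraitis_overlap(c(1, 0), c(0, 1)), 0) # complete separation
  expect_error(petraitis_overlap(c(1, 0), c(0.5, 0.25, 0.25)), "length")

  set.seed(31)
  for (i in 1:200) {
    pa <- random_proportions(6)
    pb <- random_proportions(6)
    expect_equal(petraitis_overlap(pa, pb, mode = "a_on_b"),
                 exp(-kl_oracle(pa, pb)), tolerance = 1e-12)
    expect_lt(petraitis_overlap(pa, pb, mode = "a_on_b"), 1)
    # geometric-mean mode is symmetric
    expect_equal(petraitis_overlap(pa, pb), petraitis_overlap(pb, pa),
                 tolerance = 1e-12)
  }
})

test_that("niche_overlap reports the directed pair and their geometric mean", {
  counts <- counts_tbl(mat(c(120, 30,
                             60, 5,
                             0, 8,
                             25, 12), c("A", "B", "D", "E"), c("s1", "s2")))
  all3 <- niche_overlap(counts, "s2", "s1", mode = "all")
  # D is unexploited in s1, so s2-on-s1 hits the separation limit
  expect_equal(all3$later_on_earlier, 0)
  expect_gt(all3$earlier_on_later, 0)
  expect_equal(all3$geometric_mean, 0)
  expect_equal(niche_overlap(counts, "s2", "s1", mode = "a_on_b"),
               all3$later_on_earlier)
})

test_that("guild_abundance_difference works in per-pellet units", {
  counts <- counts_tbl(mat(c(20, 50, 5, 10), c("omnivore", "insectivore"),
                           c("early", "late")))
  surveys <- tibble::tibble(survey = c("early", "late"), year = 1:2,
                            pellets = c(200L, 100L))
  ab <- per_pellet_abundance(counts, surveys)
  expect_equal(guild_abundance_difference(ab, "omnivore", "late", "early"),
               50 / 100 - 20 / 200)
  expect_equal(
    guild_abundance_difference(ab, "insectivore", "early", "early"), 0)
  expect_error(guild_abundance_difference(ab, "granivore", "late", "early"),
               "unknown guild")
})

test_that("relative_abundance_change returns both readings", {
  surveys <- tibble::tibble(survey = c("e", "l"), year = 1:2,
                            pellets = c(100L, 150L))
  counts <- counts_tbl(mat(c(10, 30, 90, 70), c("X", "other"), c("e", "l")))
  out <- relative_abundance_change(counts, surveys, "X", "l", "e")
  expect_equal(out$pp_change_proportion, 20) # 0.10 -> 0.30
  expect_equal(out$pct_change_abundance, 100) # 0.10 -> 0.20 per pellet

  nochange <- counts_tbl(mat(c(10, 10, 90, 90), c("X", "other"),
                             c("e", "l")))
  surveys_eq <- tibble::tibble(survey = c("e", "l"), year = 1:2,
                               pellets = c(100L, 100L))
  out0 <- relative_abundance_change(nochange, surveys_eq, "X", "l", "e")
  expect_equal(out0$pp_change_proportion, 0)
  expect_equal(out0$pct_change_abundance, 0)

  zero <- counts_tbl(mat(c(0, 5, 9, 5), c("X", "other"), c("e", "l")))
  expect_error(relative_abundance_change(zero, surveys_eq, "X", "l", "e"),
               "zero abundance")
})

test_that("diet_diversity summarises each survey", {
  counts <- counts_tbl(demo_matrix())
  d <- diet_diversity(counts)
  expect_equal(d$survey, c("s1", "s2"))
  expect_equal(d$richness_used, c(4L, 4L))
  expect_true(all(d$evenness > 0 & d$evenness <= 1))
})
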