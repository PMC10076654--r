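# Stimulus generator: level pool, profiles, chance draw, rendering,
# curriculum layout.

test_that("level pool has decaying multiplicity and a low mean", {
  pool <- make_level_pool(200L, 5L)
  # enumeration oracle: linear decay rounded to nearest, floored at 1
  mult_expected <- pmax(as.integer(round(5 - 4 * (0:200) / 200)), 1L)
  expect_identical(pool$multiplicity, mult_expected)
  expect_identical(pool$draws, rep(0:200, mult_expected))
  expect_equal(pool$multiplicity[1L], 5L)
  expect_equal(pool$multiplicity[201L], 1L)
  expect_true(all(diff(pool$multiplicity) <= 0L))
  # exact pool mean from the enumerated multiset favours small levels
  expect_equal(mean(pool$draws),
               sum((0:200) * mult_expected) / sum(mult_expected))
  expect_lt(mean(pool$draws), 100)

  # degenerate no-decay pool
  tiny <- make_level_pool(1L, 1L)
  expect_identical(tiny$draws, 0:1)

  expect_error(make_level_pool(0L, 5L), "max_level")
  expect_error(make_level_pool(200L, 0L), "max_repeat")
})

test_that("category profiles are reproducible and match pool frequencies", {
  pool <- make_level_pool()
  set.seed(11); p1 <- make_category_profile(pool)
  set.seed(11); p2 <- make_category_profile(pool)
  expect_identical(p1, p2)
  expect_length(p1, 400L)
  expect_true(all(p1 >= 0 & p1 <= 200))

  set.seed(12); p3 <- make_category_profile(pool)
  expect_false(identical(p1, p3))

  # pooled components against exact pool frequencies
  set.seed(13)
  draws <- as.vector(make_category_profiles(25L, pool)) # 10,000 components
  obs <- tabulate(draws + 1L, nbins = 201L)
  expect_gt(stats::chisq.test(obs, p = pool$multiplicity /
                                sum(pool$multiplicity))$p.value, 1e-3)

  set.seed(14)
  prof <- make_category_profiles(3L, pool, 50L)
  expect_identical(dim(prof), c(3L, 50L))
})

test_that("chance draw matches the enumerated spike probability", {
  # enumeration oracle over all 10,000 equally likely draws
  p_exact <- function(product) mean(product > 1:10000)
  expect_equal(p_exact(10000), 9999 / 10000)
  expect_equal(p_exact(5000), 4999 / 10000)
  expect_equal(p_exact(0), 0)
  # and the general clamp form agrees with the enumeration
  clamp_form <- function(product)
    min(max(ceiling(product) - 1, 0), 10000) / 10000
  for (prod in c(0, 1, 1.5, 37, 4999.2, 5000, 10000))
    expect_equal(p_exact(prod), clamp_form(prod))

  set.seed(21)
  expect_true(all(spike_draw(rep(0, 1000)) == 0L))
  n <- 1e5
  rate <- mean(spike_draw(rep(5000, n)))
  se <- sqrt(0.5 * 0.5 / n)
  expect_lt(abs(rate - 4999 / 10000), 3 * se)
  expect_error(spike_draw(-1), "non-negative")
})

test_that("presentations have the right geometry in both modes", {
  pool <- make_level_pool()
  set.seed(31)
  prof <- make_category_profiles(3L, pool)
  env3 <- make_modulation_envelope(75L)
  env1 <- make_modulation_envelope(25L)

  trip <- render_presentation(prof, env3, labels = c(4L, 9L, 2L))
  expect_identical(dim(trip$spikes), c(600L, 400L))
  expect_identical(trip$labels, c(4L, 9L, 2L))
  # gamma periods are whole and assigned round-robin
  per_period <- matrix(trip$segments, nrow = 8L)
  expect_true(all(apply(per_period, 2, function(x) length(unique(x)) == 1L)))
  expect_identical(per_period[1L, ], rep_len(1:3, 75L))
  expect_identical(tabulate(trip$segments %/% 1L, 3L) / 8L, rep(25, 3))
  expect_identical(trip$seg_labels[1:24],
                   rep(c(4L, 9L, 2L), each = 8L))

  single <- render_presentation(prof[1L, ], env1, labels = 7L)
  expect_identical(dim(single$spikes), c(200L, 400L))
  expect_identical(single$labels, 7L)
  expect_true(all(single$segments == 1L))

  zero <- render_presentation(rep(0L, 400), env1)
  expect_true(all(zero$spikes == 0L))

  expect_error(render_presentation(prof[1:2, ], env3), "1.*or 3")
  expect_error(render_presentation(prof, make_modulation_envelope(25L)),
               "divisible by 3")
  expect_error(make_modulation_envelope(f_hi = 51, max_level = 200L),
               "10,000")
})

test_that("empirical spike rates match the analytic chance probability", {
  # constant-propensity profile: every hi-slot cell has the same exact
  # probability, so pooling all cells gives a tight binomial check
  env <- make_modulation_envelope(75L)
  prop <- 100L
  set.seed(41)
  pres <- render_presentation(matrix(prop, 3L, 400L), env)
  hi <- env$factor == env$f_hi
  p_hi <- (prop * env$f_hi - 1) / 10000
  p_lo <- (prop * env$f_lo - 1) / 10000
  n_hi <- sum(hi) * 400
  n_lo <- sum(!hi) * 400
  expect_lt(abs(mean(pres$spikes[hi, ]) - p_hi),
            3 * sqrt(p_hi * (1 - p_hi) / n_hi))
  expect_lt(abs(mean(pres$spikes[!hi, ]) - p_lo),
            3 * sqrt(p_lo * (1 - p_lo) / n_lo))
})

test_that("triple-mode segments match single-mode marginal statistics", {
  pool <- make_level_pool()
  set.seed(42)
  prof <- make_category_profiles(3L, pool)
  env3 <- make_modulation_envelope(75L)
  env1 <- make_modulation_envelope(25L)
  trip <- render_presentation(prof, env3)
  single <- render_presentation(prof[2L, ], env1)
  # the sub-stream of category 2 has the same analytic per-component rate
  # as a single-mode rendering; compare against the exact expectation
  sub <- trip$spikes[trip$segments == 2L, ]
  p_cell <- outer(env1$factor, as.numeric(prof[2L, ]),
                  function(f, p) pmin(pmax(ceiling(f * p) - 1, 0), 10000)) /
    10000
  expect_lt(abs(mean(sub) - mean(p_cell)), 4 * sqrt(mean(p_cell) / length(sub)))
  expect_lt(abs(mean(single$spikes) - mean(p_cell)),
            4 * sqrt(mean(p_cell) / length(sub)))
})

test_that("curricula lay out the fixed-order phases", {
  cur <- build_curriculum("one")
  expect_equal(nrow(cur), 1200L)
  expect_identical(as.vector(table(cur$phase)[c("cortex_only", "teacher",
                                                "test")]),
                   c(300L, 600L, 300L))
  expect_true(all(tabulate(cur$c1, 30L) == 40L))
  # the cyclic order never changes across epochs
  expect_identical(cur$c1[1:30], cur$c1[31:60])
  expect_identical(cur$c1, ((seq_len(1200L) - 1L) %% 30L) + 1L)
  # triples are consecutive categories of the cycle
  expect_identical(cur$c2, (cur$c1 %% 30L) + 1L)

  cur2 <- build_curriculum("two")
  expect_true(all(cur2$c1[cur2$stage == "train_a"] %in% 1:15))
  expect_true(all(cur2$c1[cur2$stage == "train_b"] %in% 16:30))
  fb <- cur2[cur2$stage == "feedback", ]
  expect_equal(nrow(fb), 300L)
  expect_true(all(tabulate(fb$c1, 30L) == 10L))
  expect_identical(unique(cur2$stage),
                   c("warmup", "train_a", "train_b", "after_split",
                     "feedback", "after_feedback", "relearn",
                     "after_relearn"))

  expect_error(build_curriculum("one", n_test = 0L), "inconsistent")
  expect_error(build_curriculum("two", n_categories = 9L), "even")
})

test_that("rendering is seed-deterministic and instances never repeat", {
  pool <- make_level_pool()
  set.seed(51)
  prof <- make_category_profiles(6L, pool)
  env <- make_modulation_envelope(15L)
  set.seed(52); a <- render_presentation(prof[1:3, ], env)
  set.seed(52); b <- render_presentation(prof[1:3, ], env)
  expect_identical(a, b)
  set.seed(53)
  reps <- replicate(20, render_presentation(prof[1:3, ], env)$spikes,
                    simplify = FALSE)
  for (i in 2:20)
    expect_false(identical(reps[[1L]], reps[[i]]))
})
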