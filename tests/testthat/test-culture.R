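test_that("copy error shifts one unit either way at the stated rate", {
  # no error: identity for all values
  expect_identical(copy_with_error(1:10, error_prob = 0, max_skill = 10), 1:10)
  # certain error: always a one-unit shift (before clamping)
  set.seed(1)
  out <- copy_with_error(rep(5L, 500), error_prob = 1, max_skill = 10)
  expect_true(all(out %in% c(4L, 6L)))
  expect_true(all(c(4L, 6L) %in% out))
  # boundary clamp at 1 and at the skill cap
  expect_true(all(copy_with_error(rep(1L, 200), 1, 10) %in% c(1L, 2L)))
  expect_true(all(copy_with_error(rep(10L, 200), 1, 10) %in% c(9L, 10L)))
  expect_error(copy_with_error(0L), "max_skill")
})

test_that("empirical copy-error frequencies match 5% split evenly", {
  set.seed(123)
  n <- 1e5
  out <- copy_with_error(rep(5L, n), error_prob = 0.05, max_skill = 10)
  freq <- table(factor(out, levels = 4:6)) / n
  # ~5 binomial SDs around 0.025 / 0.95 / 0.025
  expect_lt(abs(freq[["4"]] - 0.025), 5 * sqrt(0.025 * 0.975 / n))
  expect_lt(abs(freq[["6"]] - 0.025), 5 * sqrt(0.025 * 0.975 / n))
  expect_lt(abs(freq[["5"]] - 0.95), 5 * sqrt(0.95 * 0.05 / n))
})

test_that("vertical transmission keeps the prefix rule and samples parents", {
  # child trait count is the shorter parental list
  set.seed(2)
  for (i in 1:20) {
    kid <- vertical_transmission(c(3L, 2L), 4L, error_prob = 0)
    expect_length(kid, 1L)
    expect_true(kid %in% c(3L, 4L))
  }
  # both parents are actually sampled
  kids <- replicate(50, vertical_transmission(c(3L, 2L), 4L, error_prob = 0))
  expect_setequal(unique(kids), c(3L, 4L))
  # identical parents, no error: exact copy
  expect_identical(
    vertical_transmission(c(5L, 5L, 5L), c(5L, 5L, 5L), error_prob = 0),
    c(5L, 5L, 5L)
  )
  # certain error: every value shifts by one
  kid <- vertical_transmission(c(5L, 5L, 5L), c(5L, 5L, 5L), error_prob = 1)
  expect_true(all(kid %in% c(4L, 6L)))
})

test_that("cultural model pool follows group membership and radius", {
  cfg1 <- sim_config(interaction_radius = 1L)
  cfg2 <- sim_config(interaction_radius = 2L)
  groups <- tibble::tibble(id = c(1L, 2L, 3L), col = c(4L, 5L, 9L), row = c(4L, 4L, 9L))
  inds <- tibble::tibble(
    id = 1:5, sex = c(0L, 1L, 0L, 1L, 0L), age = 20L, energy = 40,
    group_id = c(1L, 1L, 2L, 2L, 3L)
  )
  skills <- do.call(rbind, lapply(1:5, function(i) skill_row(i)))
  s1 <- make_test_state(cfg1, groups, inds, skills)
  s2 <- make_test_state(cfg2, groups, inds, skills)
  # radius 1: own group only, learner excluded
  expect_setequal(find_cultural_models(s1, 1)$id, 2)
  # radius 2: group 2 is a Moore neighbour of group 1; group 3 is not
  expect_setequal(find_cultural_models(s2, 1)$id, c(2, 3, 4))
  # isolation: a lone group member has no models at radius 1
  expect_equal(nrow(find_cultural_models(s1, 5)), 0L)
})

test_that("learning prefers acquiring the next trait and pays its cost", {
  cfg <- sim_config(copy_error_prob = 0, learning_cost = 1)
  # acquisition: model holds trait 2 at value 4
  r <- social_learning_event(10L, 30, rbind(skill_row(c(10, 4))), cfg)
  expect_true(r$learned)
  expect_identical(r$skills, c(10L, 4L))
  expect_equal(r$energy, 29) # learning cost deducted
  # improvement: no model holds trait 2, one is better at trait 1
  r <- social_learning_event(3L, 30, rbind(skill_row(2), skill_row(7)), cfg)
  expect_true(r$learned)
  expect_true(r$skills %in% c(2L, 7L)) # copied some holder's value
  # no superior model and nothing to acquire
  r <- social_learning_event(3L, 30, rbind(skill_row(3), skill_row(2)), cfg)
  expect_false(r$learned)
  expect_equal(r$energy, 30)
  # energy at or below the learning cost blocks the event
  r <- social_learning_event(3L, 1, rbind(skill_row(10)), cfg)
  expect_false(r$learned)
  # empty candidate set
  r <- social_learning_event(3L, 30, matrix(integer(), 0, 10), cfg)
  expect_false(r$learned)
})

test_that("improvement copies a sampled holder, not necessarily the best", {
  cfg <- sim_config(copy_error_prob = 0)
  set.seed(5)
  vals <- replicate(200, {
    r <- social_learning_event(
      1L, 30, rbind(skill_row(2), skill_row(9)), cfg
    )
    r$skills[1]
  })
  # both the modest and the expert model get copied
  expect_setequal(sort(unique(vals)), c(2L, 9L))
})

test_that("invention requires mastery, list space and energy above cost", {
  cfg <- sim_config(copy_error_prob = 0)
  r <- attempt_invention(10L, 30, cfg)
  expect_true(r$invented)
  expect_identical(r$skills, c(10L, 1L))
  expect_equal(r$energy, 20)
  # below the skill cap on the last trait: no invention at any energy
  expect_false(attempt_invention(7L, 1000, cfg)$invented)
  expect_false(attempt_invention(c(10L, 9L), 50, cfg)$invented)
  # full trait list
  expect_false(attempt_invention(rep(10L, 10), 50, cfg)$invented)
  # energy must strictly exceed the cost
  expect_false(attempt_invention(10L, 10, cfg)$invented)
  expect_true(attempt_invention(10L, 10.5, cfg)$invented)
})
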