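test_that("partner search enforces sex, age, energy and radius", {
  cfg1 <- sim_config(interaction_radius = 1L)
  cfg2 <- sim_config(interaction_radius = 2L)
  groups <- tibble::tibble(id = c(1L, 2L), col = c(3L, 4L), row = c(3L, 3L))
  inds <- tibble::tibble(
    id = 1:4,
    sex = c(0L, 1L, 1L, 0L),
    age = c(20L, 20L, 25L, 12L),
    energy = c(40, 19, 40, 40),
    group_id = c(1L, 1L, 2L, 2L)
  )
  skills <- do.call(rbind, replicate(4, skill_row(1), simplify = FALSE))
  s1 <- make_test_state(cfg1, groups, inds, skills)
  s2 <- make_test_state(cfg2, groups, inds, skills)
  # only within-group male is below the energy threshold -> none at radius 1
  expect_true(is.na(find_partner(s1, 1)))
  # radius 2 reaches the eligible male on the neighbouring square
  expect_equal(find_partner(s2, 1), 3)
  # already-paired candidates are excluded
  expect_true(is.na(find_partner(s2, 1, exclude = 3)))
  # under-age seeker cannot search
  expect_true(is.na(find_partner(s2, 4)))
})

test_that("reproduction transfers energy and places the child correctly", {
  cfg <- sim_config(copy_error_prob = 0, interaction_radius = 2L)
  groups <- tibble::tibble(id = c(1L, 2L), col = c(3L, 4L), row = c(3L, 3L))
  inds <- tibble::tibble(
    id = 1:2, sex = c(0L, 1L), age = 20L, energy = c(30, 30),
    group_id = c(1L, 2L)
  )
  skills <- rbind(skill_row(c(4, 6)), skill_row(3))
  s <- make_test_state(cfg, groups, inds, skills)
  set.seed(11)
  s2 <- reproduce(s, mother_id = 1, father_id = 2)
  expect_equal(nrow(s2$individuals), 3L)
  child <- s2$individuals[3, ]
  expect_equal(child$age, 0L)
  expect_equal(child$energy, 20) # 2 x birth transfer
  expect_equal(child$group_id, 1L) # born into the mother's group
  expect_equal(s2$individuals$energy[1:2], c(20, 20))
  # child holds min(k_m, k_f) = 1 trait, copied from either parent (no error)
  expect_true(s2$skills[3, 1] %in% c(4L, 3L))
  expect_true(all(s2$skills[3, -1] == 0L))
  expect_error(reproduce(s, mother_id = 2, father_id = 1), "female")
})

test_that("group pressure is the fraction of members with unmet intake", {
  cfg <- sim_config()
  groups <- tibble::tibble(id = 1L, col = 0L, row = 0L)
  inds <- flat_inds(12)
  inds$under_pressure <- c(rep(TRUE, 3), rep(FALSE, 9))
  s <- make_test_state(
    cfg, groups, inds,
    do.call(rbind, replicate(12, skill_row(1), simplify = FALSE))
  )
  gp <- group_pressure(s)
  expect_equal(gp$fraction_unmet, 0.25)
  expect_equal(gp$size, 12L)
  inds$under_pressure <- rep(TRUE, 12)
  s$individuals <- inds
  expect_equal(group_pressure(s)$fraction_unmet, 1)
})

test_that("a large pressured group fissions into two groups on two squares", {
  # resource level 6 feeds one forager per type; 30 juveniles on one square
  # are mostly unmet, no deaths (high energy), no births (under age)
  cfg <- sim_config(resource_level = 6, fission_min_size = 10L)
  groups <- tibble::tibble(id = 1L, col = 5L, row = 5L)
  inds <- flat_inds(30, age = 5L, energy = 49)
  skills <- do.call(rbind, replicate(30, skill_row(1), simplify = FALSE))
  s <- make_test_state(cfg, groups, inds, skills)
  s2 <- sim_step(s, 1L)
  expect_equal(nrow(s2$individuals), 30L) # population conserved
  expect_equal(nrow(s2$groups), 2L)
  expect_equal(as.integer(table(s2$individuals$group_id)), c(15L, 15L))
  # the new group sits on a Moore neighbour of the original square
  expect_true(all(abs(s2$groups$col - 5L) <= 1 & abs(s2$groups$row - 5L) <= 1))
  expect_state_invariants(s2)
})

test_that("a small pressured group migrates whole to a richer empty square", {
  cfg <- sim_config(resource_level = 6, fission_min_size = 10L)
  groups <- tibble::tibble(id = 1L, col = 5L, row = 5L)
  inds <- flat_inds(8, age = 5L, energy = 49)
  skills <- do.call(rbind, replicate(8, skill_row(1), simplify = FALSE))
  s <- make_test_state(cfg, groups, inds, skills)
  s2 <- sim_step(s, 1L)
  expect_equal(nrow(s2$groups), 1L)
  expect_equal(nrow(s2$individuals), 8L)
  # moved: the depleted origin square is abandoned for a full neighbour
  expect_false(s2$groups$col == 5L && s2$groups$row == 5L)
  expect_true(abs(s2$groups$col - 5L) <= 1 && abs(s2$groups$row - 5L) <= 1)
})

test_that("unpressured groups take no spatial action", {
  cfg <- sim_config(resource_level = 500)
  groups <- tibble::tibble(id = 1L, col = 5L, row = 5L)
  inds <- flat_inds(12, age = 5L, energy = 49)
  skills <- do.call(rbind, replicate(12, skill_row(1), simplify = FALSE))
  s <- make_test_state(cfg, groups, inds, skills)
  s2 <- sim_step(s, 1L)
  expect_equal(nrow(s2$groups), 1L)
  expect_equal(s2$groups$col, 5L)
  expect_equal(s2$groups$row, 5L)
})
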