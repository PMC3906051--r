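test_that("an empty world steps without error and only resets resources", {
  cfg <- sim_config()
  s <- make_test_state(
    cfg,
    tibble::tibble(id = integer(), col = integer(), row = integer()),
    tibble::tibble(
      id = numeric(), sex = integer(), age = integer(), energy = numeric(),
      group_id = integer()
    ),
    matrix(integer(), 0, 10)
  )
  s$stocks[3, ] <- 0
  s2 <- sim_step(s, 1L)
  expect_equal(s2$step, 1L)
  expect_equal(nrow(s2$individuals), 0L)
  expect_true(all(s2$stocks == cfg$resource_level))
  expect_true(s2$extinct)
})

test_that("a fixed (config, seed) reproduces the trajectory exactly", {
  cfg <- sim_config(n_steps = 150)
  a <- run_sim(cfg, seed = 5)
  b <- run_sim(cfg, seed = 5)
  expect_identical(a$timeseries, b$timeseries)
  expect_identical(a$events, b$events)
  expect_identical(a$final_state$individuals, b$final_state$individuals)
  expect_identical(a$final_state$skills, b$final_state$skills)
  # different seeds diverge
  d <- run_sim(cfg, seed = 6)
  expect_false(identical(a$timeseries, d$timeseries))
})

test_that("a lone individual's energy follows metabolism plus intake", {
  # one juvenile alone: -5 then +6 per step (satisficing, rate 6) until cap
  cfg <- sim_config(basic_rate = 6)
  groups <- tibble::tibble(id = 1L, col = 2L, row = 2L)
  inds <- flat_inds(1, age = 1L, energy = 10)
  s <- make_test_state(cfg, groups, inds, skill_row(1))
  for (t in 1:5) {
    s <- sim_step(s, 1L)
    expect_equal(s$individuals$energy, 10 + t)
    expect_equal(s$individuals$age, 1L + t)
  }
  expect_equal(nrow(s$individuals), 1L)
})

test_that("a zero-length run reports the initial state as end values", {
  cfg <- sim_config()
  r <- run_sim(cfg, seed = 3, n_steps = 0)
  expect_equal(r$end_values$step, 0L)
  expect_equal(r$end_values$population, 20L)
  expect_equal(r$end_values$mean_traits, 1)
  expect_equal(r$end_values$n_groups, 1L)
  expect_false(r$extinct)
})

test_that("structural invariants hold along a whole trajectory", {
  cfg <- sim_config(resource_level = 50, selection_differential = 0.5,
                    interaction_radius = 2L)
  for (k in c(5L, 25L, 60L, 120L)) {
    s <- run_sim(cfg, seed = 9, n_steps = k)$final_state
    expect_state_invariants(s)
    # population equals the sum of group sizes
    expect_equal(
      nrow(s$individuals),
      sum(table(factor(s$individuals$group_id, levels = s$groups$id)))
    )
  }
})

test_that("replicates are independent, ordered and reproducible", {
  cfg <- sim_config(n_steps = 60)
  e1 <- run_replicates(cfg, base_seed = 100, n_runs = 3)
  expect_length(e1$runs, 3L)
  expect_equal(e1$end_values$seed, c(100L, 101L, 102L))
  e2 <- run_replicates(cfg, base_seed = 100, n_runs = 3)
  expect_identical(e1$end_values, e2$end_values)
  # a replicate rerun on its own reproduces its row
  solo <- run_sim(cfg, seed = 101)
  expect_equal(glance(solo), e1$end_values[2, ])
})

test_that("tidy/glance/autoplot expose run results in tabular form", {
  cfg <- sim_config(n_steps = 40)
  r <- run_sim(cfg, seed = 2)
  expect_identical(tidy(r), r$timeseries)
  g <- glance(r)
  expect_equal(nrow(g), 1L)
  expect_true(all(c("population", "mean_traits", "competition") %in% names(g)))
  p <- autoplot(r)
  expect_s3_class(p, "ggplot")
  e <- run_replicates(cfg, base_seed = 1, n_runs = 2)
  tt <- tidy(e)
  expect_equal(unique(tt$run), c(1L, 2L))
  expect_s3_class(autoplot(e), "ggplot")
})

test_that("run artifacts are written in the documented formats", {
  cfg <- sim_config(n_steps = 30)
  r <- run_sim(cfg, seed = 4)
  d <- withr::local_tempdir()
  write_run(r, d)
  expect_true(file.exists(file.path(d, "timeseries.csv")))
  ts <- readr::read_csv(file.path(d, "timeseries.csv"), show_col_types = FALSE)
  expect_equal(nrow(ts), nrow(r$timeseries))
  ev <- jsonlite::read_json(file.path(d, "end_values.json"))
  expect_equal(ev$seed, 4L)
  cfg_back <- load_config(file.path(d, "config.resolved.json"))
  expect_equal(unclass(cfg_back), unclass(cfg))
})
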