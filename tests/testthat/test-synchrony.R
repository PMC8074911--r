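test_that("chordal distance matches its closed form", {
  expect_identical(chordal_distance(0, pi), 2)
  expect_equal(chordal_distance(0, 0.01), 2 * sin(0.005))
  expect_identical(chordal_distance(1.2, 1.2), 0)
  # symmetry, 2*pi periodicity, vectorization
  a <- withr::with_seed(1, stats::runif(20, 0, 2 * pi))
  b <- withr::with_seed(2, stats::runif(20, 0, 2 * pi))
  expect_equal(chordal_distance(a, b), chordal_distance(b, a))
  expect_equal(chordal_distance(a + 2 * pi, b), chordal_distance(a, b))
  expect_equal(chordal_distance(a, b), 2 * abs(sin((a - b) / 2)))
  expect_true(all(chordal_distance(a, b) >= 0 & chordal_distance(a, b) <= 2))
})

test_that("synchrony_graph thresholds pairs by chord length", {
  rel <- synchrony_graph(c(0, 0.009, 0.018, 3))
  expect_true(rel[1, 2] && rel[2, 3])
  expect_false(rel[1, 3]) # 0.018 apart: chord just over C = 0.01
  expect_false(any(rel[, 4]))
  expect_identical(rel, t(rel))
  expect_false(any(diag(rel)))
  # threshold is strict and settable
  wide <- synchrony_graph(c(0, 0.018), synchrony_criterion(C = 0.05))
  expect_true(wide[1, 2])
})

test_that("groups are connected components, chaining included", {
  part <- groups_from_run(fake_traj(c(0, 0.009, 0.018, 3)))
  expect_identical(part$groups, list(1:3))
  expect_identical(part$chimerics, 4L)
  # chimeric-only state
  none <- groups_from_run(fake_traj(c(0, 1, 2)))
  expect_identical(none$groups, list())
  expect_identical(none$chimerics, 1:3)
})

test_that("a partition covers the oscillators exactly once", {
  for (seed in 1:10) {
    theta <- withr::with_seed(seed, stats::runif(12, 0, 0.05))
    part <- groups_from_run(fake_traj(theta))
    members <- c(unlist(part$groups), part$chimerics)
    expect_identical(sort(members), 1:12)
    expect_true(all(vapply(part$groups, length, integer(1)) >= 2))
  }
})

test_that("partition_from_pair_counts applies the persistence threshold", {
  counts <- matrix(0L, 3, 3)
  counts[1, 2] <- counts[2, 1] <- 19L
  counts[2, 3] <- counts[3, 2] <- 18L
  strict <- partition_from_pair_counts(counts, 19)
  expect_identical(strict$groups, list(1:2))
  expect_identical(strict$chimerics, 3L)
  # one co-occurrence fewer required: the relation chains 1-2-3
  loose <- partition_from_pair_counts(counts, 18)
  expect_identical(loose$groups, list(1:3))
  expect_identical(loose$chimerics, integer(0))
})

test_that("a single replicate reduces to one classified run", {
  net <- coffee_fixture()$network
  cfg <- sim_config(K = 0.8, t_end = 20, seed = 31)
  part <- persistent_groups(net, cfg, persistence_config(1, 1))
  rcfg <- cfg
  rcfg$seed <- ecosync:::derive_seed(cfg$seed, 0, 1)
  single <- groups_from_run(integrate_kuramoto(net, rcfg))
  expect_identical(part$groups, single$groups)
  expect_identical(part$chimerics, single$chimerics)
})

test_that("persistent_groups is deterministic and demands a master seed", {
  net <- derive_coupling(generate_web(web_spec(2, c(3, 3), 1, 0, seed = 5)))
  cfg <- sim_config(K = 1, t_end = 10, seed = 8)
  a <- persistent_groups(net, cfg, persistence_config(5, 4))
  b <- persistent_groups(net, cfg, persistence_config(5, 4))
  expect_identical(a$groups, b$groups)
  expect_identical(a$pair_counts, b$pair_counts)
  expect_length(a$replicate_order_parameters, 5)
  expect_error(persistent_groups(net, sim_config(seed = NULL)), "seed")
})

test_that("count_in_synchrony counts the largest cluster in a subset", {
  traj <- fake_traj(c(0, 0.005, 1, 2, 3))
  expect_identical(count_in_synchrony(traj, 1:5), 2L)
  expect_identical(count_in_synchrony(traj, 3:5), 1L)
  expect_identical(count_in_synchrony(traj, 1:2), 2L)
  expect_error(count_in_synchrony(traj, c(1, 99)), "unknown")
})

test_that("tidy/glance/write_partition expose the partition faithfully", {
  part <- groups_from_run(fake_traj(c(0, 0.001, 1, 1.001, 2)))
  td <- tidy(part)
  expect_identical(td$group_id, c(1L, 1L, 2L, 2L, 0L))
  g <- glance(part)
  expect_identical(g$n_groups, 2L)
  expect_identical(g$n_chimeric, 1L)
  expect_identical(g$largest_group, 2L)

  json <- withr::local_tempfile(fileext = ".json")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_partition(part, json = json, csv = csv)
  payload <- jsonlite::read_json(json)
  expect_identical(lapply(payload$groups, function(g) as.integer(unlist(g))),
                   list(c(1L, 2L), c(3L, 4L)))
  expect_identical(as.integer(unlist(payload$chimerics)), 5L)
  expect_identical(
    as.integer(readr::read_csv(csv, show_col_types = FALSE)$group_id),
    td$group_id)
})

test_that("criterion and persistence settings are validated", {
  expect_error(synchrony_criterion(C = 0), "C > 0")
  expect_error(persistence_config(20, 21))
  expect_error(persistence_config(0, 0))
})
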