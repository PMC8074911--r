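test_that("foodweb() validates its edge list", {
  w <- foodweb(data.frame(oscillator_id = 1:2,
                          consumer = c("A", "B"), resource = c("B", "C")))
  expect_s3_class(w, "foodweb")
  expect_identical(w$species, c("A", "B", "C"))
  expect_identical(nrow(w$links), 2L)

  expect_error(foodweb(data.frame(oscillator_id = 1, consumer = "A")),
               "missing column")
  expect_error(foodweb(data.frame(oscillator_id = c(1, 1),
                                  consumer = c("A", "B"),
                                  resource = c("B", "C"))),
               "duplicate oscillator_id")
  expect_error(foodweb(data.frame(oscillator_id = 1:2,
                                  consumer = c("A", "B"),
                                  resource = c("A", "C"))),
               "self-consumption")
  expect_error(foodweb(data.frame(oscillator_id = c(1, 3),
                                  consumer = c("A", "B"),
                                  resource = c("B", "C"))),
               "contiguous")
})

test_that("read_foodweb reads a CSV and rejects missing files", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("oscillator_id,consumer,resource",
               "1,wasp,borer", "2,ant,borer"), path)
  w <- read_foodweb(path)
  expect_identical(nrow(w$links), 2L)
  expect_identical(w$links$consumer, c("wasp", "ant"))
  expect_error(read_foodweb(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("food webs round-trip through write/read", {
  w <- generate_web(web_spec(n_guilds = 2, enemies_per_guild = c(3, 4),
                             n_bridges = 1, n_cut_links = 0, seed = 11))
  path <- withr::local_tempfile(fileext = ".csv")
  write_foodweb(w, path)
  expect_identical(read_foodweb(path)$links, w$links)
})

test_that("derive_coupling captures each way of sharing a species", {
  # chain A->B, B->C: shared species B (consumer of one, resource of other)
  chain <- foodweb(data.frame(oscillator_id = 1:2,
                              consumer = c("A", "B"), resource = c("B", "C")))
  expect_identical(unname(derive_coupling(chain)$gamma[1, 2]), 1)
  # shared resource: two enemies on one pest
  shared_res <- foodweb(data.frame(oscillator_id = 1:2,
                                   consumer = c("A", "B"),
                                   resource = c("P", "P")))
  expect_identical(unname(derive_coupling(shared_res)$gamma[1, 2]), 1)
  # shared consumer: one enemy on two pests
  shared_con <- foodweb(data.frame(oscillator_id = 1:2,
                                   consumer = c("A", "A"),
                                   resource = c("P", "Q")))
  expect_identical(unname(derive_coupling(shared_con)$gamma[1, 2]), 1)
  # disjoint links are uncoupled
  disjoint <- foodweb(data.frame(oscillator_id = 1:2,
                                 consumer = c("A", "C"),
                                 resource = c("B", "D")))
  expect_identical(unname(derive_coupling(disjoint)$gamma[1, 2]), 0)
})

test_that("derive_coupling equals brute-force endpoint sharing", {
  for (seed in 1:40) {
    web <- random_web(seed)
    got <- derive_coupling(web)$gamma
    expect_identical(unname(got), unname(brute_coupling(web)),
                     info = paste("seed", seed))
    expect_identical(got, t(got))
    expect_true(all(diag(got) == 0))
  }
})

test_that("oscillator_network validates its matrix", {
  expect_error(oscillator_network(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")
  expect_error(oscillator_network(matrix(c(1, 1, 1, 1), 2, 2)), "diagonal")
  expect_error(oscillator_network(matrix(c(0, -1, -1, 0), 2, 2)),
               "non-negative")
})

test_that("scale_oscillator_coupling composes and isolates", {
  net <- coffee_fixture()$network
  expect_identical(scale_oscillator_coupling(net, 22, 1)$gamma, net$gamma)
  ab <- scale_oscillator_coupling(scale_oscillator_coupling(net, 22, 0.5),
                                  22, 0.2)
  expect_equal(ab$gamma, scale_oscillator_coupling(net, 22, 0.1)$gamma)
  iso <- scale_oscillator_coupling(net, 22, 0)
  expect_true(all(iso$gamma["22", ] == 0))
  expect_true(all(iso$gamma[, "22"] == 0))
  keep <- setdiff(as.character(1:22), "22")
  expect_identical(iso$gamma[keep, keep], net$gamma[keep, keep])
  expect_error(scale_oscillator_coupling(net, 99, 0.1), "unknown")
})

test_that("extract_subnetwork induces the right submatrix", {
  net <- coffee_fixture()$network
  expect_identical(extract_subnetwork(net, 1:22)$gamma, net$gamma)
  sub <- extract_subnetwork(net, 17:21)
  expect_identical(sub$n, 5L)
  expect_identical(sub$labels, 17:21)
  expect_true(all(sub$gamma[upper.tri(sub$gamma)] == 1))
  expect_error(extract_subnetwork(net, c(1, 99)), "unknown")
})

test_that("coupling matrices round-trip through TSV bit-exactly", {
  net <- scale_oscillator_coupling(coffee_fixture()$network, 22, 0.1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_coupling_matrix(net, path)
  back <- read_coupling_matrix(path)
  expect_identical(back$gamma, net$gamma)
  expect_identical(back$labels, net$labels)
})

test_that("check_constraints reports per-constraint passes without mutation", {
  fx <- coffee_fixture()
  before <- fx$network$gamma
  report <- check_constraints(fx$network, fx$constraints)
  expect_identical(fx$network$gamma, before)
  expect_true(all(report$pass))
  expect_identical(nrow(report), length(fx$constraints))

  # a corrupted network is caught: add the forbidden 8-5 coupling
  bad <- fx$network
  bad$gamma["8", "5"] <- bad$gamma["5", "8"] <- 1
  report2 <- check_constraints(bad, fx$constraints)
  expect_false(all(report2$pass))
  expect_error(
    check_constraints(fx$network, list(structural_constraint(
      "edge_present", edge = c(1L, 99L)))),
    "absent from the network")
})
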