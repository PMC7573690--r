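# Synthetic proteome and network generators.

test_that("proteome generator honors counts, seeds and the empty case", {
  expect_equal(nrow(generate_proteome(proteome_sim_params(0))), 0L)
  expect_error(proteome_sim_params(-5), class = "homomer_invalid_parameter")
  expect_error(proteome_sim_params(10, known_fraction = 1.2),
               class = "homomer_invalid_parameter")
  expect_error(proteome_sim_params(10, odd_suppression = -0.1),
               class = "homomer_invalid_parameter")
  expect_error(proteome_sim_params(10, k_support = c(3, 2)),
               class = "homomer_invalid_parameter")

  p <- proteome_sim_params(500, seed = 7)
  expect_identical(generate_proteome(p), generate_proteome(p))
  rec <- generate_proteome(p)
  expect_equal(nrow(rec), 500L)
  expect_true(all(rec$length_aa >= 1))
})

test_that("even-only proteome matches exact multinomial proportions", {
  p <- proteome_sim_params(50000, known_fraction = 1, odd_suppression = 0,
                           monomer_weight = 0, k_support = c(2, 4, 6, 8),
                           seed = 31)
  rec <- generate_proteome(p)
  f2 <- mean(rec$oligomer_k == 2)
  # oracle: exact multinomial proportion 0.5/0.875 = 4/7 with binomial SE
  p2 <- 4 / 7
  se <- sqrt(p2 * (1 - p2) / 50000)
  expect_lt(abs(f2 - p2), 3 * se)
})

test_that("full-support empirical frequencies converge to the model weights", {
  p <- proteome_sim_params(100000, known_fraction = 1, odd_suppression = 1,
                           seed = 13)
  rec <- generate_proteome(p)
  emp <- table(rec$oligomer_k) / nrow(rec)
  k <- 1:12
  w <- k / 2^k  # rho = 1 and monomer_weight = 0.5 reproduce k/2^k everywhere
  model <- stats::setNames(w / sum(w), k)
  expect_lt(tv_distance(as.vector(emp) |> stats::setNames(names(emp)), model),
            0.02)
})

test_that("degree sequences respect the cutoff, parity and seeds", {
  expect_error(network_sim_params(100, gamma = 1),
               class = "homomer_invalid_parameter")
  p <- network_sim_params(10000, gamma = 2.5, k_min = 5, head_mean = 0,
                          seed = 5)
  d <- generate_degree_sequence(p)
  expect_equal(min(d), 5L)
  expect_equal(sum(d) %% 2, 0)
  expect_identical(d, generate_degree_sequence(p))
})

test_that("pure power-law tail mean matches the zeta-ratio oracle", {
  p <- network_sim_params(10000, gamma = 3, k_min = 1, head_mean = 0,
                          k_max = 10000, seed = 17)
  d <- generate_degree_sequence(p)
  kk <- 1:10000
  w <- kk^(-3) / sum(kk^(-3))
  mu <- sum(kk * w)            # ~ zeta(2)/zeta(3) = 1.3684 minus truncation
  sdev <- sqrt(sum(kk^2 * w) - mu^2)
  expect_lt(abs(mean(d) - mu), 3 * sdev / sqrt(10000) + 2e-4)
  expect_equal(mu, 1.3684, tolerance = 1e-3)
})

test_that("stub matching realizes tiny degree sequences exactly", {
  g <- realize_edges(c(1, 1), seed = 1)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(length(g$nodes), 2L)

  tri <- realize_edges(c(2, 2, 2), seed = 2)
  expect_equal(nrow(tri$edges), 3L)  # the unique simple realization

  expect_error(realize_edges(c(1, 1, 1)),
               class = "homomer_invalid_parameter")
})

test_that("realized graphs are simple and preserve degrees when nothing is discarded", {
  for (s in 1:5) {
    d <- generate_degree_sequence(network_sim_params(300, gamma = 2.5,
                                                     k_min = 3, seed = s))
    g <- suppressWarnings(realize_edges(d, seed = s + 100))
    expect_true(all(g$edges[, 1] != g$edges[, 2]))
    expect_false(anyDuplicated(paste(g$edges[, 1], g$edges[, 2])) > 0)
    if (g$discarded_stubs == 0) {
      deg <- stats::setNames(rep(0L, length(d)), g$nodes)
      tab <- table(c(g$edges[, 1], g$edges[, 2]))
      deg[names(tab)] <- as.integer(tab)
      expect_equal(sort(unname(deg)), sort(as.integer(d)))
    }
  }
})

test_that("category assignment follows the weights", {
  rec <- make_records(rep(c(1, 2, 4), length.out = 20000))
  one <- assign_categories(rec, c(metabolic = 1), seed = 3)
  expect_true(all(one$go_terms == "metabolic"))

  two <- assign_categories(rec, c(a = 1, b = 1), seed = 4)
  pa <- mean(two$go_terms == "a")
  se <- sqrt(0.25 / 20000)
  expect_lt(abs(pa - 0.5), 3 * se)
  expect_identical(two, assign_categories(rec, c(a = 1, b = 1), seed = 4))

  expect_error(assign_categories(rec, numeric(0)),
               class = "homomer_invalid_parameter")
  expect_error(assign_categories(rec, c(a = 0, b = 0)),
               class = "homomer_invalid_parameter")
})

test_that("simulation writer produces readable TSVs and a JSON sidecar", {
  dir <- withr::local_tempdir()
  p <- proteome_sim_params(50, seed = 8)
  rec <- generate_proteome(p)
  np <- network_sim_params(30, k_min = 2, seed = 9)
  g <- suppressWarnings(realize_edges(generate_degree_sequence(np), seed = 10))
  files <- write_simulation(file.path(dir, "sim"), records = rec, graph = g,
                            params = list(proteome = p, network = np))
  expect_true(all(file.exists(file.path(dir, c("sim.proteome.tsv",
                                               "sim.edges.tsv",
                                               "sim.params.json")))))
  back <- read_proteome_table(file.path(dir, "sim.proteome.tsv"))
  expect_equal(nrow(back), 50L)
  side <- jsonlite::read_json(file.path(dir, "sim.params.json"))
  expect_equal(side$proteome$seed, 8L)
})
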