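test_that("simulation is byte-identical under a fixed seed and leaves the RNG alone", {
  cfg <- simulation_config(seed = 5)
  sim1 <- simulate_registry(cfg)
  sim2 <- simulate_registry(cfg)
  expect_identical(sim1, sim2)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_registry(sim1$registry, f1)
  write_registry(sim2$registry, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(simulate_registry(cfg))
  expect_identical(rnorm(1), before)

  sim3 <- simulate_registry(simulation_config(seed = 6))
  expect_false(identical(sim1$registry, sim3$registry))
})

test_that("simulated registries are bit-compatible with the registry reader", {
  sim <- simulate_registry(simulation_config(seed = 3))
  f <- withr::local_tempfile(fileext = ".csv")
  write_registry(sim$registry, f)
  reg <- suppressMessages(load_registry(f))
  expect_equal(nrow(reg), nrow(sim$registry))
  expect_equal(reg$dog_id, sim$registry$dog_id)
  expect_equal(reg$distichiasis, sim$registry$distichiasis)
  dogs <- resolve_dogs(reg)
  expect_equal(sum(dogs$status == "affected"), sum(sim$registry$distichiasis))
})

test_that("default conditions emulate the target cohort: size, prevalence, mix, female excess", {
  sim <- simulate_registry(simulation_config(seed = 1))
  dogs <- resolve_dogs(sim$registry)
  expect_gt(nrow(dogs), 600); expect_lt(nrow(dogs), 1000)
  p <- prevalence(dogs)
  expect_gt(p$proportion, 0.40); expect_lt(p$proportion, 0.60)
  trio <- suppressMessages(build_trio_cohort(dogs))
  expect_gt(nrow(trio$members), 400)
  mix <- table(trio$members$mating_class) / nrow(trio$members)
  expect_equal(unname(mix[["one_affected"]]), 0.417, tolerance = 0.15)
  # grading mild-heavy
  g <- table(dogs$grade[dogs$status == "affected"])
  expect_gt(g[["mild"]], g[["moderate"]])
})

test_that("prevalence converges to target and the sex offset drives a female excess", {
  cfg <- simulation_config(seed = 21, n_parents = 20000, n_matings = 8000,
                           litter_size_mean = 5, sex_threshold_offset = 0.3,
                           certificate_missing_prob = 0)
  sim <- simulate_registry(cfg)
  off <- sim$truth[sim$truth$role == "offspring", ]
  n <- nrow(off)
  p_hat <- mean(off$affected)
  # offspring of the configured mating mix keep prevalence near target
  expect_equal(p_hat, cfg$prevalence_target, tolerance = 0.05)
  pf <- mean(off$affected[off$sex == "female"])
  pm <- mean(off$affected[off$sex == "male"])
  expect_gt(pf, pm)

  # population-level check on the unselected parental pools
  cfg0 <- simulation_config(seed = 22, n_parents = 30000, n_matings = 10,
                            sex_threshold_offset = 0,
                            include_unused_parents = TRUE,
                            certificate_missing_prob = 0)
  sim0 <- simulate_registry(cfg0)
  founders <- sim0$truth[sim0$truth$role != "offspring", ]
  p0 <- mean(founders$affected)
  se <- sqrt(cfg0$prevalence_target * (1 - cfg0$prevalence_target) / nrow(founders))
  expect_lt(abs(p0 - cfg0$prevalence_target), 3 * se)

  # no sex offset: no significant sex association among offspring
  cfg_ns <- simulation_config(seed = 23, n_parents = 5000, n_matings = 2000,
                              litter_size_mean = 5, sex_threshold_offset = 0,
                              certificate_missing_prob = 0)
  dogs_ns <- resolve_dogs(simulate_registry(cfg_ns)$registry)
  expect_gt(sex_association(dogs_ns)$p_value, 0.01)
})

test_that("offspring liability variance stays near one under a random-mating mix", {
  prev <- 0.49
  mix <- c(prev^2, 2 * prev * (1 - prev), (1 - prev)^2)
  mix <- mix / sum(mix)
  cfg <- simulation_config(seed = 31, h2_true = 0.5, prevalence_target = prev,
                           n_parents = 40000, n_matings = 20000,
                           mating_mix = mix, litter_size_mean = 5,
                           sex_threshold_offset = 0,
                           certificate_missing_prob = 0)
  sim <- simulate_registry(cfg)
  off <- sim$truth[sim$truth$role == "offspring", ]
  expect_gt(nrow(off), 1e5 - 5e3)
  expect_equal(stats::var(off$liability), 1, tolerance = 0.02)
  # Mendelian + environmental decomposition: breeding values carry ~h2 of it
  expect_equal(stats::var(off$breeding_value), cfg$h2_true, tolerance = 0.05)
})

test_that("class incidences match the closed-form oracle; h2 = 0 removes the parental association", {
  expect_equal(expected_offspring_incidence(0, 0.37, "both_affected"), 0.37)
  expect_gt(expected_offspring_incidence(1, 0.5, "both_affected"), 0.5)
  expect_error(expected_offspring_incidence(0.5, 1.5, "both_affected"))

  run_classes <- function(h2, seed, n_matings = 9000) {
    cfg <- simulation_config(seed = seed, h2_true = h2, prevalence_target = 0.49,
                             n_parents = 20000, n_matings = n_matings,
                             mating_mix = c(1, 1, 1) / 3, litter_size_mean = 5,
                             sex_threshold_offset = 0,
                             certificate_missing_prob = 0)
    sim <- simulate_registry(cfg)
    off <- sim$truth[sim$truth$role == "offspring", ]
    sapply(split(off$affected, off$mating_class), function(x) c(p = mean(x), n = length(x)))
  }

  for (h2 in c(0, 0.5)) {
    obs <- run_classes(h2, seed = 40 + round(10 * h2))
    for (cl in colnames(obs)) {
      p_exp <- expected_offspring_incidence(h2, 0.49, cl)
      se <- sqrt(p_exp * (1 - p_exp) / obs["n", cl])
      expect_lt(abs(obs["p", cl] - p_exp), 3 * se)
    }
    if (h2 == 0) {
      # no inheritance: equal incidence across classes within Monte-Carlo noise
      spread <- diff(range(obs["p", ]))
      expect_lt(spread, 6 * sqrt(0.25 / min(obs["n", ])))
    }
  }
})

test_that("mating mix is enforced by rejection, erroring when a pool is empty", {
  cfg <- simulation_config(seed = 2, prevalence_target = 0.02, n_parents = 20,
                           n_matings = 30,
                           mating_mix = c(both_affected = 1, one_affected = 0,
                                          neither_affected = 0))
  expect_error(simulate_registry(cfg), "n_parents")
})

test_that("grading follows the cilia-count boundaries with the secondary-change override", {
  expect_equal(assign_grading(3), "mild")
  expect_equal(assign_grading(5), "mild")
  expect_equal(assign_grading(6), "moderate")
  expect_equal(assign_grading(10), "moderate")
  expect_equal(assign_grading(11), "severe")
  expect_equal(assign_grading(12), "severe")
  expect_equal(assign_grading(2, secondary_changes = TRUE), "moderate")
  expect_equal(assign_grading(12, secondary_changes = TRUE), "severe")
  expect_equal(assign_grading(c(1, 7, 15), c(FALSE, FALSE, FALSE)),
               c("mild", "moderate", "severe"))
  expect_error(assign_grading(0), "positive")
})

test_that("reference registries reproduce the published margins end to end", {
  fx <- fixture_bundle()
  expect_equal(nrow(fx$registry), 799L)
  expect_equal(prevalence(fx$dogs)$percent, 49.31)
  g <- table(fx$dogs$grade[fx$dogs$status == "affected"])
  expect_equal(as.integer(g[c("mild", "moderate", "severe")]), c(116L, 15L, 4L))
  expect_equal(sum(fx$dogs$other_diagnosis[fx$dogs$status == "affected"]), 25L)
  expect_equal(sum(fx$dogs$other_diagnosis[fx$dogs$status == "unaffected"]), 32L)
  expect_identical(reference_registry(), fx$registry)
})
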