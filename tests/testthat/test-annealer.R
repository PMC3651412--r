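make_instance <- function(seed, n = 20, m = 4, d = 3) {
  coh <- generate_cohort(n, m, 0.5, seed = seed)
  resp <- generate_iid_responses(n, d, seed = seed + 100L)
  list(cohort = coh, responses = resp)
}

test_that("energy is minus cohort size times the overall response rate", {
  inst <- make_instance(1)
  empty <- replicate(3, drug_protocol(), simplify = FALSE)
  expect_equal(assignment_energy(inst$cohort, inst$responses, empty, c = 1,
                                 min_group_size = 1), 0)
  set.seed(5)
  for (rep in 1:5) {
    prots <- random_protocols(4, 3, k_max = 2)
    ev <- evaluate_assignment(inst$cohort, inst$responses, prots, 2,
                              min_group_size = 1)
    expect_equal(assignment_energy(inst$cohort, inst$responses, prots, 2,
                                   min_group_size = 1), -20 * ev$O)
  }
})

test_that("Metropolis rule accepts improvements surely and worsenings at exp(-beta dE)", {
  set.seed(6)
  expect_true(accept_move(-1, 5))
  expect_true(accept_move(0, 5))
  acc <- mean(vapply(1:10000, function(i) accept_move(1, 1), logical(1)))
  p <- exp(-1)
  expect_lt(abs(acc - p), 3 * sqrt(p * (1 - p) / 10000))
  expect_error(accept_move(1, -0.5), ">= 0")
})

test_that("move proposals respect feasibility and protocol invariants", {
  set.seed(7)
  # a drug with no markers can only gain one
  empty <- list(drug_protocol())
  for (i in 1:50) {
    mv <- propose_move(empty, m = 4, k_max = 2)
    expect_identical(mv$type, "add")
    expect_length(mv$protocol$markers, 1)
  }
  # at K = k_max = 2 the menu is remove/change, each about half the time
  full <- list(drug_protocol(c(1, 2), boolfun(c(0, 1, 1, 0))))
  types <- vapply(1:10000, function(i) propose_move(full, 4, 2)$type, "")
  expect_setequal(unique(types), c("remove", "change"))
  expect_lt(abs(mean(types == "remove") - 0.5), 3 * sqrt(0.25 / 10000))

  # forced removal restricts the menu to removals
  types_forced <- vapply(1:100, function(i) {
    propose_move(full, 4, 2, force_remove = TRUE)$type
  }, "")
  expect_true(all(types_forced == "remove"))

  # proposals always satisfy the protocol invariants
  set.seed(8)
  prots <- random_protocols(5, 4, k_max = 2)
  for (i in 1:300) {
    mv <- propose_move(prots, 5, 2)
    p <- mv$protocol
    expect_identical(anyDuplicated(p$markers), 0L)
    if (length(p$markers)) {
      expect_true(depends_on_all_inputs(p$fn$outputs))
      expect_identical(p$fn$K, length(p$markers))
    }
    prots[[mv$drug]] <- p
  }
})

test_that("annealing is deterministic under a fixed seed", {
  inst <- make_instance(2)
  cfg <- anneal_config(c = 1, k_max = 2, steps_per_drug = 100, restarts = 1,
                       min_group_size = 1)
  f1 <- anneal(inst$cohort, inst$responses, cfg, seed = 11, trace_energy = TRUE)
  f2 <- anneal(inst$cohort, inst$responses, cfg, seed = 11, trace_energy = TRUE)
  expect_identical(f1$energy_trace, f2$energy_trace)
  expect_identical(f1$best$O, f2$best$O)
  expect_identical(lapply(f1$best$protocols, unclass),
                   lapply(f2$best$protocols, unclass))
})

test_that("at near-infinite inverse temperature the walk is greedy descent", {
  inst <- make_instance(3)
  cfg <- anneal_config(c = 1, k_max = 1, steps_per_drug = 150, restarts = 1,
                       beta0 = 1e9, dbeta = 0, min_group_size = 1)
  fit <- anneal(inst$cohort, inst$responses, cfg, seed = 4, trace_energy = TRUE)
  expect_true(all(diff(fit$energy_trace) <= 1e-12))
})

test_that("cached energy bookkeeping matches full recomputation", {
  inst <- make_instance(4, n = 30, m = 5, d = 4)
  cfg <- anneal_config(c = 2, k_max = 2, steps_per_drug = 150, restarts = 3,
                       base_seed = 9, min_group_size = 5)
  res <- multi_start(inst$cohort, inst$responses, cfg)
  E_full <- assignment_energy(inst$cohort, inst$responses, res$best$protocols,
                              c = 2, min_group_size = 5)
  expect_lt(abs(res$best$E - E_full), 1e-9)
  expect_equal(res$eval$O, res$best$O, tolerance = 1e-9)
})

test_that("the optimizer attains the exhaustive-search optimum on a tiny instance", {
  inst <- make_instance(5)
  best_exh <- oracle_best_assignment(inst$cohort, inst$responses, c = 1,
                                     min_group_size = 1)
  cfg <- anneal_config(c = 1, k_max = 1, steps_per_drug = 300, restarts = 20,
                       base_seed = 1, min_group_size = 1)
  res <- multi_start(inst$cohort, inst$responses, cfg)
  expect_equal(res$best$O, best_exh, tolerance = 1e-12)
})

test_that("multi-restart reporting is a running maximum with a single-run base case", {
  inst <- make_instance(6)
  cfg1 <- anneal_config(c = 1, k_max = 1, steps_per_drug = 100, restarts = 1,
                        base_seed = 3, min_group_size = 1)
  res1 <- multi_start(inst$cohort, inst$responses, cfg1)
  single <- anneal(inst$cohort, inst$responses, cfg1, seed = 3)
  expect_equal(res1$best$O, single$best$O)

  cfg <- anneal_config(c = 1, k_max = 1, steps_per_drug = 100, restarts = 8,
                       base_seed = 3, min_group_size = 1)
  res <- multi_start(inst$cohort, inst$responses, cfg)
  expect_false(is.unsorted(res$trace$best_so_far))
  expect_equal(max(res$trace$O_star), res$best$O)
  expect_gte(res$best$O, max(res$trace$O_star))
})

test_that("forced removals on untreating drugs never worsen the energy", {
  # a drug that carries markers but treats nobody contributes nothing to O;
  # any change to its column can only add better candidates, so the pruning
  # rule's forced removals always have dE <= 0 and are accepted
  set.seed(31)
  coh <- generate_cohort(40, 4, 0.5, seed = 31)
  resp <- generate_iid_responses(40, 3, seed = 32)
  checked <- 0L
  while (checked < 30L) {
    prots <- random_protocols(4, 3, k_max = 2)
    ev <- evaluate_assignment(coh, resp, prots, c = 1, min_group_size = 1)
    unused <- which(colSums(ev$plan$e) == 0 &
                      lengths(lapply(prots, `[[`, "markers")) > 0)
    if (!length(unused)) next
    E0 <- assignment_energy(coh, resp, prots, c = 1, min_group_size = 1)
    force <- seq_along(prots) %in% unused
    mv <- propose_move(prots, 4, 2, force_remove = force)
    if (!(mv$drug %in% unused)) next
    expect_identical(mv$type, "remove")
    prots2 <- prots
    prots2[[mv$drug]] <- mv$protocol
    E1 <- assignment_energy(coh, resp, prots2, c = 1, min_group_size = 1)
    expect_lte(E1, E0 + 1e-12)
    checked <- checked + 1L
  }
})
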