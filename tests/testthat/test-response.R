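test_that("group index enumerates marker states with binary weights", {
  expect_identical(group_index(c(1, 0)), 1L)
  expect_identical(group_index(c(1, 1)), 3L)
  expect_identical(group_index(integer(0)), 0L)
  expect_error(group_index(c(1, 2)), "binary")
})

test_that("group rates are group means with small groups shrunk to zero", {
  profiles <- matrix(c(rep(1, 15), rep(0, 5)), ncol = 1)
  coh <- cohort(profiles)
  resp <- matrix(ifelse(profiles[, 1] == 1, 0.6, 0.9), ncol = 1)
  prot <- list(drug_protocol(1, boolfun(c(0, 1))))

  tab <- estimate_group_rates(coh, resp, prot, min_group_size = 10)
  expect_equal(tab$drugs[[1]]$q, c(0, 0.6))     # negative group of 5 -> 0
  expect_identical(tab$drugs[[1]]$n, c(5L, 15L))

  tab1 <- estimate_group_rates(coh, matrix(0.3, 20, 1), prot, min_group_size = 1)
  expect_equal(tab1$drugs[[1]]$q, c(0.3, 0.3))

  # by-marker lookup returns the group rate for the sample's status
  expect_equal(marker_response(tab, c(1), 1), 0.6)
  expect_equal(marker_response(tab, c(0), 1), 0)
  expect_error(marker_response(estimate_group_rates(coh, resp,
                                                    list(drug_protocol()), 10),
                               c(1), 1), "no markers")
})

test_that("group rates match a group-by/mean oracle on random instances", {
  set.seed(11)
  coh <- generate_cohort(50, 4, 0.4, seed = 5)
  resp <- generate_iid_responses(50, 3, seed = 6)
  prots <- list(drug_protocol(c(1, 2), boolfun(c(0, 1, 1, 0))),
                drug_protocol(3, boolfun(c(1, 0))),
                drug_protocol())
  tab <- estimate_group_rates(coh, resp, prots, min_group_size = 1)
  for (j in 1:2) {
    mk <- prots[[j]]$markers
    for (i in 1:50) {
      st <- coh$profiles[i, mk]
      grp <- apply(coh$profiles[, mk, drop = FALSE], 1,
                   function(r) all(r == st))
      expect_equal(marker_response(tab, coh$profiles[i, ], j),
                   mean(resp[grp, j]))
    }
  }
  expect_length(tab$drugs[[3]]$q, 0)
  # group sizes partition the cohort
  expect_identical(sum(tab$drugs[[1]]$n), 50L)
})

test_that("top-c selection picks the highest by-marker estimates with index tie-break", {
  # 1 sample, 3 drugs always suggested, pbar 0.9 / 0.7 / 0.8
  coh <- cohort(matrix(1, 1, 1))
  resp <- matrix(c(0.9, 0.7, 0.8), 1, 3)
  prots <- replicate(3, drug_protocol(1, boolfun(c(0, 1))), simplify = FALSE)
  tab <- estimate_group_rates(coh, resp, prots, min_group_size = 1)
  plan <- select_treatment(coh, prots, tab, c = 2)
  expect_identical(plan$chosen[[1]], c(1L, 3L))

  # no candidates -> untreated
  plan0 <- select_treatment(coh, replicate(3, drug_protocol(), simplify = FALSE),
                            estimate_group_rates(coh, resp,
                                                 replicate(3, drug_protocol(),
                                                           simplify = FALSE), 1),
                            c = 2)
  expect_identical(sum(plan0$e), 0L)

  # c = 1 equals an argmax scan with lower-index ties on random instances
  for (seed in 1:5) {
    coh2 <- generate_cohort(30, 3, 0.5, seed = seed)
    resp2 <- generate_iid_responses(30, 4, seed = seed + 50)
    set.seed(seed)
    prots2 <- random_protocols(3, 4, k_max = 1)
    tab2 <- estimate_group_rates(coh2, resp2, prots2, min_group_size = 1)
    plan2 <- select_treatment(coh2, prots2, tab2, c = 1)
    for (i in 1:30) {
      cand <- which(vapply(prots2, function(p) {
        suggest(p, coh2$profiles[i, ]) == 1L
      }, logical(1)))
      if (!length(cand)) {
        expect_identical(plan2$chosen[[i]], integer(0))
      } else {
        pb <- vapply(cand, function(j) marker_response(tab2, coh2$profiles[i, ], j),
                     numeric(1))
        expect_identical(plan2$chosen[[i]], cand[which.max(pb)])
      }
    }
  }
})

test_that("combination response matches at-least-one enumeration and interaction corrections", {
  expect_equal(combination_response(c(0.5, 0.5), c(1, 1)), 0.75)
  expect_equal(combination_response(c(0.2, 0.9), c(0, 1)), 0.9)
  J <- matrix(c(0, log(2), log(2), 0), 2)
  expect_equal(combination_response(c(0.5, 0.5), c(1, 1), J), 0.5)

  set.seed(3)
  for (rep in 1:50) {
    d <- sample(1:10, 1)
    p <- runif(d)
    e <- rbinom(d, 1, 0.6)
    expect_equal(combination_response(p, e), oracle_at_least_one(p[e == 1]),
                 tolerance = 1e-12)
    # J = 0 reduces to the independent form
    expect_equal(combination_response(p, e, matrix(0, d, d)),
                 combination_response(p, e), tolerance = 1e-12)
  }

  # sign of J moves the response in the stated direction
  p <- c(0.4, 0.6)
  base <- combination_response(p, c(1, 1))
  syn <- matrix(c(0, -0.5, -0.5, 0), 2)
  ant <- matrix(c(0, 0.5, 0.5, 0), 2)
  expect_gt(combination_response(p, c(1, 1), syn), base)
  expect_lt(combination_response(p, c(1, 1), ant), base)

  # p = 1 forces P = 1 regardless of antagonism
  expect_equal(combination_response(c(1, 0.5), c(1, 1), ant), 1)
  expect_error(combination_response(c(1.2, 0.5), c(1, 1)), "\\[0,1\\]")
})

test_that("P_i is monotone in each single-drug probability", {
  set.seed(9)
  for (rep in 1:20) {
    p <- runif(3)
    j <- sample(3, 1)
    p2 <- p
    p2[j] <- min(1, p[j] + 0.1)
    expect_gte(combination_response(p2, c(1, 1, 1)),
               combination_response(p, c(1, 1, 1)))
  }
})

test_that("overall response is the sample mean", {
  expect_equal(overall_response(c(1, 0)), 0.5)
  expect_equal(overall_response(rep(0.9, 7)), 0.9)
  set.seed(2)
  P <- runif(40)
  expect_equal(overall_response(P), sum(P) / 40)
  expect_error(overall_response(numeric(0)), "no samples")
})

test_that("assignment evaluation composes the pieces and is monotone in c", {
  # all-empty protocols: nobody treated, O = 0
  coh <- generate_cohort(30, 3, 0.5, seed = 2)
  resp <- generate_iid_responses(30, 3, seed = 4)
  empty <- replicate(3, drug_protocol(), simplify = FALSE)
  ev <- evaluate_assignment(coh, resp, empty, c = 2, min_group_size = 1)
  expect_equal(ev$O, 0)
  expect_identical(sum(ev$plan$e), 0L)

  # one drug, one perfectly predictive marker, c = 1: O equals the mean
  # by-marker estimate over suggested samples
  profiles <- matrix(c(rep(1, 12), rep(0, 8)), ncol = 1)
  coh1 <- cohort(profiles)
  resp1 <- matrix(ifelse(profiles[, 1] == 1, 0.8, 0.1), ncol = 1)
  prot1 <- list(drug_protocol(1, boolfun(c(0, 1))))
  ev1 <- evaluate_assignment(coh1, resp1, prot1, c = 1, min_group_size = 1)
  expect_equal(ev1$O, (12 * 0.8 + 8 * 0) / 20)

  # O never decreases as the combination budget grows
  for (seed in 1:5) {
    coh2 <- generate_cohort(40, 4, 0.5, seed = seed)
    resp2 <- generate_iid_responses(40, 5, seed = seed + 9)
    set.seed(seed + 20)
    prots <- random_protocols(4, 5, k_max = 2)
    Os <- vapply(1:4, function(cc) {
      evaluate_assignment(coh2, resp2, prots, cc, min_group_size = 1)$O
    }, numeric(1))
    expect_false(is.unsorted(Os))
  }
})
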