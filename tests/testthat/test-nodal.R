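# exhaustive enumeration oracle: probability of observing k positives when
# drawing n of M nodes of which the first p are positive
enumerate_pmf <- function(p, M, n) {
  subsets <- utils::combn(M, n)
  k <- colSums(subsets <= p)
  tab <- table(factor(k, levels = 0:min(p, n)))
  as.numeric(tab) / ncol(subsets)
}

test_that("detection pmf matches closed-form and edge cases", {
  expect_equal(unname(detection_pmf(0, 20, 5)), 1)
  expect_equal(unname(detection_pmf(1, 10, 10)), c(0, 1))
  pmf <- detection_pmf(2, 10, 5)
  expect_equal(unname(pmf["0"]), 2 / 9, tolerance = 1e-12)
  expect_equal(sum(pmf), 1, tolerance = 1e-12)
  expect_error(detection_pmf(-1, 10, 5), "p_true")
  expect_error(detection_pmf(2, 10, 0), "n_examined")
  expect_error(detection_pmf(11, 10, 5), "p_true")
})

test_that("detection pmf agrees with subset enumeration on small problems", {
  for (M in c(5, 8)) {
    for (n in 1:M) {
      for (p in 0:M) {
        expect_equal(unname(detection_pmf(p, M, n)),
                     enumerate_pmf(p, M, n), tolerance = 1e-10,
                     label = sprintf("M=%d p=%d n=%d", M, p, n))
      }
    }
  }
})

test_that("empirical prior estimation tabulates thoroughly examined patients", {
  co <- toy_cohort()
  # qualifying counts at eln >= 10 are {0, 0, 3, 1}
  pr <- estimate_prior(co, min_eln = 10, min_patients = 4)
  expect_s3_class(pr, "node_prior")
  expect_equal(pr$mass[pr$support == 0], 0.5)
  expect_equal(pr$mass[pr$support == 3], 0.25)
  expect_error(estimate_prior(co, min_eln = 10), "at least 50")
  expect_error(estimate_prior(co, min_eln = 99, min_patients = 2),
               "0 patients")
})

test_that("prior recovered from exhaustively sampled synthetic patients", {
  cfg <- generator_config(n_patients = 30000, seed = 14, m_total = 12,
                          eln_mu = 1e4, eln_size = 5,
                          positivity_logodds = list(intercept = stats::qlogis(0.4)),
                          ztgeom_p = 0.5)
  co <- generate_cohort(cfg)
  pr <- estimate_prior(co, min_eln = 12)
  truth <- c(0.6, 0.4 * stats::dgeom(0:(max(pr$support) - 1), 0.5))
  truth <- truth / sum(truth)
  tv <- 0.5 * sum(abs(pr$mass - truth[seq_along(pr$mass)]))
  expect_lt(tv, 0.02)
})

test_that("occult probability reproduces the worked Bayes example", {
  pr <- node_prior(c(`0` = 0.5, `2` = 0.5))
  expect_equal(occult_probability(pr, 10, 5, 0), 2 / 11, tolerance = 1e-12)
  expect_equal(occult_probability(pr, 10, 10, 0), 0)
  expect_equal(occult_probability(node_prior(c(`0` = 1)), 10, 4, 0), 0)
  # impossible observation: every prior mass point excludes k = 0 at n = 9
  expect_error(occult_probability(node_prior(c(`2` = 1)), 10, 9, 0),
               "zero probability")
  expect_error(occult_probability(pr, 10, 11, 0), "n_examined <= m_total")
})

test_that("posterior over the true count is a proper Bayes posterior", {
  set.seed(19)
  for (i in 1:20) {
    supp <- sort(sample(0:8, 4))
    pr <- node_prior(setNames(runif(4), supp))
    n <- sample(1:10, 1)
    lik <- vapply(pr$support, function(p) {
      pmf <- detection_pmf(p, 12, n)
      unname(pmf["0"])
    }, numeric(1))
    post <- pr$mass * lik / sum(pr$mass * lik)
    expect_equal(sum(post), 1, tolerance = 1e-9)
    expect_equal(occult_probability(pr, 12, n, 0),
                 sum(post[pr$support > 0]), tolerance = 1e-12)
  }
})

test_that("occult table tabulates the worked example and degenerate prior", {
  pr <- node_prior(c(`0` = 0.5, `2` = 0.5))
  tab <- occult_table(pr, 10)
  expect_equal(tab$p_occult_given_k0[tab$n == 5], 2 / 11, tolerance = 1e-12)
  expect_equal(tab$p_occult_given_k0[tab$n == 10], 0)
  expect_true(all(diff(tab$p_occult_given_k0) <= 1e-12))

  tab0 <- occult_table(node_prior(c(`0` = 1)), 10)
  expect_true(all(tab0$p_occult_given_k0 == 0))
})

test_that("model-predicted occult risk matches the generator's latent truth", {
  co <- generate_cohort(generator_config(n_patients = 50000, seed = 17))
  prior_tab <- table(co$latent_true_positive) / nrow(co)
  pr <- node_prior(setNames(as.numeric(prior_tab), names(prior_tab)),
                   source = "empirical")
  for (n_ex in c(3, 7, 12)) {
    sel <- co$eln_count == n_ex & co$n_stage == "node_negative"
    emp <- mean(co$latent_true_positive[sel] > 0)
    half_width <- 1.96 * sqrt(emp * (1 - emp) / sum(sel))
    pred <- occult_probability(pr, 40, n_ex, 0)
    expect_lt(abs(pred - emp), half_width + 1e-3,
              label = sprintf("n_examined=%d", n_ex))
  }
})
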