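test_that("forward-backward matches brute-force path sums", {
  par <- hmm_params(p = 1e-4)
  set.seed(55)
  for (rep in 1:50) {
    n <- sample(1:6, 1)
    ch <- random_chain(n)
    fb <- forward_backward(ch$emissions, ch$distances, par)
    enum <- enumerate_chain(ch$emissions, ch$distances, par)
    expect_equal(fb$loglik, enum$total_loglik, tolerance = 1e-9)
    expect_equal(unname(rowSums(fb$posterior)), rep(1, n),
                 tolerance = 1e-9)
  }

  # single-target chain: posterior proportional to prior x emission
  em <- matrix(c(-1, -2, -3), 1, 3)
  fb1 <- forward_backward(em, numeric(0), par)
  expected <- exp(log(c(par$p, 1 - 2 * par$p, par$p)) + em[1, ])
  expect_equal(unname(fb1$posterior[1, ]), expected / sum(expected),
               tolerance = 1e-12)

  # flat evidence: posterior DIP ~ 1 - 2p at every target
  emf <- matrix(-2, 6, 3)
  fbf <- forward_backward(emf, rep(1000, 5), par)
  expect_equal(unname(fbf$posterior[, "DIP"]), rep(1 - 2 * par$p, 6),
               tolerance = 1e-3)
})

test_that("Phred pair follows the definition and caps", {
  s <- nbcnv:::phred_pair(log(0.1))
  expect_equal(s$SQ, 10)
  expect_equal(s$NQ, -10 * log10(0.9))
  expect_equal(s$NQ, 0.4575749, tolerance = 1e-6)
  capped <- nbcnv:::phred_pair(log(1 - 1e-15))
  expect_equal(capped$SQ, 0, tolerance = 1e-5)
  expect_equal(capped$NQ, 99)
})

test_that("SQ/NQ satisfy pre-cap complementarity on random instances", {
  par <- hmm_params()
  set.seed(66)
  for (rep in 1:100) {
    delta <- -rexp(1, rate = 0.2)  # log P_none
    s <- nbcnv:::phred_pair(delta, cap = Inf)
    expect_equal(10^(-s$SQ / 10) + 10^(-s$NQ / 10), 1, tolerance = 1e-6)
  }
})

test_that("restricted-chain P_none matches enumeration and is monotone in the region", {
  par <- hmm_params(p = 1e-3)
  set.seed(77)
  for (rep in 1:40) {
    n <- 5
    ch <- random_chain(n)
    first <- sample(1:4, 1); last <- sample(first:n, 1)
    forbidden <- sample(c(1L, 3L), 1)
    total <- forward_backward(ch$emissions, ch$distances, par)$loglik
    restr <- nbcnv:::restricted_loglik(ch$emissions, ch$distances, par,
                                       first, last, forbidden)
    p_none <- exp(restr - total)
    expect_gte(p_none, 0); expect_lte(p_none, 1 + 1e-12)
    oracle <- enumerate_p_none(ch$emissions, ch$distances, par,
                               first, last, forbidden)
    expect_equal(p_none, oracle, tolerance = 1e-9)

    # enlarging the forbidden region can only remove paths: P_none falls
    if (first > 1) {
      wider <- nbcnv:::restricted_loglik(ch$emissions, ch$distances, par,
                                         first - 1L, last, forbidden)
      expect_lte(exp(wider - total), p_none + 1e-12)
    }
  }
})

test_that("interval qualities reflect evidence in a simulated sample", {
  sim <- tiny_cohort(n_samples = 25, n_targets = 300, seed = 13)
  set.seed(14)
  sim <- spike_cnvs(sim, data.frame(sample = "S002", first_target = 101,
                                    last_target = 105, copy = 1))
  mom <- suppressMessages(
    estimate_moments(sim$counts, sim$targets, "S002",
                     min_targets_trend = 100))
  iq <- interval_qualities(mom, sim$counts[, "S002"], sim$targets,
                           c(101, 105), "DEL")
  expect_gt(iq$SQ, 60)
  expect_lt(iq$NQ, 1)

  # same region, no evidence: SQ ~ 0, NQ near the prior ceiling
  # (-10 log10 of the ~5e-9 prior odds of any event in a short region)
  iq0 <- interval_qualities(mom, sim$counts[, "S002"], sim$targets,
                            c(200, 204), "DEL")
  expect_lt(iq0$SQ, 1)
  expect_gt(iq0$NQ, 60)

  expect_error(interval_qualities(mom, sim$counts[, "S002"], sim$targets,
                                  c(150, 149), "DEL"), "region")
})

test_that("copy-number estimation picks supported states via likelihood ratios", {
  nt <- 4
  mom <- structure(list(sample = "s", mu = rep(100, nt),
                        var = rep(250, nt),
                        size = rep(100^2 / 150, nt)),
                   class = "nbcnv_moments")
  del_call <- data.frame(sample = "s", type = "DEL", chrom = "chr1",
                         start = 0L, end = 400L, first_target = 1L,
                         last_target = 3L, n_targets = 3L)
  # counts near mu/2: the het baseline wins
  cn1 <- copy_number_estimate(del_call, c(52, 48, 50, 100), mom)
  expect_equal(cn1$copy_number, 1L)

  # all-zero counts over 3 targets at mu = 100: homozygous deletion,
  # with LR over copy 1 far above 1000 (checked directly)
  cn0 <- copy_number_estimate(del_call, c(0, 0, 0, 100), mom)
  expect_equal(cn0$copy_number, 0L)
  ll1 <- sum(dnbinom(c(0, 0, 0), mu = 50, size = mom$size[1] / 2,
                     log = TRUE))
  ll0 <- sum(dpois(c(0, 0, 0), 0.2, log = TRUE))
  expect_equal(unname(cn0$loglik["1"]), ll1)
  expect_equal(unname(cn0$loglik["0"]), ll0)
  expect_gt(ll0 - ll1, log(1000))

  dup_call <- del_call
  dup_call$type <- "DUP"; dup_call$last_target <- 4L; dup_call$n_targets <- 4L
  # counts near 2*mu: copy 4 beats copy 3 by direct likelihood comparison
  k4 <- c(205, 195, 200, 198)
  cn4 <- copy_number_estimate(dup_call, k4, mom)
  ll3 <- sum(dnbinom(k4, mu = 150, size = 1.5 * mom$size, log = TRUE))
  ll4 <- sum(dnbinom(k4, mu = 200, size = 2 * mom$size, log = TRUE))
  expect_gt(ll4 - ll3, log(1000))
  expect_equal(cn4$copy_number, 4L)

  # counts near 1.5*mu: the single-copy duplication baseline stands
  cn3 <- copy_number_estimate(dup_call, c(155, 145, 150, 148), mom)
  expect_equal(cn3$copy_number, 3L)

  # scale consistency: doubling mu, z and counts leaves the choice alone
  mom2 <- mom; mom2$mu <- 2 * mom$mu; mom2$size <- 2 * mom$size
  cn0b <- copy_number_estimate(del_call, c(0, 0, 0, 200), mom2)
  expect_equal(cn0b$copy_number, 0L)
  cn4b <- copy_number_estimate(dup_call, 2 * k4, mom2)
  expect_equal(cn4b$copy_number, 4L)
})
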