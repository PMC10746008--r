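test_that("analytic limits of the Stable Ecotype simulator hold", {
  crit <- binning_criteria()
  # huge periodic-selection rate, one ecotype: everything coalesces at ~0,
  # so the curve is all ones at every criterion
  r <- simulate_replicate(sem_params(0, 1e7, 1), n = 10, depth = 0.05,
                          L = 500, seed = 3)
  expect_true(all(r$curve$n_bins == 1L))

  # no events: the genealogy is a star of the full depth
  r0 <- simulate_replicate(sem_params(0, 0, 3), n = 8, depth = 0.04,
                           L = 400, seed = 4)
  tr <- r0$genealogy
  expect_s3_class(tr, "phylo")
  expect_equal(ape::Ntip(tr), 8L)
  expect_equal(tr$Nnode, 1L)
  expect_true(all(abs(tr$edge.length - 0.04) < 1e-12))
})

test_that("genealogies are ultrametric and seeds give bit-reproducible output", {
  p <- sem_params(0.5, 50, 3)
  r1 <- simulate_replicate(p, n = 12, depth = 0.03, L = 600, seed = 11)
  r2 <- simulate_replicate(p, n = 12, depth = 0.03, L = 600, seed = 11)
  expect_identical(r1$alignment$seq, r2$alignment$seq)
  expect_identical(r1$curve$n_bins, r2$curve$n_bins)
  expect_identical(write_newick(r1$genealogy), write_newick(r2$genealogy))
  # ultrametric: every leaf at the same distance from the root
  depths <- ape::node.depth.edgelength(r1$genealogy)[seq_len(12)]
  expect_true(max(depths) - min(depths) < 1e-9)
})

test_that("two persistent ecotypes produce two bins at separating criteria", {
  # npop = 2, no formation, instant within-ecotype coalescence: leaves in
  # different ecotypes diverge for ~2*depth; expected two bins at criteria
  # above 1 - 2*depth and below 1 (estimated over replicates)
  depth <- 0.02
  crit <- c(1, 0.995, 0.99, 0.985)
  p <- sem_params(0, 1e7, 2)
  two_bins <- 0L
  n_rep <- 200L
  for (i in seq_len(n_rep)) {
    r <- simulate_replicate(p, n = 4, depth = depth, L = 2000,
                            criteria = crit, seed = 1000L + i, full = FALSE)
    # criterion 0.99: tolerates distance 0.01 < 2*depth = 0.04
    if (r$curve$n_bins[3] == 2L) two_bins <- two_bins + 1L
  }
  # JC-expected observed distance 0.75*(1-exp(-4*0.04/3)) ~ 0.039 >> 0.01;
  # binomial fluctuation cannot bring 2000 sites below 1% difference
  expect_gt(two_bins / n_rep, 0.95)
})

test_that("mean pairwise distance grows with depth and stays below the JC bound", {
  p <- sem_params(0, 0, 2)
  mean_p <- vapply(c(0.01, 0.05, 0.2, 0.7), function(dep) {
    r <- simulate_replicate(p, n = 6, depth = dep, L = 1500, seed = 21)
    dm <- distance_matrix(r$alignment, "p_distance")
    mean(dm$d[upper.tri(dm$d)])
  }, numeric(1))
  expect_true(all(diff(mean_p) > 0))
  expect_true(all(mean_p < 0.75))
})

test_that("the match-fraction likelihood behaves as a probability estimate", {
  crit <- binning_criteria()
  ones <- structure(
    tibble::tibble(criterion = crit, n_bins = rep(1L, length(crit))),
    class = c("binning_curve", class(tibble::tibble())))
  # degenerate optimum: huge sigma, npop = 1 reproduces the all-ones curve
  lk <- likelihood_estimate(sem_params(0, 1e7, 1), ones, match_rule(1.1),
                            R = 50, n = 8, depth = 0.02, L = 500, seed = 5)
  expect_equal(lk, 1)
  # infinite tolerance accepts anything
  lk_inf <- likelihood_estimate(sem_params(1, 1, 5), ones,
                                match_rule(Inf), R = 20, n = 8,
                                depth = 0.02, L = 500, seed = 5)
  expect_equal(lk_inf, 1)
  # compositional check: equals the hand-run fraction over the same substreams
  obs <- simulate_replicate(sem_params(0.1, 100, 2), n = 6, depth = 0.02,
                            L = 400, seed = 8)$curve
  p <- sem_params(0.1, 100, 2)
  R <- 10L
  by_hand <- mean(vapply(seq_len(R), function(i) {
    r <- simulate_replicate(p, n = 6, depth = 0.02, L = 400,
                            seed = ecotypesim:::derive_seed(42L, i),
                            full = FALSE)
    lo <- floor(r$curve$n_bins / 1.1); hi <- ceiling(r$curve$n_bins * 1.1)
    all(obs$n_bins >= lo & obs$n_bins <= hi)
  }, logical(1)))
  got <- likelihood_estimate(p, obs, match_rule(1.1), R = R, n = 6,
                             depth = 0.02, L = 400, seed = 42L)
  expect_equal(got, by_hand)
})

test_that("likelihood Monte-Carlo error shrinks roughly as 1/sqrt(R)", {
  obs <- simulate_replicate(sem_params(0.1, 200, 3), n = 10, depth = 0.02,
                            L = 500, seed = 14)$curve
  p <- sem_params(0.1, 200, 3)
  est <- function(R, seeds) vapply(seeds, function(s)
    likelihood_estimate(p, obs, match_rule(1.2), R = R, n = 10,
                        depth = 0.02, L = 500, seed = s), numeric(1))
  sd_small <- stats::sd(est(25L, 1:12))
  sd_large <- stats::sd(est(100L, 101:112))
  # fourfold replicates should halve the spread (allow generous slack)
  expect_lt(sd_large, sd_small * 0.9 + 0.02)
})

test_that("ecotype count is non-increasing backward in time (omega = 0 keeps it fixed)", {
  # with omega = 0 and finite sigma, lineages of distinct ecotypes never mix:
  # the final curve keeps at least npop bins at stringent criteria when depth
  # separates them
  r <- simulate_replicate(sem_params(0, 1e6, 3), n = 9, depth = 0.03,
                          L = 1500, seed = 33)
  expect_gte(r$curve$n_bins[r$curve$criterion == 0.99], 3L)
})
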