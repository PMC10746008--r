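# Fast checks of the fitter and the recursive demarcation; the full
# parameter-recovery experiment lives in the acceptance suite.

test_that("an all-ones curve fits npop = 1", {
  crit <- binning_criteria()
  ones <- ecotypesim:::new_binning_curve(crit, rep(1L, length(crit)))
  fit <- fit_parameters(ones, n = 8, depth = 0.02, L = 500, R = 50,
                        restarts = 1, seed = 2, maxit = 40)
  expect_equal(fit$best$npop, 1L)
  expect_gt(fit$likelihood, 0.5)
})

test_that("fits are bit-reproducible under a fixed seed", {
  sim <- simulate_ecotype_alignment(synth_config(n_ecotypes = 2,
                                                 seqs_per_ecotype = 6,
                                                 L = 400, seed = 5))
  dmp <- distance_matrix(sim$alignment, "p_distance")
  crv <- binning_curve(dmp)
  f1 <- suppressWarnings(fit_parameters(crv, n = 12, depth = 0.02, L = 400,
                                        R = 60, restarts = 2, seed = 7,
                                        maxit = 30))
  f2 <- suppressWarnings(fit_parameters(crv, n = 12, depth = 0.02, L = 400,
                                        R = 60, restarts = 2, seed = 7,
                                        maxit = 30))
  expect_identical(tidy(f1), tidy(f2))
  expect_identical(f1$likelihood, f2$likelihood)
})

test_that("profile CIs contain the estimate and widen as the threshold drops", {
  sim <- simulate_ecotype_alignment(synth_config(n_ecotypes = 2,
                                                 seqs_per_ecotype = 6,
                                                 L = 400, seed = 9))
  crv <- binning_curve(distance_matrix(sim$alignment, "p_distance"))
  fit <- suppressWarnings(fit_parameters(crv, n = 12, depth = 0.02, L = 400,
                                         R = 60, restarts = 1, seed = 3,
                                         maxit = 30))
  ci95 <- profile_ci(fit, "npop", R = 60, seed = 3)
  expect_true(ci95[1] <= fit$best$npop && fit$best$npop <= ci95[2])
  ci_loose <- profile_ci(fit, "npop", R = 60, seed = 3,
                         rel_threshold = 0.01)
  expect_lte(ci_loose[1], ci95[1])
  expect_gte(ci_loose[2], ci95[2])
  prof <- attr(ci95, "profile")
  expect_true(all(c("value", "likelihood") %in% names(prof)))
})

test_that("demarcation partitions leaves into tree-consistent clades", {
  sim <- simulate_ecotype_alignment(synth_config(n_ecotypes = 3,
                                                 seqs_per_ecotype = 6,
                                                 L = 600, seed = 21))
  aln <- sim$alignment
  dmj <- distance_matrix(aln, "jc_corrected")
  tree <- suppressMessages(nj_tree(dmj))
  fit <- suppressWarnings(
    fit_parameters(binning_curve(distance_matrix(aln, "p_distance")),
                   n = nrow(aln), depth = max(dmj$d) / 2, L = 600,
                   R = 200, restarts = 2, seed = 13))
  dem <- demarcate(tree, aln, fit, demarcate_control(seed = 13))
  # a partition: every leaf exactly once
  expect_setequal(dem$assignments$id, aln$id)
  expect_false(anyDuplicated(dem$assignments$id) > 0)
  # hierarchical consistency: every ecotype is the leaf set of one tree node
  for (i in seq_len(nrow(dem$clades))) {
    node <- dem$clades$node[i]
    tips <- if (node <= ape::Ntip(tree)) tree$tip.label[node] else
      tree$tip.label[unlist(phangorn::Descendants(tree, node, "tips"))]
    expect_setequal(dem$clades$members[[i]], tips)
  }
  # recovered the generating structure
  expect_equal(nrow(dem$clades), 3L)
  joined <- dplyr::inner_join(dem$assignments, sim$truth, by = "id")
  expect_equal(length(unique(paste(joined$ecotype.x, joined$ecotype.y))), 3L)
})

test_that("a tree over identical sequences demarcates as a single ecotype", {
  aln <- make_aln(rep("ACGTACGTACGTACGTACGT", 6))
  tree <- ape::rtree(6, tip.label = aln$id)
  fit <- sem_params(0.1, 500, 1)
  dem <- demarcate(tree, aln, fit, demarcate_control(R = 40, seed = 1))
  expect_equal(nrow(dem$clades), 1L)
  expect_equal(dem$clades$n_members, 6L)
})

test_that("well-separated clades are never merged into one ecotype", {
  # two clusters > 3% apart, tight within
  sim <- simulate_ecotype_alignment(synth_config(n_ecotypes = 2,
                                                 seqs_per_ecotype = 8,
                                                 L = 750, seed = 31))
  aln <- sim$alignment
  dmj <- distance_matrix(aln, "jc_corrected")
  tree <- suppressMessages(nj_tree(dmj))
  for (s in 1:3) {
    fit <- sem_params(0.5, 400, 2)
    dem <- demarcate(tree, aln, fit, demarcate_control(R = 60, seed = s))
    agree <- dplyr::inner_join(dem$assignments, sim$truth, by = "id")
    tab <- table(agree$ecotype.x, agree$ecotype.y)
    # no demarcated ecotype mixes the two generating clusters
    expect_true(all(rowSums(tab > 0) == 1L))
  }
  expect_error(demarcate(tree, aln[-1, ], sem_params(1, 1, 1)),
               "absent from alignment")
})
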