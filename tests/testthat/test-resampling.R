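test_that("add-one Monte Carlo p-values follow (k+1)/(n+1)", {
  expect_equal(monte_carlo_pvalue(17, 1000), 18 / 1001)
  expect_equal(round(monte_carlo_pvalue(17, 1000), 3), 0.018)
  expect_equal(round(monte_carlo_pvalue(19, 1000), 2), 0.02)
  expect_equal(monte_carlo_pvalue(5, 5), 1)
  expect_equal(monte_carlo_pvalue(0, 99), 0.01)
  expect_error(monte_carlo_pvalue(6, 5), "k_exceed")
})

test_that("beta-fit p-values are self-consistent on simulated nulls", {
  set.seed(41)
  pseudo <- rbeta(2000, 40, 20)
  q99 <- qbeta(0.99, 40, 20)
  p <- beta_fit_pvalue(pseudo, q99)
  expect_gt(p, 0.004); expect_lt(p, 0.025)
  expect_equal(beta_fit_pvalue(pseudo, qbeta(0.5, 40, 20)), 0.5,
               tolerance = 0.1)
  # smooth extrapolation beyond the pseudo range
  p_far <- beta_fit_pvalue(pseudo, 0.999)
  expect_gt(p_far, 0); expect_lt(p_far, 1 / 2001)
  expect_error(beta_fit_pvalue(runif(5), 0.5), ">= 10")
  # values clamped at the boundary still fit
  expect_no_error(beta_fit_pvalue(c(0, 1, rbeta(50, 5, 5)), 0.9))
})

test_that("permutation tests rerun the whole training and are seeded", {
  d <- make_small_z(seed = 19, n_unaffected = 8, n_nonprogressed = 12,
                    n_progressed = 12, n_mirnas = 40,
                    planted = default_planted(40, effect = 2))
  pt1 <- permutation_test(d$z2, d$labels, n_perm = 60, max_markers = 3,
                          seed = 5)
  pt2 <- permutation_test(d$z2, d$labels, n_perm = 60, max_markers = 3,
                          seed = 5)
  expect_identical(pt1$pseudo_aucs, pt2$pseudo_aucs)
  expect_true(all(pt1$pseudo_aucs >= 0 & pt1$pseudo_aucs <= 1))
  expect_gte(pt1$p_montecarlo, 1 / 61)
  expect_lte(pt1$p_montecarlo, 1)
  k <- sum(pt1$pseudo_aucs > pt1$true_auc)
  expect_equal(pt1$p_montecarlo, (k + 1) / 61)
  expect_error(permutation_test(d$z2, d$labels, n_perm = 0), "n_perm")
})

test_that("a strongly planted signal drives the permutation p to its floor", {
  ps <- vapply(1:3, function(s) {
    d <- make_small_z(seed = s + 60, n_unaffected = 10,
                      n_nonprogressed = 18, n_progressed = 15,
                      n_mirnas = 60, planted = default_planted(60, 2))
    permutation_test(d$z2, d$labels, n_perm = 200, max_markers = 6,
                     seed = s)$p_montecarlo
  }, numeric(1))
  expect_true(all(ps <= 0.05))
  expect_true(min(ps) == 1 / 201)
})

test_that("stability selection tallies sign-blind selection counts", {
  d <- make_small_z(seed = 23, n_unaffected = 8, n_nonprogressed = 14,
                    n_progressed = 12, n_mirnas = 40,
                    planted = default_planted(40, 1.5))
  one <- stability_selection(d$z2, d$labels, n_trials = 1,
                             max_markers = 4, seed = 2)
  expect_true(all(one$counts %in% 0:1))
  st <- stability_selection(d$z2, d$labels, n_trials = 40,
                            max_markers = 4, seed = 2)
  expect_lte(sum(st$counts), 40 * 4)
  expect_true(all(st$counts >= 0 & st$counts <= 40))
  planted <- sprintf("mir-%03d", d$cohort$truth$planted$index)
  top7 <- names(sort(st$counts, decreasing = TRUE))[1:7]
  expect_gte(sum(planted %in% top7), 4)
  expect_error(stability_selection(d$z2, d$labels, subset_fraction = 0.1),
               "subset_fraction")
})

test_that("classifier integration intersects stable and full-data markers", {
  stab <- structure(list(counts = c(A = 900, B = 600, C = 400, D = 100),
                         n_trials = 1000, subset_fraction = 0.8),
                    class = "calf_stability")
  full <- structure(list(terms = data.frame(mirna = c("A", "D"),
                                            weight = c(1, -1)),
                         pos_class = "p"), class = "calf")
  integ <- integrate_classifier(stab, full, min_count = 225)
  expect_equal(integ$terms$mirna, "A")
  expect_equal(integ$terms$weight, 1)

  full2 <- structure(list(terms = data.frame(mirna = c("A", "B"),
                                             weight = c(1, -1)),
                          pos_class = "p"), class = "calf")
  integ2 <- integrate_classifier(stab, full2, min_count = 225)
  expect_equal(integ2$terms, full2$terms)

  full3 <- structure(list(terms = data.frame(mirna = "D", weight = 1),
                          pos_class = "p"), class = "calf")
  expect_error(integrate_classifier(stab, full3, 225), "min_count")
})

test_that("fixed-model subset AUC distributions behave at the extremes", {
  z <- rbind(sep = c(rep(-4, 12), rep(4, 12)))
  colnames(z) <- paste0("s", 1:24)
  lab <- rep(c("ctrl", "case"), each = 12)
  model <- structure(list(terms = data.frame(mirna = "sep", weight = 1),
                          pos_class = "case"), class = "calf")
  res <- subset_auc_distribution(model, z, lab, n_per_group = 6,
                                 n_trials = 50, seed = 3)
  expect_equal(res$mean, 1); expect_equal(res$sd, 0)

  full <- subset_auc_distribution(model, z, lab, n_per_group = 12,
                                  n_trials = 20, seed = 3)
  expect_equal(full$sd, 0)

  d <- make_small_z(seed = 29, n_unaffected = 10, n_nonprogressed = 30,
                    n_progressed = 30, n_mirnas = 40,
                    planted = default_planted(40))
  fit <- calf(d$z2, d$labels, pos_class = "progressed")
  sub <- subset_auc_distribution(fit, d$z2, d$labels, n_per_group = 25,
                                 n_trials = 300, seed = 11)
  expect_lt(abs(sub$mean - fit$auc), 0.02)
  expect_error(subset_auc_distribution(fit, d$z2, d$labels,
                                       n_per_group = 31), "smaller")
})

test_that("confound-extremal subsetting isolates a score-linked flag", {
  d <- make_small_z(seed = 31, n_unaffected = 10, n_nonprogressed = 30,
                    n_progressed = 30, n_mirnas = 40,
                    planted = default_planted(40, effect = 0.5))
  fit <- calf(d$z2, d$labels, pos_class = "progressed")
  scores <- predict(fit, d$z2)

  # independent flag: the two extremal modes stay close to plain subsetting
  set.seed(7)
  flag_ind <- rbinom(length(d$labels), 1, 0.4)
  mx <- confound_extremal_subsets(fit, d$z2, d$labels, flag_ind,
                                  n_per_group = 25, n_trials = 200,
                                  mode = "maximize", seed = 2)
  mn <- confound_extremal_subsets(fit, d$z2, d$labels, flag_ind,
                                  n_per_group = 25, n_trials = 200,
                                  mode = "minimize", seed = 2)
  plain <- subset_auc_distribution(fit, d$z2, d$labels, n_per_group = 25,
                                   n_trials = 200, seed = 2)
  expect_lt(abs(mx$mean - plain$mean), 0.05)
  expect_lt(abs(mn$mean - plain$mean), 0.05)

  # adversarial flag (positive control): flags mark the samples that
  # contradict the classifier, so forcing them in or out separates the modes
  pos <- d$labels == "progressed"
  flag_adv <- integer(length(scores))
  flag_adv[!pos][order(-scores[!pos])[1:10]] <- 1L   # worst negatives
  flag_adv[pos][order(scores[pos])[1:10]] <- 1L      # worst positives
  mx2 <- confound_extremal_subsets(fit, d$z2, d$labels, flag_adv,
                                   n_per_group = 15, n_trials = 200,
                                   mode = "maximize", seed = 2)
  mn2 <- confound_extremal_subsets(fit, d$z2, d$labels, flag_adv,
                                   n_per_group = 15, n_trials = 200,
                                   mode = "minimize", seed = 2)
  expect_gt(mn2$mean - mx2$mean, 0.05)

  # all-flagged maximize reduces to plain subsetting
  all_on <- confound_extremal_subsets(fit, d$z2, d$labels,
                                      rep(1, length(d$labels)),
                                      n_per_group = 25, n_trials = 50,
                                      mode = "maximize", seed = 9)
  plain2 <- subset_auc_distribution(fit, d$z2, d$labels, n_per_group = 25,
                                    n_trials = 50, seed = 9)
  expect_equal(all_on$aucs, plain2$aucs)
})
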