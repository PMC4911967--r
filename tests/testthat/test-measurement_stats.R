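# Accuracy/precision estimators, repeated-measures ANOVA, Kendall tau.

test_that("c4 matches the closed form and its Monte-Carlo definition", {
  expect_error(c4(1), "n >= 2")
  expect_equal(c4(2), sqrt(2 / pi), tolerance = 1e-12)
  # E[s]/sigma over many normal samples
  set.seed(10)
  s2 <- replicate(2e5, sd(rnorm(2)))
  expect_equal(c4(2), mean(s2), tolerance = 0.005)
  s4 <- replicate(1e5, sd(rnorm(4)))
  expect_equal(c4(4), mean(s4), tolerance = 0.005)
  # asymptote
  expect_equal(c4(1e6), 1, tolerance = 1e-5)
})

test_that("accuracy is the mean signed error with a t interval", {
  tab <- flat_measurement_table(c(9.8, 10.1))
  tr <- anova_truths(2)
  a <- accuracy(tab, tr)
  expect_equal(a$mean_diff, -0.05)
  expect_equal(a$n, 2L)
  expect_true(a$ci_lo <= a$mean_diff & a$mean_diff <= a$ci_hi)
  # exact measurements give zero bias; n = 1 leaves the CI undefined
  a1 <- accuracy(flat_measurement_table(10), anova_truths(1))
  expect_equal(a1$mean_diff, 0)
  expect_true(is.na(a1$ci_lo))
})

test_that("intraobserver variability applies the c4 correction to round pairs", {
  tab <- rbind(flat_measurement_table(5.0, round = 1),
               flat_measurement_table(5.4, round = 2))
  iv <- intraobserver_variability(tab)
  expect_equal(iv$value, sd(c(5, 5.4)) / c4(2), tolerance = 1e-12)
  expect_equal(iv$value, 0.3545, tolerance = 1e-4)
  # identical rounds give zero
  tab0 <- rbind(flat_measurement_table(c(5, 7, 9), round = 1),
                flat_measurement_table(c(5, 7, 9), round = 2))
  expect_equal(intraobserver_variability(tab0)$value, 0)
  # a pair with a non-measurable round drops that nodule only
  tab$nonmeasurable[tab$round == 2] <- TRUE
  tab$measured_diameter[tab$round == 2] <- NA
  expect_equal(nrow(intraobserver_variability(tab)), 0L)
})

test_that("interobserver variability pools observers with c4(m)", {
  vals <- c(5.0, 5.2, 5.4, 5.8)
  tab <- do.call(rbind, lapply(1:4, function(o)
    flat_measurement_table(vals[o], observer = o)))
  iv <- interobserver_variability(tab)
  expect_equal(iv$value, sd(vals) / c4(4), tolerance = 1e-12)
  expect_equal(iv$value, 0.3708, tolerance = 1e-3)
  tab_same <- do.call(rbind, lapply(1:4, function(o)
    flat_measurement_table(5.5, observer = o)))
  expect_equal(interobserver_variability(tab_same)$value, 0)
  expect_error(interobserver_variability(flat_measurement_table(5)),
               "two or more")
})

test_that("internodule variability is the SD of signed errors, uncorrected", {
  tab <- flat_measurement_table(c(9.8, 10.0, 10.2))
  tr <- anova_truths(3)
  iv <- internodule_variability(tab, tr)
  expect_equal(iv$value, 0.2, tolerance = 1e-12)
  expect_equal(iv$n, 3L)
  tab_eq <- flat_measurement_table(c(9.9, 9.9, 9.9))
  expect_equal(internodule_variability(tab_eq, tr)$value, 0)
})

test_that("variability estimators order as intra <= inter, internodule", {
  nt <- nodule_table(generate_nodule_set(nodule_set_spec(d_eq_list = 8)))
  tr <- nodule_truths(nt)
  ints <- replicate(30, {
    op <- observer_params(sigma_intra = 0.2, sigma_observer = 0.15,
                          sigma_nodule = 0.3,
                          nonmeasurable = c(-30, 0, 0),
                          seed = sample.int(1e6, 1))
    m <- simulate_measurements(nt, 1, op)
    c(intra = mean(intraobserver_variability(m)$value),
      inter = mean(interobserver_variability(m)$value),
      internod = mean(internodule_variability(m, tr)$value))
  })
  means <- rowMeans(ints)
  expect_gt(means["inter"], means["intra"])
  expect_gt(means["internod"], means["intra"])
})

test_that("estimators are invariant to row order and scale with the units", {
  nt <- nodule_table(generate_nodule_set(nodule_set_spec(d_eq_list = c(4, 8))))
  tr <- nodule_truths(nt)
  op <- observer_params(seed = 3)
  m <- simulate_measurements(nt, c(1, 0.5), op)
  set.seed(1)
  m_perm <- m[sample.int(nrow(m)), ]
  for (f in list(accuracy, internodule_variability)) {
    a <- f(m, tr); b <- f(m_perm, tr)
    expect_equal(a[order(a$observer_id, a$size_group, a$dose_level), ],
                 b[order(b$observer_id, b$size_group, b$dose_level), ],
                 ignore_attr = TRUE)
  }
  # mm -> cm scales every estimate by 0.1
  m_cm <- m; m_cm$measured_diameter <- m$measured_diameter / 10
  tr_cm <- tr; tr_cm$true_diameter <- tr$true_diameter / 10
  expect_equal(accuracy(m_cm, tr_cm)$mean_diff, accuracy(m, tr)$mean_diff / 10)
  expect_equal(intraobserver_variability(m_cm)$value,
               intraobserver_variability(m)$value / 10)
  expect_equal(internodule_variability(m_cm, tr_cm)$value,
               internodule_variability(m, tr)$value / 10)
})

test_that("repeated-measures ANOVA has the complete-case df identity", {
  set.seed(5)
  for (n in c(9, 27, 24)) {
    tab <- anova_table(n)
    r <- rm_anova_abs_diff(tab, anova_truths(n))
    expect_length(r, 1)
    expect_equal(unname(r[[1]]$df),
                 c(2, switch(as.character(n), "9" = 16, "27" = 52,
                             "24" = 46)))
    expect_equal(r[[1]]$n_complete, n)
    expect_true(r[[1]]$p >= 0 && r[[1]]$p <= 1)
  }
  # incomplete nodules are excluded before the df are formed
  tab <- anova_table(10)
  drop_idx <- tab$nodule_id == "n01" & tab$dose_level == 0.5
  tab$nonmeasurable[drop_idx] <- TRUE
  tab$measured_diameter[drop_idx] <- NA
  r <- rm_anova_abs_diff(tab, anova_truths(10))
  expect_equal(r[[1]]$n_complete, 9)
  expect_equal(unname(r[[1]]$df), c(2, 16))
})

test_that("ANOVA flags a real dose effect and reports Bonferroni post hocs", {
  set.seed(8)
  n <- 27
  tab <- anova_table(n, sd = 0.15)
  # inflate the error at the lowest dose
  low <- tab$dose_level == 0.32
  tab$measured_diameter[low] <- 10 + rnorm(n, 0.6, 0.3)
  r <- rm_anova_abs_diff(tab, anova_truths(n))
  expect_lt(r[[1]]$p, 0.05)
  expect_false(is.null(r[[1]]$posthoc))
  expect_equal(nrow(r[[1]]$posthoc), 3)
  expect_true(all(r[[1]]$posthoc$p_bonferroni <= 1))
  # the pair not involving the lowest dose stays non-significant
  null_pair <- r[[1]]$posthoc[r[[1]]$posthoc$dose_a == 1 &
                              r[[1]]$posthoc$dose_b == 0.5, ]
  expect_gt(null_pair$p_bonferroni, 0.05)
})

test_that("Kendall tau is +-1 for monotone triples with exact enumeration p", {
  k <- kendall_tau_dose_vs_variability(c(1, 0.5, 0.32), c(0.2, 0.3, 0.4))
  expect_equal(k$tau, -1)
  expect_equal(k$p, 1 / 3)  # 2 of the 6 orderings reach |tau| = 1
  k2 <- kendall_tau_dose_vs_variability(c(0.32, 0.5, 1), c(0.2, 0.3, 0.4))
  expect_equal(k2$tau, 1)
  # all 6 orderings match a direct pair-counting oracle
  vals <- c(0.21, 0.34, 0.55)
  perms <- tomonodule:::permutations_of(1:3)
  for (i in seq_len(nrow(perms))) {
    v <- vals[perms[i, ]]
    pairs <- combn(3, 2)
    conc <- sum(apply(pairs, 2, function(ij)
      sign(v[ij[2]] - v[ij[1]]) * sign(ij[2] - ij[1]) > 0))
    tau_oracle <- (conc - (3 - conc)) / 3
    expect_equal(kendall_tau_dose_vs_variability(1:3, v)$tau, tau_oracle)
  }
  # constant values are flagged, not computed
  kc <- kendall_tau_dose_vs_variability(1:3, c(1, 1, 1))
  expect_true(is.na(kc$tau))
})

test_that("non-measurable tallies count round-1 flags per stratum", {
  tab <- flat_measurement_table(c(5, NA, NA, 5.2))
  cnt <- count_nonmeasurable(tab)
  expect_equal(cnt$n_nonmeasurable, 2L)
  expect_equal(cnt$n_total, 4L)
  tab$nonmeasurable <- TRUE
  expect_equal(count_nonmeasurable(tab)$n_nonmeasurable, 4L)
  tab$nonmeasurable <- FALSE
  expect_equal(count_nonmeasurable(tab)$n_nonmeasurable, 0L)
})
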