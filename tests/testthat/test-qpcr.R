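test_that("Grubbs test flags a gross outlier and spares clean data", {
  res <- grubbs_test(c(1, 1.1, 0.9, 5.0))
  expect_identical(res$outlier, 4L)
  expect_gt(res$G, res$critical)

  expect_true(is.na(grubbs_test(c(1, 1.02, 0.98, 1.03, 0.97))$outlier))
  expect_true(is.na(grubbs_test(c(-2, -1, 0, 1, 2))$outlier))
  expect_error(grubbs_test(c(1, 2)), "insufficient-data")
  expect_true(is.na(grubbs_test(c(3, 3, 3, 3))$outlier))
})

test_that("Grubbs critical values match the published two-sided 5% table", {
  published <- c(`3` = 1.154, `4` = 1.481, `5` = 1.715, `6` = 1.887,
                 `7` = 2.020, `8` = 2.126, `10` = 2.290, `15` = 2.549,
                 `20` = 2.709, `30` = 2.908)
  got <- grubbs_critical(as.integer(names(published)), 0.05)
  expect_equal(unname(round(got, 3)), unname(published), tolerance = 1e-3)
})

test_that("Grubbs critical value matches the simulated null 95th percentile", {
  set.seed(42)
  for (n in c(5, 10)) {
    g <- replicate(20000, {
      x <- rnorm(n)
      max(abs(x - mean(x))) / sd(x)
    })
    expect_equal(unname(quantile(g, 0.95)), grubbs_critical(n, 0.05),
                 tolerance = 0.02)
  }
})

test_that("ddCt recovers constructed folds and honors the anchor rules", {
  tab <- two_sample_ct(24.00, 20.00, 28.12, 22.00)
  res <- delta_delta_ct(tab)
  treated <- res$per_sample[res$per_sample$condition == "treated", ]
  expect_equal(round(treated$fold, 2), 0.23)
  expect_equal(treated$fold, 2^-((28.12 - 22.00) - (24.00 - 20.00)))
  anchor <- res$per_sample[res$per_sample$sample_id == res$anchor, ]
  expect_identical(anchor$fold, 1)   # anchor normalized to exactly 1

  # shifting both genes of one sample by a constant leaves its fold unchanged
  tab2 <- two_sample_ct(24.00, 20.00, 28.12 + 3, 22.00 + 3)
  res2 <- delta_delta_ct(tab2)
  expect_equal(res2$per_sample$fold, res$per_sample$fold, tolerance = 1e-12)

  # explicit anchor override must name a control sample
  expect_error(delta_delta_ct(tab, anchor = "trt_1"), "not a control")
})

test_that("ddCt pipeline validates its inputs", {
  bad <- data.frame(sample_id = "s1", condition = "a", gene = "g", ct = 24)
  expect_error(ct_table(bad, "ref", "a"), "reference gene")
  missing_ref <- data.frame(
    sample_id = c("s1", "s1", "s2"), condition = c("a", "a", "a"),
    gene = c("g", "ref", "g"), ct = c(24, 20, 25))
  expect_error(ct_table(missing_ref, "ref", "a"), "s2")
})

test_that("fold positivity and anchor normalization hold on random tables", {
  for (seed in 1:5) {
    set.seed(seed)
    fl <- matrix(exp(runif(4, -4, 4)), 2, 2,
                 dimnames = list(c("ctrl", "trt"), c("g1", "g2")))
    fl["ctrl", ] <- 1
    tab <- gen_ct_table(c("ctrl", "trt"), c("g1", "g2", "hk"), "hk", fl,
                        replicates = 4, ct_noise_sd = 0.3, seed = seed)
    res <- delta_delta_ct(tab)
    expect_true(all(res$per_sample$fold > 0))
    expect_true(all(res$per_condition$fold_geomean > 0))
    anchor_rows <- res$per_sample[res$per_sample$sample_id == res$anchor, ]
    expect_true(all(anchor_rows$fold == 1))
  }
})

test_that("Grubbs rejection inside ddCt removes a spiked sample", {
  fl <- matrix(c(1, 2), 2, 1, dimnames = list(c("ctrl", "trt"), "g"))
  tab <- gen_ct_table(c("ctrl", "trt"), c("g", "hk"), "hk", fl,
                      replicates = 6, ct_noise_sd = 0.05, seed = 2)
  # spike one treated replicate by 6 cycles (a pipetting-scale error)
  idx <- which(tab$condition == "trt" & tab$gene == "g")[1]
  tab$ct[idx] <- tab$ct[idx] + 6
  res <- delta_delta_ct(tab, outlier_alpha = 0.05)
  expect_equal(nrow(res$removed_outliers), 1L)
  expect_identical(res$removed_outliers$sample_id,
                   tab$sample_id[idx])
})

test_that("Mann-Whitney matches hand-checked exact cases", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)      # 2 * 1/20 over all rank splits

  same <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)

  expect_error(mann_whitney(numeric(0), 1:3), "input error")
})

test_that("exact Mann-Whitney agrees with brute-force enumeration", {
  set.seed(11)
  for (rep in 1:5) {
    x <- rnorm(5); y <- rnorm(5, 0.8)
    expect_equal(mann_whitney(x, y)$p, brute_force_mw_p(x, y),
                 tolerance = 1e-12)
  }
  # tied data go through the permutation path with the same answer
  x <- c(1, 2, 2, 3); y <- c(2, 3, 3, 4)
  expect_equal(mann_whitney(x, y)$p, brute_force_mw_p(x, y),
               tolerance = 1e-12)
})

test_that("Kruskal-Wallis H matches stats::kruskal.test with and without ties", {
  g <- list(c(1, 2), c(3, 4), c(5, 6))
  kd <- kruskal_dunn(g)
  expect_equal(kd$H, 32 / 7, tolerance = 1e-12)   # hand-computed mean ranks
  expect_equal(kd$H, unname(kruskal.test(g)$statistic), tolerance = 1e-12)
  expect_equal(kd$p, kruskal.test(g)$p.value, tolerance = 1e-12)

  set.seed(8)
  gt <- list(sample(1:4, 6, TRUE), sample(1:4, 5, TRUE), sample(2:6, 7, TRUE))
  kdt <- kruskal_dunn(gt)
  expect_equal(kdt$H, unname(kruskal.test(gt)$statistic), tolerance = 1e-12)

  ident <- list(c(1, 2), c(1, 2), c(1, 2))
  kdi <- kruskal_dunn(ident)
  expect_equal(kdi$H, 0, tolerance = 1e-12)
  expect_true(all(kdi$pairwise$p_adj == 1))

  expect_error(kruskal_dunn(list(1:3, 4:6)), "input error")
  expect_error(kruskal_dunn(list(1:3, 4:6, 7)), "input error")
})

test_that("H is invariant under monotone transforms of the pooled data", {
  set.seed(5)
  g <- list(rnorm(5), rnorm(6, 1), rnorm(4, 2))
  h1 <- kruskal_dunn(g)$H
  h2 <- kruskal_dunn(lapply(g, function(x) exp(x)))$H
  expect_equal(h1, h2, tolerance = 1e-12)
})

test_that("noisy Ct tables recover folds within 10% by geometric-mean ratio", {
  # per-sample folds inherit the anchor sample's own measurement noise; the
  # ratio of condition geometric means cancels it and estimates the true fold
  fl <- matrix(c(1, 0.23), 2, 1, dimnames = list(c("ctrl", "trt"), "g"))
  devs <- vapply(1:10, function(seed) {
    tab <- gen_ct_table(c("ctrl", "trt"), c("g", "hk"), "hk", fl,
                        replicates = 6, ct_noise_sd = 0.1, seed = seed)
    pc <- delta_delta_ct(tab)$per_condition
    ratio <- pc$fold_geomean[pc$condition == "trt"] /
      pc$fold_geomean[pc$condition == "ctrl"]
    abs(ratio / 0.23 - 1)
  }, numeric(1))
  expect_lt(median(devs), 0.10)
})
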