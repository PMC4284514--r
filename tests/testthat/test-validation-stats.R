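test_that("2^-ddCt identities hold", {
  m <- data.frame(group = rep(c("ctrl", "up", "down"), each = 3),
                  ct_target = c(24, 24, 24, 23, 23, 23, 25, 25, 25),
                  ct_reference = 18)
  res <- relative_expression(m, "ctrl")
  expect_equal(res$rq_mean[res$group == "ctrl"], 1)
  expect_equal(res$rq_mean[res$group == "up"], 2)      # one cycle lower
  expect_equal(res$rq_mean[res$group == "down"], 0.5)  # one cycle higher
  expect_equal(res$n, c(3, 3, 3))
  # identical Cts everywhere: every RQ is 1
  flat <- data.frame(group = rep(c("a", "b"), each = 2),
                     ct_target = 30, ct_reference = 20)
  expect_equal(relative_expression(flat, "a")$rq_mean, c(1, 1))
  # invariant to a constant shift of every Ct
  shifted <- m
  shifted$ct_target <- shifted$ct_target + 3.7
  shifted$ct_reference <- shifted$ct_reference + 3.7
  expect_equal(relative_expression(shifted, "ctrl"), res)
  expect_error(relative_expression(m, "nope"), "not present")
})

test_that("calibrator RQ is exactly 1 even with replicate scatter", {
  set.seed(8)
  m <- data.frame(group = rep(c("cal", "test"), each = 6),
                  ct_target = rnorm(12, 25, 0.4),
                  ct_reference = rnorm(12, 18, 0.2))
  res <- relative_expression(m, "cal")
  expect_equal(res$rq_mean[res$group == "cal"], 1, tolerance = 1e-12)
  expect_true(all(res$rq_se > 0))
})

test_that("dual-luciferase ratios normalize within construct", {
  w <- expand.grid(construct = c("wt", "mut"),
                   mirna_arm = c("ctrl", "pre"), rep = 1:3,
                   stringsAsFactors = FALSE)
  w$firefly <- 1000
  w$renilla <- 500
  # pre-miR halves renilla for the wild-type construct only
  w$renilla[w$construct == "wt" & w$mirna_arm == "pre"] <- 250
  res <- dual_luciferase(w, reference_arm = "ctrl")
  get <- function(c_, a_) res$relative_mean[res$construct == c_ &
                                              res$mirna_arm == a_]
  expect_equal(get("wt", "ctrl"), 1)
  expect_equal(get("wt", "pre"), 0.5)
  expect_equal(get("mut", "pre"), 1)  # mutant site unaffected
  # suppression specific to the wild-type site: directional contrast
  expect_lt(get("wt", "pre"), get("mut", "pre"))
  # all identical wells give activity 1
  same <- w; same$renilla <- 400
  expect_true(all(dual_luciferase(same, "ctrl")$relative_mean == 1))
  bad <- w; bad$firefly[2] <- 0; bad$well_id <- paste0("w", seq_len(nrow(w)))
  expect_error(dual_luciferase(bad, "ctrl"), "w2")
})

test_that("dual-luciferase honors the ratio contract under arm rescaling", {
  set.seed(4)
  w <- expand.grid(construct = "wt", mirna_arm = c("ctrl", "pre"), rep = 1:4,
                   stringsAsFactors = FALSE)
  w$firefly <- runif(8, 800, 1200)
  w$renilla <- runif(8, 300, 700)
  base <- dual_luciferase(w, "ctrl")
  # rescaling renilla in every arm identically leaves activities unchanged
  all_scaled <- w; all_scaled$renilla <- all_scaled$renilla * 3
  expect_equal(dual_luciferase(all_scaled, "ctrl")$relative_mean,
               base$relative_mean, tolerance = 1e-12)
  # rescaling the test arm only rescales its relative activity
  arm_scaled <- w
  sel <- arm_scaled$mirna_arm == "pre"
  arm_scaled$renilla[sel] <- arm_scaled$renilla[sel] * 3
  res <- dual_luciferase(arm_scaled, "ctrl")
  expect_equal(res$relative_mean[res$mirna_arm == "pre"],
               3 * base$relative_mean[base$mirna_arm == "pre"],
               tolerance = 1e-12)
})

test_that("viability folds compare groups to the matched baseline", {
  r <- expand.grid(group = c("ctrl", "anti"), timepoint = c(24, 96),
                   rep = 1:3, stringsAsFactors = FALSE)
  r$absorbance <- 0.5
  r$absorbance[r$group == "anti" & r$timepoint == 96] <- 1.0
  res <- viability_fold(r, control_group = "ctrl")
  expect_equal(res$fold_mean[res$group == "ctrl"], c(1, 1))
  expect_equal(res$fold_mean[res$group == "anti" & res$timepoint == 96], 2)
  # per-group first-timepoint baseline
  res2 <- viability_fold(r, baseline = "first_timepoint")
  expect_equal(res2$fold_mean[res2$group == "anti" & res2$timepoint == 96], 2)
  expect_equal(res2$fold_mean[res2$timepoint == 24], c(1, 1))
  # SE propagates from the numerator replicates
  r2 <- r
  r2$absorbance[r2$group == "anti" & r2$timepoint == 96] <- c(0.9, 1.0, 1.1)
  res3 <- viability_fold(r2, control_group = "ctrl")
  expect_equal(res3$fold_se[res3$group == "anti" & res3$timepoint == 96],
               sd(c(0.9, 1.0, 1.1)) / sqrt(3) / 0.5)
  zero <- r; zero$absorbance[zero$group == "ctrl"] <- 0
  expect_error(viability_fold(zero, control_group = "ctrl"), "baseline")
})

test_that("positivity proportions render integer percents", {
  res <- positivity_proportion(c(rep(TRUE, 7), rep(FALSE, 3)))
  expect_equal(res$positive, 7)
  expect_equal(res$total, 10)
  expect_equal(res$percent, 70)
  expect_equal(positivity_proportion(rep(FALSE, 8))$percent, 0)
  expect_equal(positivity_proportion(rep(1, 5))$percent, 100)
  expect_equal(positivity_proportion(c(1, 0, 0))$percent, 33)
})

test_that("exact signed-rank p matches closed cases and drops zeros", {
  # n = 5 all-positive tie-free: p = 2/2^5
  res <- wilcoxon_signed_rank(c(3, 5, 4, 6, 8), c(1, 2, 3, 4, 5))
  expect_equal(res$statistic, 15)
  expect_equal(res$p_value, 0.0625)
  # antisymmetric differences sit at the null mean: p about 1
  res2 <- wilcoxon_signed_rank(c(1, -1, 2, -2), c(0, 0, 0, 0))
  expect_gte(res2$p_value, 0.8)
  # zero differences are dropped
  res3 <- wilcoxon_signed_rank(c(2, 2, 5), c(2, 1, 3))
  expect_equal(res3$n_used, 2)
  expect_equal(res3$n_zero, 1)
  expect_error(wilcoxon_signed_rank(c(1, 2), c(1, 2)), "zero")
})

test_that("exact signed-rank equals full enumeration up to n = 12", {
  set.seed(123)
  for (n in c(4, 6, 9, 12)) {
    for (rep in 1:5) {
      case <- round(rnorm(n, 1, 2), 2)
      control <- round(rnorm(n, 0, 2), 2)
      if (all(case - control == 0)) next
      got <- wilcoxon_signed_rank(case, control, mode = "exact")
      expect_equal(got$p_value, oracle_wilcoxon_exact(case, control),
                   tolerance = 1e-12)
    }
  }
})

test_that("exact signed-rank handles ties with midranks like enumeration", {
  set.seed(9)
  for (rep in 1:10) {
    case <- sample(0:4, 8, replace = TRUE)
    control <- sample(0:4, 8, replace = TRUE)
    if (all(case - control == 0)) next
    got <- wilcoxon_signed_rank(case, control, mode = "exact")
    expect_equal(got$p_value, oracle_wilcoxon_exact(case, control),
                 tolerance = 1e-12)
  }
})

test_that("double-tail exact mode matches stats::wilcox.test on tie-free data", {
  set.seed(31)
  for (rep in 1:8) {
    case <- rnorm(10)
    control <- rnorm(10)
    got <- wilcoxon_signed_rank(case, control, mode = "exact",
                                two_sided = "double_tail")
    ref <- suppressWarnings(stats::wilcox.test(case, control, paired = TRUE,
                                               exact = TRUE))
    expect_equal(got$p_value, unname(ref$p.value), tolerance = 1e-10)
    expect_equal(got$statistic, unname(ref$statistic))
  }
})

test_that("normal approximation tracks the exact test for moderate n", {
  set.seed(7)
  for (rep in 1:6) {
    case <- rnorm(18, 0.4)
    control <- rnorm(18)
    ex <- wilcoxon_signed_rank(case, control, mode = "exact")
    ap <- wilcoxon_signed_rank(case, control, mode = "approximate")
    expect_lt(abs(ex$p_value - ap$p_value), 0.02)
  }
})
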