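# Downstream regressions: noiseless recovery, algebraic consistency, and
# agreement with lm()/confint() as an independent implementation.

make_cohort <- function(n = 200, seed = 1, ...) {
  simulate_cohort(cohort_sim_config(n = n, seed = seed, ...), icosphere(0))
}

test_that("fit summaries agree with lm() and confint() (independent oracle)", {
  co <- make_cohort(150, seed = 5)
  tab <- co$table
  tab$cluster_spc <- co$truth$cluster_spc
  fs <- fit_memory_model(tab, "cluster_spc")
  lmfit <- lm(memory ~ cluster_spc + age + female + apoe4 + entorhinal +
                test_gap, data = tab)
  ci <- confint(lmfit)
  got <- fs$coefficients
  expect_equal(got$b, unname(coef(lmfit)), tolerance = 1e-10)
  expect_equal(got$ci_lower, unname(ci[, 1]), tolerance = 1e-10)
  expect_equal(got$ci_upper, unname(ci[, 2]), tolerance = 1e-10)
  expect_equal(got$p, unname(summary(lmfit)$coefficients[, 4]),
               tolerance = 1e-10)
  expect_equal(fs$df, df.residual(lmfit))
  # standardized betas follow b * SD(x) / SD(y) on every non-intercept term
  for (i in seq_len(nrow(got))[-1])
    expect_equal(got$std_beta[i],
                 got$b[i] * sd(tab[[got$term[i]]]) / sd(tab$memory),
                 tolerance = 1e-12)
  expect_true(all(got$ci_lower <= got$b & got$b <= got$ci_upper))
})

test_that("planted interaction is recovered exactly without noise", {
  co <- make_cohort(250, seed = 9, spc_resid_sd = 0,
                    interaction = c(Black = -0.3, Hispanic = 0))
  tab <- co$table
  tab$cluster_spc <- co$truth$cluster_spc
  fs <- fit_interaction_model(tab, "cluster_spc", "wmh_parietal")
  b <- fs$coefficients
  expect_equal(b$b[b$term == "Black:wmh"], -0.3, tolerance = 1e-10)
  expect_equal(b$b[b$term == "Hispanic:wmh"], 0, tolerance = 1e-10)
  expect_equal(b$b[b$term == "wmh_parietal"], co$truth$cluster_wmh_slope,
               tolerance = 1e-10)
  # stratified slope in Black subjects = main effect + interaction, exactly
  fstrat <- fit_stratified(tab, "cluster_spc", "wmh_parietal", "Black")
  expect_equal(fstrat$coefficients$b[fstrat$coefficients$term == "wmh_parietal"],
               co$truth$cluster_wmh_slope - 0.3, tolerance = 1e-10)
  fw <- fit_stratified(tab, "cluster_spc", "wmh_parietal", "White")
  expect_equal(fw$coefficients$b[fw$coefficients$term == "wmh_parietal"],
               co$truth$cluster_wmh_slope, tolerance = 1e-10)
})

test_that("stratified table has one row per (measure, group) with CI and p", {
  co <- make_cohort(180, seed = 21)
  tab <- co$table
  tab$cluster_spc <- co$truth$cluster_spc
  st <- stratified_table(tab, c(planted = "cluster_spc"), "wmh_parietal")
  expect_equal(nrow(st), 3)
  expect_setequal(st$group, c("Black", "Hispanic", "White"))
  expect_true(all(st$ci_lower <= st$b & st$b <= st$ci_upper))
  expect_equal(sum(st$n), 180)
})

test_that("stratified standard errors shrink as the stratum grows", {
  co <- make_cohort(600, seed = 33)
  tab <- co$table
  tab$cluster_spc <- co$truth$cluster_spc
  black <- tab[tab$group == "Black", ]
  set.seed(1)
  sub30 <- black[sample(nrow(black), 30), ]
  se_of <- function(d) {
    fs <- fit_stratified(d, "cluster_spc", "wmh_parietal", "Black")
    fs$coefficients$se[fs$coefficients$term == "wmh_parietal"]
  }
  expect_gt(se_of(sub30), se_of(black))
})

test_that("covariate-set tags toggle the three specifications by config only", {
  expect_equal(covariate_set("primary"),
               c("age", "female", "apoe4", "entorhinal"))
  expect_equal(covariate_set("primary-minus-entorhinal"),
               c("age", "female", "apoe4"))
  expect_equal(covariate_set("primary-plus-education"),
               c("age", "female", "apoe4", "entorhinal", "education"))
  expect_error(covariate_set("robust"), "unknown covariate set")
  co <- make_cohort(120, seed = 3)
  tab <- co$table
  tab$cluster_spc <- co$truth$cluster_spc
  for (tag in c("primary", "primary-minus-entorhinal", "primary-plus-education")) {
    fs <- fit_memory_model(tab, "cluster_spc", tag)
    expect_setequal(fs$coefficients$term,
                    c("intercept", "cluster_spc", covariate_set(tag), "test_gap"))
  }
})

test_that("group-difference ANCOVA is exact on duplicated groups and calibrated under the null", {
  # three identical copies of one stratum -> no between-group variance
  co <- make_cohort(90, seed = 41)
  base <- co$table[1:30, ]
  dup <- rbind(base, base, base)
  dup$group <- factor(rep(c("White", "Hispanic", "Black"), each = 30),
                      levels = c("White", "Black", "Hispanic"))
  gd <- group_difference_tests(dup, "wmh_total")
  expect_lt(gd$F, 1e-10)
  expect_equal(gd$White_mean, gd$Black_mean)
  expect_equal(gd$White_sd, gd$Hispanic_sd)
  # empty / tiny group refuses
  solo <- co$table[co$table$group != "Black", ]
  expect_error(group_difference_tests(solo, "wmh_total"), ">= 2 subjects")
  # null calibration: groups drawn from one distribution
  set.seed(55)
  reps <- 300
  rej <- replicate(reps, {
    tb <- data.frame(age = rnorm(60), female = rbinom(60, 1, 0.5),
                     apoe4 = rbinom(60, 1, 0.3),
                     group = factor(sample(c("White", "Black", "Hispanic"),
                                           60, TRUE),
                                    levels = c("White", "Black", "Hispanic")),
                     y = rnorm(60))
    group_difference_tests(tb, "y")$p < 0.05
  })
  band <- 2.576 * sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(mean(rej) - 0.05), band + 1e-9)
})

test_that("strong group shifts are detected with near-certain power", {
  set.seed(77)
  n <- 100
  tb <- data.frame(age = rnorm(3 * n), female = rbinom(3 * n, 1, 0.5),
                   apoe4 = rbinom(3 * n, 1, 0.3),
                   group = factor(rep(c("White", "Black", "Hispanic"), each = n),
                                  levels = c("White", "Black", "Hispanic")))
  tb$y <- rnorm(3 * n) + 2 * (tb$group == "Black")
  expect_lt(group_difference_tests(tb, "y")$p, 1e-6)
})

test_that("degenerate strata are rejected in the interaction model", {
  co <- make_cohort(100, seed = 61)
  tab <- co$table
  tab$cluster_spc <- co$truth$cluster_spc
  tab$wmh_parietal[tab$group == "Hispanic"] <- 2.5   # constant within stratum
  expect_error(fit_interaction_model(tab, "cluster_spc", "wmh_parietal"),
               "fewer than 2 distinct WMH values")
})
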