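# two-cage toy study built in code: 2 groups x 2 animals, 4 days
toy_study <- function(organ_a = c(45, 5), organ_b = c(20, 5),
                      urine1 = 40, injected = 100) {
  animals <- data.frame(animal_id = c("a1", "a2", "b1", "b2"),
                        group = c("g1", "g1", "g2", "g2"))
  organs <- data.frame(
    animal_id = rep(c("a1", "a2", "b1", "b2"), each = 2),
    compartment = rep(c("skeleton", "liver"), 4),
    activity_kBq = c(organ_a, organ_a, organ_b, organ_b))
  mk_exc <- function(cage, u1) data.frame(
    cage = cage, day = rep(1:4, 2),
    route = rep(c("urine", "feces"), each = 4),
    activity_kBq = c(u1, 2, 1, 1, 2, 1, 1, 1))
  balance_study(animals, organs, rbind(mk_exc("g1", urine1),
                                       mk_exc("g2", urine1)),
                injected_kBq = injected)
}

test_that("percent recovered dose is activity over recovered, excreta shared", {
  st <- toy_study()
  prd <- percent_recovered_dose(st)
  # animal a1: organs 50, cage excreta 49 shared across 2 animals -> 24.5
  tot <- 50 + 24.5
  expect_equal(prd$pct_rd[prd$animal_id == "a1" & prd$compartment == "skeleton"],
               45 / tot * 100)
  expect_equal(prd$pct_rd[prd$animal_id == "a1" & prd$compartment == "liver"],
               5 / tot * 100)
  # each animal's compartments sum to exactly 100
  sums <- tapply(prd$pct_rd, prd$animal_id, sum)
  expect_equal(as.numeric(sums), rep(100, 4), tolerance = 1e-12)

  # single compartment holding everything -> 100%
  one <- balance_study(
    data.frame(animal_id = "x1", group = "g"),
    data.frame(animal_id = "x1", compartment = "skeleton", activity_kBq = 7),
    data.frame(cage = "g", day = rep(1:4, 2),
               route = rep(c("urine", "feces"), each = 4), activity_kBq = 0),
    injected_kBq = 7)
  prd1 <- percent_recovered_dose(one)
  expect_equal(prd1$pct_rd[prd1$compartment == "skeleton"], 100)

  # zero recovery is an error
  zero <- one; zero$organs$activity_kBq <- 0
  expect_error(percent_recovered_dose(zero), "zero recovered")
})

test_that("recovery check flags groups under 90% of injected dose", {
  st <- toy_study()  # g1: (100 organs + 49 excreta)/200 = 74.5% -> flagged
  rc <- recovery_check(st)
  expect_equal(rc$recovery_pct[rc$group == "g1"], 74.5)
  expect_true(all(rc$flagged))
  st2 <- toy_study(organ_a = c(70, 5), organ_b = c(70, 5))
  rc2 <- recovery_check(st2)
  expect_false(any(rc2$flagged))
  # recovered equals injected -> 100%
  st3 <- toy_study(organ_a = c(70.5, 5), organ_b = c(70.5, 5))
  expect_equal(recovery_check(st3)$recovery_pct, c(100, 100))
})

test_that("Dixon's Q implements the r10 gap-over-range statistic", {
  q <- dixon_q_test(c(0.060, 0.063, 0.065, 0.095))
  expect_equal(q$Q, (0.095 - 0.065) / (0.095 - 0.060), tolerance = 1e-12)
  expect_equal(q$Q, 0.857, tolerance = 1e-3)
  expect_equal(q$critical, 0.829)
  expect_equal(q$outlier_index, 4L)

  # symmetric two-sided: a low outlier is caught too
  ql <- dixon_q_test(c(0.030, 0.063, 0.065, 0.066))
  expect_equal(ql$outlier_index, 1L)

  # {1,2,3,4}: Q = 1/3, no outlier at 95%
  q2 <- dixon_q_test(c(1, 2, 3, 4))
  expect_equal(q2$Q, 1 / 3, tolerance = 1e-12)
  expect_null(q2$outlier_index)

  # identical values: zero range, Q defined as 0, no outlier
  q3 <- dixon_q_test(rep(2.5, 4))
  expect_identical(q3$Q, 0)
  expect_null(q3$outlier_index)

  # n outside 3..10
  expect_error(dixon_q_test(c(1, 2)), "3 <= n <= 10")
  expect_error(dixon_q_test(rnorm(11)), "3 <= n <= 10")

  # removal is idempotent: after one removal the remainder is clean
  v <- c(0.060, 0.063, 0.065, 0.095)
  q4 <- dixon_q_test(v[-dixon_q_test(v)$outlier_index])
  expect_null(q4$outlier_index)
})

test_that("one-way ANOVA matches the classical decomposition", {
  # {1,2,3} vs {4,5,6}: SSB = 13.5, SSW = 4, F = 13.5
  a <- one_way_anova(list(g1 = c(1, 2, 3), g2 = c(4, 5, 6)))
  expect_equal(a$F, 13.5, tolerance = 1e-12)
  expect_equal(a$p, stats::pf(13.5, 1, 4, lower.tail = FALSE))

  # equal constant groups: F = 0, p = 1
  z <- one_way_anova(list(g1 = c(2, 2), g2 = c(2, 2)))
  expect_identical(z$F, 0)
  expect_identical(z$p, 1)

  # cross-check against stats::oneway.test on random data
  set.seed(11)
  g <- list(a = rnorm(5), b = rnorm(6, 1), c = rnorm(4, -0.5))
  mine <- one_way_anova(g)
  ref <- stats::oneway.test(
    value ~ group,
    data.frame(value = unlist(g), group = rep(names(g), lengths(g))),
    var.equal = TRUE)
  expect_equal(mine$F, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(mine$p, unname(ref$p.value), tolerance = 1e-10)

  expect_error(one_way_anova(list(a = 1, b = c(1, 2))), "n >= 2")
})

test_that("ANOVA F is invariant under shift and scale of the data", {
  set.seed(3)
  g <- list(a = rnorm(4), b = rnorm(4, 2), c = rnorm(4, 1))
  f0 <- one_way_anova(g)$F
  expect_equal(one_way_anova(lapply(g, `+`, 100))$F, f0, tolerance = 1e-9)
  expect_equal(one_way_anova(lapply(g, `*`, 7.3))$F, f0, tolerance = 1e-9)
})

test_that("Dunnett comparisons are adjusted and agree with multcomp", {
  # treatment identical to control: adjusted p ~ 1
  same <- dunnett_vs_control(list(ctrl = c(1, 2, 3, 4), t1 = c(1, 2, 3, 4),
                                  t2 = c(5, 6, 7, 8)), "ctrl")
  expect_gt(same$p_adj[same$group == "t1"], 0.99)

  # multiplicity: adjusted p >= per-comparison t-test p
  set.seed(21)
  for (rep in 1:10) {
    g <- list(ctrl = rnorm(4), a = rnorm(4, 0.8), b = rnorm(4, -0.5),
              c = rnorm(4))
    d <- dunnett_vs_control(g, "ctrl")
    praw <- 2 * stats::pt(abs(d$t), d$df, lower.tail = FALSE)
    expect_true(all(d$p_adj >= praw - 1e-9))
  }

  # numerical agreement with multcomp::glht (independent implementation)
  set.seed(77)
  g <- list(ctrl = rnorm(5), a = rnorm(4, 1), b = rnorm(6, -1), c = rnorm(4))
  d <- dunnett_vs_control(g, "ctrl")
  df <- data.frame(value = unlist(g),
                   group = factor(rep(names(g), lengths(g)),
                                  levels = names(g)))
  mc <- summary(multcomp::glht(stats::aov(value ~ group, df),
                               linfct = multcomp::mcp(group = "Dunnett")))
  expect_equal(d$p_adj, as.numeric(mc$test$pvalues), tolerance = 2e-3)

  expect_error(dunnett_vs_control(list(a = 1:3, b = 1:3), "ctrl"),
               "control group")
})

test_that("Tukey all-pairs p-values match TukeyHSD", {
  two <- tukey_pairwise(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_gt(two$p_adj, 0.99)

  set.seed(13)
  g <- list(a = rnorm(4), b = rnorm(5, 1.5), c = rnorm(4, -1))
  tk <- tukey_pairwise(g)
  df <- data.frame(value = unlist(g),
                   group = factor(rep(names(g), lengths(g))))
  ref <- stats::TukeyHSD(stats::aov(value ~ group, df))$group
  expect_equal(tk$p_adj, unname(ref[, "p adj"]), tolerance = 1e-9)

  # multiplicity: Tukey p >= the unadjusted p of the same pooled statistic
  praw <- 2 * stats::pt(tk$q / sqrt(2), tk$df, lower.tail = FALSE)
  expect_true(all(tk$p_adj >= praw - 1e-9))
  expect_true(all(tk$p_adj >= 0 & tk$p_adj <= 1))
})

test_that("excretion time course closes the balance identity", {
  st <- toy_study()
  tc <- excretion_timecourse(st)
  expect_equal(tc$totals$retained_pct + tc$totals$excreted_pct,
               c(100, 100), tolerance = 1e-12)
  d1 <- tc$daily[tc$daily$group == "g1" & tc$daily$day == 1, ]
  expect_equal(sum(d1$pct_rd), (40 + 2) / 149 * 100, tolerance = 1e-12)
  cum4 <- tc$daily[tc$daily$group == "g1" & tc$daily$day == 4, "cum_pct_rd"]
  expect_equal(sum(cum4), tc$totals$excreted_pct[tc$totals$group == "g1"],
               tolerance = 1e-12)

  # all activity retained -> zero excretion every day
  ret <- toy_study(urine1 = 0)
  ret$excreta$activity_kBq <- 0
  tc0 <- excretion_timecourse(ret)
  expect_true(all(tc0$daily$pct_rd == 0))
  expect_equal(tc0$totals$retained_pct, c(100, 100))

  # missing day refuses to compute
  broken <- toy_study()
  expect_error(balance_study(broken$animals, broken$organs,
                             broken$excreta[broken$excreta$day != 3, ],
                             injected_kBq = 100),
               "incomplete excreta")
})

test_that("balance studies round-trip through the delimited-text format", {
  st <- generate_balance_study(generator_config(seed = 3))
  rec <- withr::local_tempfile(fileext = ".tsv")
  man <- withr::local_tempfile(fileext = ".yml")
  write_balance_study(st, rec, man)
  back <- read_balance_study(rec, man)
  expect_equal(back$organs$activity_kBq, st$organs$activity_kBq)
  expect_setequal(back$animals$animal_id, st$animals$animal_id)
  key <- function(x) x$excreta[order(x$excreta$cage, x$excreta$day,
                                     x$excreta$route), "activity_kBq"]
  expect_equal(key(back), key(st))
  expect_equal(unname(back$injected_kBq), unname(st$injected_kBq))
  # identical %RD tables either way
  expect_equal(percent_recovered_dose(back)$pct_rd,
               percent_recovered_dose(st)$pct_rd)
})

test_that("group summary conserves %RD and records outliers", {
  st <- generate_balance_study(generator_config(seed = 8))
  gs <- summarize_groups(st)
  expect_equal(gs$totals$retained_pct + gs$totals$excreted_pct,
               rep(100, nrow(gs$totals)), tolerance = 1e-9)
  # per-animal basis closes too: retained mean + mean excreta share = 100
  prd <- percent_recovered_dose(st)
  sums <- tapply(prd$pct_rd, prd$animal_id, sum)
  expect_equal(as.numeric(sums), rep(100, length(sums)), tolerance = 1e-9)
})
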