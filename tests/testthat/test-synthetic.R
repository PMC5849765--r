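test_that("the generator is deterministic under a fixed seed", {
  a <- generate_balance_study(generator_config(seed = 314))
  b <- generate_balance_study(generator_config(seed = 314))
  expect_identical(a$organs, b$organs)
  expect_identical(a$excreta, b$excreta)
  c <- generate_balance_study(generator_config(seed = 315))
  expect_false(identical(a$organs$activity_kBq, c$organs$activity_kBq))
})

test_that("degenerate noise puts every animal exactly at the group means", {
  # zero compartment SDs plus a degenerate recovery interval: with pooled
  # cage excreta, per-animal %RD is exact only when recovery is also common
  st <- generate_balance_study(
    generator_config(seed = 1, sd_scale = 0, recovery_range = c(0.95, 0.95)))
  prd <- percent_recovered_dose(st)
  gt <- default_group_table()$compartments
  for (g in c("control", "HOPO_-1h", "DTPA_-1h")) {
    for (cp in c("skeleton", "liver", "kidneys", "brain")) {
      vals <- prd$pct_rd[prd$group == g & prd$compartment == cp]
      ref <- gt$mean_pct[gt$group == g & gt$compartment == cp]
      expect_equal(vals, rep(ref, length(vals)), tolerance = 1e-12,
                   label = paste(g, cp))
    }
  }
})

test_that("generated recovery fractions stay inside the configured range", {
  cfg <- generator_config(seed = 2, recovery_range = c(0.92, 0.99))
  st <- generate_balance_study(cfg)
  an <- st$animals
  for (g in unique(an$group)) {
    ids <- an$animal_id[an$group == g]
    rec <- (sum(st$organs$activity_kBq[st$organs$animal_id %in% ids]) +
              sum(st$excreta$activity_kBq[st$excreta$cage == g])) /
      sum(st$injected_kBq[ids])
    expect_gte(rec, 0.92)
    expect_lte(rec, 0.99)
  }
})

test_that("pipeline means converge to configured means at large n", {
  cfg <- generator_config(seed = 9, n_per_group = 1000,
                          groups = c("control", "HOPO_-1h"))
  st <- generate_balance_study(cfg)
  prd <- percent_recovered_dose(st)
  gt <- default_group_table()$compartments
  for (g in cfg$groups) {
    for (cp in c("skeleton", "liver", "kidneys")) {
      vals <- prd$pct_rd[prd$group == g & prd$compartment == cp]
      ref <- gt$mean_pct[gt$group == g & gt$compartment == cp]
      sd_ref <- gt$sd_pct[gt$group == g & gt$compartment == cp]
      # %RD normalization rescales draws by the animal's recovered total,
      # a < 1% distortion at these SDs; 3 SE plus that margin
      tol <- 3 * sd_ref / sqrt(length(vals)) + 0.01 * ref
      expect_lt(abs(mean(vals) - ref), tol + 1e-9,
                label = paste(g, cp))
    }
  }
})

test_that("generator defaults reproduce the study's printed anchor values", {
  st <- generate_balance_study(generator_config(seed = 6, n_per_group = 200))
  prd <- percent_recovered_dose(st)
  ctl <- function(cp) mean(prd$pct_rd[prd$group == "control" &
                                        prd$compartment == cp])
  expect_equal(ctl("skeleton"), 41, tolerance = 0.02)
  expect_equal(ctl("liver"), 11, tolerance = 0.02)
  expect_equal(ctl("kidneys"), 0.62, tolerance = 0.05)

  tc <- excretion_timecourse(st)
  d1 <- tc$daily[tc$daily$group == "control" & tc$daily$day == 1, ]
  expect_equal(sum(d1$pct_rd), 34.4, tolerance = 0.05)
  expect_equal(d1$pct_rd[d1$route == "urine"] / sum(d1$pct_rd), 0.95,
               tolerance = 0.01)

  ret <- tapply(prd$pct_rd[!grepl("day", prd$compartment)],
                prd$group[!grepl("day", prd$compartment)], sum) / 200
  expect_equal(unname(ret[["HOPO_-1h"]]), 1.04, tolerance = 0.05)
})

test_that("treatment effects register in ANOVA but not in matched kidneys", {
  st <- generate_balance_study(generator_config(seed = 10))
  prd <- percent_recovered_dose(st)
  organ <- prd[!grepl("^(urine|feces)_day", prd$compartment), ]
  # total-body retention per animal, grouped
  tot <- stats::aggregate(pct_rd ~ animal_id + group, organ, sum)
  a <- one_way_anova(split(tot$pct_rd, tot$group))
  expect_lt(a$p, 0.001)
  # kidney burdens of the two 1 h pre-treatments are indistinguishable
  kid <- organ[organ$compartment == "kidneys", ]
  tk <- tukey_pairwise(split(kid$pct_rd, kid$group))
  pair <- tk[(tk$group1 == "DTPA_-1h" & tk$group2 == "HOPO_-1h") |
               (tk$group1 == "HOPO_-1h" & tk$group2 == "DTPA_-1h"), ]
  expect_gt(pair$p_adj, 0.001)
})

test_that("impossible configurations are rejected", {
  gt <- default_group_table()
  gt$compartments$mean_pct[gt$compartments$group == "control"] <- 15
  expect_error(generator_config(group_table = gt), "sum above 100")
  expect_error(generator_config(recovery_range = c(0.5, 1.2)), "within \\(0, 1]")
  expect_error(generator_config(groups = "nope"), "unknown group")
})

test_that("the planted brain outlier is flagged by the Q screen", {
  st <- generate_balance_study(generator_config(seed = 4, brain_outlier = TRUE))
  gs <- summarize_groups(st)
  hit <- gs$outliers[gs$outliers$group == "control" &
                       gs$outliers$compartment == "brain", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$animal_id, "control_01")
  expect_gt(hit$Q, hit$critical)
  # and the corrected mean moves back toward the configured 0.063
  bm <- gs$compartments[gs$compartments$group == "control" &
                          gs$compartments$compartment == "brain", ]
  expect_equal(bm$n, 3L)
  expect_lt(abs(bm$mean_pct - 0.063), 0.01)
})

test_that("random thermodynamic systems are reproducible and bounded", {
  a <- generate_random_thermo_system(5)
  b <- generate_random_thermo_system(5)
  expect_identical(a$table$species, b$table$species)
  expect_identical(a$problem$totals, b$problem$totals)

  expect_error(generate_random_thermo_system(1, n_components = 4))
  expect_error(generate_random_thermo_system(1, n_species = 7))

  # free-ions-only problem
  s0 <- generate_random_thermo_system(3, n_species = 0)
  expect_equal(count_equilibria(s0$problem), 0L)
  sol <- solve_equilibrium(s0$problem)
  expect_identical(unname(sol$free[s0$problem$components]),
                   unname(s0$problem$totals))

  for (seed in 1:20) {
    sys <- generate_random_thermo_system(seed)
    expect_true(all(sys$table$species$log_beta >= 2 &
                      sys$table$species$log_beta <= 25))
    expect_true(all(sys$problem$totals >= 1e-9 & sys$problem$totals <= 1e-2))
    expect_true(all(sys$table$stoich %in% 0:2))
  }
})
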