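# ANOVA decomposition, effect sizes, ranking, outliers.

make_design <- function(a = 2, b = 3, n = 4, seed = 1, sd = 1,
                        interaction = 0) {
  set.seed(seed)
  d <- expand.grid(group = paste0("g", seq_len(a)),
                   timepoint = seq_len(b), rep = seq_len(n))
  d$response <- rnorm(nrow(d), sd = sd) +
    interaction * (d$group == "g1") * scale(d$timepoint)[, 1]
  d
}

test_that("two_way_anova matches the hand-computed 2x2 cell-means case", {
  d <- data.frame(group = rep(c("a", "b"), each = 4),
                  timepoint = rep(c(1, 2, 1, 2), each = 2),
                  response = c(10, 10, 10, 10, 10, 10, 20, 20))
  dec <- two_way_anova(d)
  # cell means 10,10,10,20 (n=2 each); grand mean 12.5
  # SS_total = 6*(2.5)^2 + 2*(7.5)^2 = 150
  # SS_A = SS_B = 4*(2.5)^2 + 4*(2.5)^2 = 50 (marginal means 10 vs 15)
  # SS_cells = 3*2*(2.5)^2 + 2*(7.5)^2 = 150, so SS_AB = 150 - 50 - 50 = 50
  # (interaction contrast (y11 - y12 - y21 + y22) = 10, n/4 * 10^2 * 2 = 50)
  expect_equal(dec$SS_total, 150)
  expect_equal(dec$SS_A, 50)
  expect_equal(dec$SS_B, 50)
  expect_equal(dec$SS_effect, 50)
  expect_equal(dec$SS_error, 0)
  expect_equal(dec$DF_effect, 1L)
  # all-equal responses: all SS zero
  dz <- transform(d, response = 7)
  decz <- two_way_anova(dz)
  expect_equal(decz$SS_total, 0)
  expect_equal(decz$SS_effect, 0)
})

test_that("balanced decompositions match the regression oracle to 1e-9", {
  for (seed in 1:10) {
    d <- make_design(a = 2 + seed %% 2, b = 3, n = 2 + seed %% 3,
                     seed = seed, sd = 2, interaction = seed %% 2)
    dec <- two_way_anova(d)
    orc <- oracle_anova_lm(d)
    for (f in c("SS_A", "SS_B", "SS_effect", "SS_error")) {
      expect_equal(dec[[f]], orc[[f]], tolerance = 1e-9)
    }
    expect_identical(dec$DF_effect, orc$DF_effect)
    expect_identical(dec$DF_error, orc$DF_error)
    # partition identity
    expect_equal(dec$SS_A + dec$SS_B + dec$SS_effect + dec$SS_error,
                 dec$SS_total, tolerance = 1e-9)
  }
})

test_that("two_way_anova validates its design", {
  d <- make_design()
  expect_error(two_way_anova(d[d$group == "g1", ]), ">= 2 levels")
  expect_error(two_way_anova(d[!(d$group == "g1" & d$timepoint == 2), ]),
               "empty cell")
  d1 <- make_design(n = 1)
  expect_warning(dec <- two_way_anova(d1), "single replicate")
  expect_true(dec$single_replicate)
  expect_true(is.na(dec$MS_error))
  # unbalanced designs are flagged
  expect_false(two_way_anova(make_design()[-1, ])$balanced)
})

test_that("effect sizes follow the printed equations", {
  d <- structure(list(SS_effect = 20, SS_error = 60, SS_total = 100,
                      DF_effect = 2L, DF_error = 12L, MS_error = 5),
                 class = "anova_decomposition")
  es <- effect_sizes(d)
  expect_equal(es$eta2, 0.2)
  expect_equal(es$partial_eta2, 20 / 160)         # SS_eff/(SS_tot+SS_err)
  expect_equal(es$partial_eta2_classical, 0.25)   # SS_eff/(SS_eff+SS_err)
  expect_equal(es$omega2, (20 - 2 * 5) / 105)
  expect_true(es$large_eta2)
  # zero effect: eta2 = 0 and omega2 forced negative by the equation
  d0 <- structure(list(SS_effect = 0, SS_error = 60, SS_total = 100,
                       DF_effect = 2L, DF_error = 12L, MS_error = 5),
                  class = "anova_decomposition")
  es0 <- effect_sizes(d0)
  expect_equal(es0$eta2, 0)
  expect_equal(es0$partial_eta2, 0)
  expect_lt(es0$omega2, 0)
  # zero-error limit: eta2 = classical partial = 1
  d1 <- structure(list(SS_effect = 50, SS_error = 0, SS_total = 50,
                       DF_effect = 1L, DF_error = 10L, MS_error = 0),
                  class = "anova_decomposition")
  es1 <- effect_sizes(d1)
  expect_equal(es1$eta2, 1)
  expect_equal(es1$partial_eta2_classical, 1)
  # undefined for a constant response
  dz <- structure(list(SS_effect = 0, SS_error = 0, SS_total = 0,
                       DF_effect = 1L, DF_error = 4L, MS_error = 0),
                  class = "anova_decomposition")
  expect_error(effect_sizes(dz), "SS_total")
})

test_that("effect-size invariants hold on randomized balanced tables", {
  for (seed in 1:25) {
    d <- make_design(a = 2, b = 3, n = 5, seed = 100 + seed, sd = 1,
                     interaction = (seed %% 3) / 2)
    es <- effect_sizes(two_way_anova(d))
    expect_gte(es$eta2, 0); expect_lte(es$eta2, 1)
    expect_lte(es$partial_eta2, es$eta2)            # printed denominator
    expect_gte(es$partial_eta2_classical, es$eta2)  # classical bound
    expect_lte(es$omega2, es$eta2)
    # invariance to shift and positive scaling
    d2 <- transform(d, response = 3 * response + 40)
    es2 <- effect_sizes(two_way_anova(d2))
    expect_equal(es2$eta2, es$eta2, tolerance = 1e-9)
    expect_equal(es2$omega2, es$omega2, tolerance = 1e-9)
  }
})

test_that("stronger interactions never lower eta-squared", {
  base <- make_design(seed = 9, sd = 1, interaction = 0)
  contrast <- (base$group == "g1") * scale(base$timepoint)[, 1]
  prev <- -Inf
  for (k in c(0, 0.5, 1, 2, 4)) {
    d <- transform(base, response = response + k * contrast)
    e <- effect_sizes(two_way_anova(d))$eta2
    expect_gte(e, prev - 1e-12)
    prev <- e
  }
})

test_that("rank_biomarkers puts the programmed responder first", {
  set.seed(5)
  bones <- c("Tal", "Calc", "Cub", "Tib")
  rows <- list()
  for (b in bones) {
    d <- expand.grid(group = c("placebo", "antiTNF"), timepoint = c(0, 3, 6),
                     rep = 1:6)
    d$response <- 1 + 0.05 * d$timepoint + rnorm(nrow(d), sd = 0.1)
    if (b == "Tal") {
      d$response <- d$response +
        0.3 * d$timepoint * (d$group == "antiTNF")
    }
    rows[[b]] <- cbind(bone = b, d)
  }
  tab <- do.call(rbind, rows)
  rk <- rank_biomarkers(tab)
  expect_identical(rk$bone[1], "Tal")
  expect_true(rk$large_eta2[1])
  expect_true(all(!rk$large_eta2[-1]))
  # identical responses for all bones -> equal eta2, catalog-order ranking
  flat <- tab
  one <- tab[tab$bone == "Tal", ]
  flat <- do.call(rbind, lapply(bones, function(b)
    transform(one, bone = b)))
  rf <- rank_biomarkers(flat)
  expect_equal(length(unique(round(rf$eta2, 12))), 1L)
  expect_identical(rf$bone, c("Calc", "Tal", "Tib", "Cub"))  # catalog order
})

test_that("outlier flagging hits planted spikes and controls false positives", {
  x <- c(rep(10, 19), 50)
  fl <- flag_outliers(x)
  expect_true(fl$outlier[20])
  expect_equal(sum(fl$outlier), 1L)
  # n=3 violates the precondition
  expect_error(flag_outliers(c(1, 2, 3)), ">= 4")
  # MAD 0 -> warning, nothing flagged
  expect_warning(f0 <- flag_outliers(rep(2, 6)), "MAD")
  expect_false(any(f0$outlier))
  # standard-normal sample: flagged fraction stays near the 1% target
  set.seed(11)
  fn <- flag_outliers(rnorm(1000), q_target = 0.01)
  expect_lte(mean(fn$outlier), 0.02)
})
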