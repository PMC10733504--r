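test_that("perturbation renormalises probability blocks and clips spans", {
  p <- default_parameters()
  pm <- perturb_parameter(p, "p.med_art", 0.5)
  blk <- c("p.med_art", "p.med_amnio", "p.med_natural", "p.med_none")
  expect_equal(sum(pm$values[blk]), 1, tolerance = 1e-12)
  expect_equal(unname(pm$values[["p.med_art"]]), 0.5)
  # siblings keep their relative proportions
  expect_equal(pm$values[["p.med_amnio"]] / pm$values[["p.med_natural"]],
               p$values[["p.med_amnio"]] / p$values[["p.med_natural"]])
  expect_warning(perturb_parameter(p, "p.high_birth", 1.2), "clipped")
  # every block still sums to one after a sweep of random perturbations
  set.seed(42)
  meta <- p$meta
  prob_ids <- meta$id[meta$kind == "probability"]
  for (id in sample(prob_ids, 10)) {
    pv <- perturb_parameter(p, id, runif(1))
    for (b in unique(na.omit(meta$block))) {
      ids <- meta$id[!is.na(meta$block) & meta$block == b]
      expect_lt(abs(sum(pv$values[ids]) - 1), 1e-9)
    }
  }
})

test_that("span rule follows provenance and zero span is an identity", {
  p <- default_parameters()
  expect_equal(dsa_span(p, "c.art_pgt")$span, 0.20)        # survey
  expect_equal(dsa_span(p, "c.reproductive")$span, 0.10)   # literature
  expect_equal(dsa_span(p, "p.deaf_medlow_natural")$span, 0.10)  # mendelian
  ow <- one_way(p, "c.amniocentesis", "healthy",
                span = list(low = 2686.60, high = 2686.60))
  expect_equal(ow$icer_low, ow$icer_base)
  expect_equal(ow$icer_high, ow$icer_base)
  expect_identical(ow$swing, 0)
})

test_that("ICER falls as medium-risk ART uptake rises", {
  p <- default_parameters()
  ow <- one_way(p, "p.med_art", "healthy")
  expect_gt(ow$icer_low, ow$icer_base)
  expect_gt(ow$icer_base, ow$icer_high)
})

test_that("reproductive cost cancels from the deaf-model incremental effect", {
  p <- default_parameters()
  for (value in c(651 * 0.8, 651 * 1.2)) {
    pv <- perturb_parameter(p, "c.reproductive", value)
    r <- run_model(pv, "deaf")
    # effect deltas untouched; cost delta driven only by differential birth
    # mass (verified against the brute-force enumerator)
    expect_equal(r$comparison$delta_eff,
                 run_model(p, "deaf")$comparison$delta_eff,
                 tolerance = 1e-12)
    sc <- build_screening_tree(pv, "deaf")
    sq <- build_status_quo_tree(pv, "deaf")
    expect_equal(r$comparison$delta_cost,
                 oracle_expected(sc, "cost") - oracle_expected(sq, "cost"),
                 tolerance = 1e-12)
  }
})

test_that("tornado covers each requested parameter once, sorted by swing", {
  p <- default_parameters()
  ids <- c("c.art_pgt", "c.amniocentesis", "p.med_art", "p.high_birth",
           "c.screening.test")
  tor <- tornado(p, ids, "healthy")
  expect_setequal(tor$id, ids)
  expect_identical(anyDuplicated(tor$id), 0L)
  expect_true(all(diff(tor$swing) <= 0))
  single <- tornado(p, "c.art_pgt", "healthy")
  expect_identical(nrow(single), 1L)
  # full default set completes with every ICER finite or tagged dominated
  full <- tornado(p, variant = "deaf")
  expect_true(all(is.finite(full$icer_base) | is.na(full$icer_base)))
})

test_that("ART-uptake sweep passes through the base case and forced branches", {
  p <- default_parameters()
  sw <- art_uptake_sweep(p, grid = c(0, 0.1774, 0.5, 1))
  base_row <- sw$curve[sw$curve$uptake == 0.1774, ]
  r <- run_model(p, "healthy")
  expect_equal(base_row$incr_healthy, r$comparison$delta_eff,
               tolerance = 1e-9)
  expect_equal(base_row$incr_cost, r$comparison$delta_cost,
               tolerance = 1e-9)
  # u = 1: all medium-risk couples take ART, so their deaf probability is
  # the post-ART one
  p1 <- load_parameters(list(p.med_art = 1, p.med_amnio = 0,
                             p.med_natural = 0, p.med_none = 0,
                             p.wife_bi = 0, p.wife_mono = 1, p.wife_neg = 0,
                             p.husband_bi = 0, p.husband_mono = 1,
                             p.husband_neg = 0))
  sc <- strategy_result(build_screening_tree(p1, "deaf"))
  expect_equal(sc$expected[["eff_deaf"]], p$values[["p.deaf_art"]],
               tolerance = 1e-12)
})

test_that("break-even uptake for positive incremental healthy births is near 17%", {
  sw <- art_uptake_sweep(default_parameters(), grid = c(0, 0.5, 1),
                         rule = "none_absorbing")
  expect_equal(sw$break_even_uptake, 0.174, tolerance = 0.02 / 0.174)
  # incremental healthy births increase monotonically in uptake
  fine <- art_uptake_sweep(default_parameters(),
                           grid = seq(0, 1, by = 0.1))$curve
  expect_true(all(diff(fine$incr_healthy) > 0))
  # proportional rule also brackets a nearby break-even
  swp <- art_uptake_sweep(default_parameters(), grid = c(0, 1),
                          rule = "proportional")
  expect_equal(swp$break_even_uptake, 0.16, tolerance = 0.2)
})

test_that("PSA sampling is reproducible, on-simplex, and moment-faithful", {
  p <- default_parameters()
  m1 <- sample_parameters(p, 2000, seed = 99)
  m2 <- sample_parameters(p, 2000, seed = 99)
  expect_identical(m1, m2)
  blk <- c("p.med_art", "p.med_amnio", "p.med_natural", "p.med_none")
  expect_true(all(abs(rowSums(m1[, blk]) - 1) < 1e-12))
  expect_true(all(m1[, blk] >= 0))
  pairs <- m1[, "p.high_birth"] + m1[, "p.high_none"]
  expect_true(all(abs(pairs - 1) < 1e-12))
  # gamma draws: sample mean of ART cost within 3 SE of the base value
  x <- m1[, "c.art_pgt"]
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - 11940.30), 3 * se)
})

test_that("cv -> 0 PSA reproduces the deterministic comparison on every draw", {
  p <- default_parameters()
  spec0 <- psa_spec(p, cv_cost = 0, cv_prob = 0)
  ps <- run_psa(p, "healthy", n = 25, seed = 5, spec = spec0)
  det <- run_model(p, "healthy")$comparison
  expect_true(all(ps$draws$delta_cost == det$delta_cost))
  expect_true(all(ps$draws$delta_eff == det$delta_eff))
})

test_that("CEAC matches a brute-force indicator recount and its endpoints", {
  one <- data.frame(delta_cost = -1, delta_eff = 0)
  expect_true(all(ceac(one, c(0, 1e6))$prob_ce == 1))
  one2 <- data.frame(delta_cost = 1, delta_eff = 0)
  expect_true(all(ceac(one2, c(0, 1e6))$prob_ce == 0))
  set.seed(31)
  draws <- data.frame(delta_cost = rnorm(4000), delta_eff = 1)
  cc <- ceac(draws, c(0, 0.5, 2))
  for (i in seq_len(nrow(cc))) {
    brute <- sum(cc$wtp[i] * draws$delta_eff - draws$delta_cost >= 0) /
      nrow(draws)
    expect_identical(cc$prob_ce[i], brute)
  }
  # dC ~ N(0,1), dE = 1: CEAC(w) follows the normal CDF
  expect_equal(cc$prob_ce[1], 0.5, tolerance = 0.05)
  expect_equal(cc$prob_ce[3], pnorm(2), tolerance = 0.02)
  # at wtp = 0 the CEAC is the fraction of cost-saving draws
  ps <- run_psa(default_parameters(), "healthy", n = 200, seed = 8,
                wtp_grid = c(0))
  expect_equal(ps$ceac$prob_ce[1], mean(ps$draws$delta_cost <= 0))
})

test_that("the 95% ellipse covers ~95% of bivariate normal draws", {
  set.seed(2024)
  n <- 10000
  z1 <- rnorm(n)
  z2 <- rnorm(n)
  draws <- data.frame(delta_eff = 0.001 * z1,
                      delta_cost = 100 + 50 * (0.6 * z1 + 0.8 * z2))
  ell <- psa_ellipse(draws)
  cover <- mean(in_ellipse(draws, ell))
  expect_lt(abs(cover - 0.95), 4 * sqrt(0.95 * 0.05 / n))
})

test_that("PSA output is bit-identical under the same seed", {
  p <- default_parameters()
  a <- run_psa(p, "deaf", n = 40, seed = 77)
  b <- run_psa(p, "deaf", n = 40, seed = 77)
  expect_identical(a$draws, b$draws)
  expect_identical(a$ceac, b$ceac)
})
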