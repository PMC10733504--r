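test_that("couples are classified into the four risk categories", {
  expect_identical(classify_couple("bi", "bi"), "high")
  expect_identical(classify_couple("bi", "mono"), "medium_high")
  expect_identical(classify_couple("mono", "bi"), "medium_high")
  expect_identical(classify_couple("mono", "mono"), "medium_low")
  expect_identical(classify_couple("neg", "untested"), "low")
  expect_identical(classify_couple("neg", "bi"), "low")
  expect_identical(classify_couple("mono", "neg"), "low")
  expect_error(classify_couple("bi", "untested"), "cascade violation")
})

test_that("base-case rollbacks reproduce the published strategy table", {
  p <- default_parameters()
  r_deaf <- run_model(p, "deaf")
  expect_equal(r_deaf$status_quo$expected[["eff_deaf"]], 0.0073,
               tolerance = 0.0001 / 0.0073)
  expect_equal(r_deaf$screening$expected[["eff_deaf"]], 0.0022,
               tolerance = 0.0001 / 0.0022)
  expect_equal(r_deaf$status_quo$expected[["cost"]], 651.00)
  expect_equal(r_deaf$screening$expected[["cost"]], 817.60,
               tolerance = 0.002)
  expect_equal(r_deaf$comparison$delta_eff, -0.0051, tolerance = 0.01)
  expect_identical(r_deaf$comparison$dominance, "alt_dominated")

  r_health <- run_model(p, "healthy")
  expect_equal(r_health$status_quo$expected[["eff_healthy"]], 0.9927,
               tolerance = 1e-4)
  expect_equal(r_health$screening$expected[["eff_healthy"]], 0.9928,
               tolerance = 1e-4)
  expect_equal(r_health$comparison$icer, 1203926.40, tolerance = 0.05)

  r_util <- run_model(p, "utility")
  expect_equal(r_util$status_quo$expected[["cost"]], -107615.66,
               tolerance = 1e-5)
  expect_equal(r_util$screening$expected[["cost"]], -107184.25,
               tolerance = 1e-4)
  expect_equal(r_util$status_quo$expected[["eff_utility"]], 22.09,
               tolerance = 1e-3)
  expect_equal(r_util$screening$expected[["eff_utility"]], 21.99,
               tolerance = 1e-3)
  expect_equal(r_util$comparison$delta_eff, -0.0995, tolerance = 0.01)
  expect_identical(r_util$comparison$dominance, "alt_dominated")
})

test_that("leaf cost accounting follows the path composition", {
  p <- default_parameters()
  v <- p$values
  paths <- enumerate_paths(build_screening_tree(p, "deaf"))
  # wife-negative healthy birth: one screen + reproductive cost only
  wn <- paths[paths$path == "wife_neg/healthy", ]
  expect_equal(wn$cost, 64.20 + 651.00)
  expect_equal(wn$eff_deaf, 0)
  # medium-risk no-children: two screens, nothing else
  nc <- paths[paths$path == "wife_mono/husband_mono/no_children", ]
  expect_equal(nc$cost, 2 * 64.20)
  expect_equal(nc$eff_healthy + nc$eff_deaf, 0)
  # ART path carries ART + productivity loss + reproductive cost
  art <- paths[paths$path == "wife_mono/husband_mono/art_pgt/healthy", ]
  expect_equal(art$cost, 2 * 64.20 + 11940.30 + 28.70 + 651.00)
  # amniocentesis-terminate carries amnio costs but no reproductive cost
  term <- paths[paths$path ==
    "wife_mono/husband_mono/amniocentesis/amnio_positive/terminate", ]
  expect_equal(term$cost, 2 * 64.20 + 2686.60 + 14.40)
  # utility variant: status-quo healthy birth nets lifetime financials
  pu <- enumerate_paths(build_status_quo_tree(p, "utility"))
  hb <- pu[pu$path == "low/healthy", ]
  expect_equal(hb$cost, 651.00 + 6961.40 - 115622.00)
  expect_equal(hb$eff_utility, 22.1)
})

test_that("outcome masses conserve probability and status quo has no childless path", {
  p <- default_parameters()
  sq <- strategy_result(build_status_quo_tree(p, "deaf"))
  sc <- strategy_result(build_screening_tree(p, "deaf"))
  expect_equal(sq$outcome_mass[["no_birth"]], 0)
  expect_equal(sum(sq$outcome_mass), 1, tolerance = 1e-9)
  expect_equal(sum(sc$outcome_mass), 1, tolerance = 1e-9)
  expect_gt(sc$outcome_mass[["no_birth"]], 0)
  expect_equal(sc$outcome_mass[["no_birth"]], 0.005, tolerance = 0.01)
})

test_that("degenerate all-negative prevalence collapses to pure screening overhead", {
  p <- load_parameters(list(p.wife_bi = 0, p.wife_mono = 0, p.wife_neg = 1))
  r <- run_model(p, "deaf")
  expect_equal(r$screening$expected[["eff_deaf"]],
               p$values[["p.deaf_low_natural"]])
  expect_equal(r$comparison$delta_eff, 0)
  expect_equal(r$comparison$delta_cost, per_person_screening_cost(p))
})

test_that("expected utility decomposes exactly over the outcome mass", {
  for (pset in list(default_parameters(),
                    load_parameters(list(p.med_art = 0.5, p.med_amnio = 0.3,
                                         p.med_natural = 0.1,
                                         p.med_none = 0.1)))) {
    sc <- strategy_result(build_screening_tree(pset, "utility"))
    v <- pset$values
    expect_equal(sc$expected[["eff_utility"]],
                 v[["u.healthy_qaly"]] * sc$outcome_mass[["healthy_birth"]] +
                 v[["u.deaf_qaly"]] * sc$outcome_mass[["deaf_birth"]],
                 tolerance = 1e-12)
  }
})

test_that("moving medium-risk mass to childlessness weakly lowers both birth masses", {
  p <- default_parameters()
  base <- strategy_result(build_screening_tree(p, "deaf"))$outcome_mass
  for (extra in c(0.1, 0.3, 0.8)) {
    pm <- perturb_parameter(p, "p.med_none",
                            p$values[["p.med_none"]] + extra)
    m <- strategy_result(build_screening_tree(pm, "deaf"))$outcome_mass
    expect_lte(m[["deaf_birth"]], base[["deaf_birth"]] + 1e-12)
    expect_lte(m[["healthy_birth"]], base[["healthy_birth"]] + 1e-12)
  }
})

test_that("run_model outputs match exhaustive enumeration to 1e-12", {
  p <- default_parameters()
  for (v in c("deaf", "healthy", "utility")) {
    r <- run_model(p, v)
    for (tree in list(build_status_quo_tree(p, v),
                      build_screening_tree(p, v))) {
      sr <- if (tree$strategy_name == "status_quo") r$status_quo
            else r$screening
      for (key in c("cost", "eff_deaf", "eff_healthy", "eff_utility")) {
        expect_equal(sr$expected[[key]], oracle_expected(tree, key),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("families needed inverts the incremental effect", {
  p <- default_parameters()
  expect_equal(run_model(p, "deaf")$families_needed, 196)
  expect_equal(run_model(p, "healthy")$families_needed, 7226,
               tolerance = 0.05)
  fake <- structure(list(delta_eff = 1, delta_cost = 0),
                    class = "cea_comparison")
  expect_identical(families_needed(fake), 1)
  fake0 <- structure(list(delta_eff = 0, delta_cost = 1),
                     class = "cea_comparison")
  expect_error(families_needed(fake0), "undefined")
})

test_that("same-gene concordance factor defaults to 1 and rescales joint mass", {
  p <- default_parameters()
  base <- strategy_result(build_screening_tree(p, "deaf"))
  again <- strategy_result(build_screening_tree(p, "deaf", concordance = 1))
  expect_identical(base$expected, again$expected)
  up <- strategy_result(build_screening_tree(p, "deaf", concordance = 1.5))
  expect_gt(up$expected[["eff_deaf"]], base$expected[["eff_deaf"]])
  expect_equal(sum(up$outcome_mass), 1, tolerance = 1e-9)
})
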