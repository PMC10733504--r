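# Builds the status-quo and two-step screening strategy trees from a
# parameter set, for each of the three payoff models, and reproduces the
# base-case cost-effectiveness table.

MODEL_VARIANTS <- c("deaf", "healthy", "utility")

variant_eff_key <- function(variant) {
  switch(match.arg(variant, MODEL_VARIANTS),
         deaf = "eff_deaf", healthy = "eff_healthy", utility = "eff_utility")
}

#' Classify a couple into a deafness risk category
#'
#' Two-step cascade: the husband is genotyped only when the wife screens
#' positive, so an untested husband is only legal for a screen-negative
#' wife.
#'
#' @param wife,husband Genotype: `"bi"` (bi-allelic), `"mono"`
#'   (mono-allelic), `"neg"` (wild-type / screen-negative); `husband` may be
#'   `"untested"`.
#' @return One of `"high"`, `"medium_high"`, `"medium_low"`, `"low"`.
#' @export
classify_couple <- function(wife, husband = "untested") {
  wife <- match.arg(wife, c("bi", "mono", "neg"))
  husband <- match.arg(husband, c("bi", "mono", "neg", "untested"))
  if (husband == "untested") {
    if (wife != "neg") {
      stop("cascade violation: husband untested while wife screened positive",
           call. = FALSE)
    }
    return("low")
  }
  if (wife == "neg" || husband == "neg") return("low")
  if (wife == "bi" && husband == "bi") return("high")
  if (wife == "mono" && husband == "mono") return("medium_low")
  "medium_high"
}

# Leaf constructors. `sunk` is the cost accumulated before the outcome
# (screening tests, ART/amniocentesis and productivity losses). A birth adds
# the reproductive cost; under the utility variant it also adds the born
# individual's discounted lifetime medical expenditure minus lifetime income.
make_leaf <- function(outcome, sunk, v, variant) {
  if (outcome == "no_birth") {
    return(terminal_node("no_birth", cost = sunk, eff_utility = 0))
  }
  cost <- sunk + v[["c.reproductive"]]
  if (variant == "utility") {
    if (outcome == "healthy_birth") {
      cost <- cost + v[["c.future_medical_healthy"]] -
        v[["c.future_income_healthy"]]
    } else {
      cost <- cost + v[["c.future_medical_disabled"]] -
        v[["c.future_income_disabled"]]
    }
  }
  utility <- if (outcome == "healthy_birth") v[["u.healthy_qaly"]]
             else v[["u.deaf_qaly"]]
  terminal_node(outcome, cost = cost, eff_utility = utility)
}

# Chance node over deaf vs healthy birth.
birth_node <- function(p_deaf, sunk, v, variant) {
  chance_node(
    branch(p_deaf, make_leaf("deaf_birth", sunk, v, variant), "deaf"),
    branch(1 - p_deaf, make_leaf("healthy_birth", sunk, v, variant),
           "healthy"))
}

# Joint risk-category mass under independent wife x husband genotypes
# (products of the Table of marginal frequencies; no same-gene adjustment by
# default, `concordance` scales the positive x positive joint mass).
category_mass <- function(v, concordance = 1) {
  high <- concordance * v[["p.wife_bi"]] * v[["p.husband_bi"]]
  medium_high <- concordance *
    (v[["p.wife_bi"]] * v[["p.husband_mono"]] +
     v[["p.wife_mono"]] * v[["p.husband_bi"]])
  medium_low <- concordance * v[["p.wife_mono"]] * v[["p.husband_mono"]]
  low <- 1 - high - medium_high - medium_low
  c(high = high, medium_high = medium_high, medium_low = medium_low,
    low = low)
}

#' Status-quo strategy tree (no screening, no intervention)
#'
#' Every couple gives birth naturally; the deaf-birth probability is the
#' risk-category-specific natural (Mendelian) one. There are no childless
#' paths and no screening or intervention costs.
#'
#' @param params A `cea_params` object.
#' @param variant `"deaf"`, `"healthy"` or `"utility"` (affects only the
#'   cost payoffs on birth leaves).
#' @param concordance Same-gene concordance factor on the positive x
#'   positive joint genotype mass (default 1: independent marginals).
#' @return A `cea_tree`.
#' @export
build_status_quo_tree <- function(params, variant = "deaf",
                                  concordance = 1) {
  variant <- match.arg(variant, MODEL_VARIANTS)
  v <- params$values
  m <- category_mass(v, concordance)
  p_deaf <- c(high = v[["p.deaf_high_natural"]],
              medium_high = v[["p.deaf_medhigh_natural"]],
              medium_low = v[["p.deaf_medlow_natural"]],
              low = v[["p.deaf_low_natural"]])
  branches <- lapply(names(m), function(cat) {
    branch(m[[cat]], birth_node(p_deaf[[cat]], 0, v, variant), cat)
  })
  decision_tree(chance_node(branches), "status_quo")
}

# Medium-risk (medium_high / medium_low) decision subtree: 4-way choice
# between ART+PGT, amniocentesis, natural birth and no children. `q` is the
# Mendelian deaf/amniocentesis-positive probability of the category.
medium_subtree <- function(q, sunk, v, variant) {
  art_sunk <- sunk + v[["c.art_pgt"]] + v[["c.art_productivity_loss"]]
  amnio_sunk <- sunk + v[["c.amniocentesis"]] +
    v[["c.amnio_productivity_loss"]]
  amnio_pos <- chance_node(
    branch(v[["p.post_amnio_birth"]],
           birth_node(v[["p.deaf_amnio_pos_birth"]], amnio_sunk, v, variant),
           "birth"),
    branch(v[["p.post_amnio_terminate"]],
           make_leaf("no_birth", amnio_sunk, v, variant), "terminate"))
  amnio <- chance_node(
    branch(q, amnio_pos, "amnio_positive"),
    branch(1 - q,
           birth_node(v[["p.deaf_amnio_neg_birth"]], amnio_sunk, v, variant),
           "amnio_negative"))
  chance_node(
    branch(v[["p.med_art"]],
           birth_node(v[["p.deaf_art"]], art_sunk, v, variant), "art_pgt"),
    branch(v[["p.med_amnio"]], amnio, "amniocentesis"),
    branch(v[["p.med_natural"]], birth_node(q, sunk, v, variant), "natural"),
    branch(v[["p.med_none"]], make_leaf("no_birth", sunk, v, variant),
           "no_children"))
}

#' Two-step screening strategy tree
#'
#' The wife is always screened; her husband only when she is positive.
#' Screen-negative couples give birth naturally at low risk. Positive x
#' positive couples follow the risk-category subtree: high-risk couples
#' choose natural birth or no children; medium-risk couples choose between
#' ART with PGT, amniocentesis (with Mendelian fetal diagnosis and a
#' post-positive birth/terminate decision), natural birth and no children.
#'
#' @inheritParams build_status_quo_tree
#' @return A `cea_tree`.
#' @export
build_screening_tree <- function(params, variant = "deaf", concordance = 1) {
  variant <- match.arg(variant, MODEL_VARIANTS)
  v <- params$values
  screen1 <- per_person_screening_cost(params)
  screen2 <- 2 * screen1
  p_low <- v[["p.deaf_low_natural"]]

  high <- chance_node(
    branch(v[["p.high_birth"]],
           birth_node(v[["p.deaf_high_natural"]], screen2, v, variant),
           "birth"),
    branch(v[["p.high_none"]], make_leaf("no_birth", screen2, v, variant),
           "no_children"))
  med_high <- medium_subtree(v[["p.amnio_pos_medhigh"]], screen2, v, variant)
  med_low <- medium_subtree(v[["p.amnio_pos_medlow"]], screen2, v, variant)

  husband_given_wife <- function(wife) {
    pos_node <- function(husband) {
      cat <- classify_couple(wife, husband)
      switch(cat, high = high, medium_high = med_high, medium_low = med_low)
    }
    chance_node(
      branch(v[["p.husband_neg"]] * concordance_neg(v, concordance),
             birth_node(p_low, screen2, v, variant), "husband_neg"),
      branch(v[["p.husband_mono"]] * concordance, pos_node("mono"),
             "husband_mono"),
      branch(v[["p.husband_bi"]] * concordance, pos_node("bi"),
             "husband_bi"))
  }

  root <- chance_node(
    branch(v[["p.wife_neg"]], birth_node(p_low, screen1, v, variant),
           "wife_neg"),
    branch(v[["p.wife_mono"]], husband_given_wife("mono"), "wife_mono"),
    branch(v[["p.wife_bi"]], husband_given_wife("bi"), "wife_bi"))
  decision_tree(root, "screening")
}

# Keeps the husband marginal on the simplex when a same-gene concordance
# factor inflates the positive genotypes.
concordance_neg <- function(v, concordance) {
  if (concordance == 1) return(1)
  pos <- v[["p.husband_mono"]] + v[["p.husband_bi"]]
  (1 - concordance * pos) / v[["p.husband_neg"]]
}

#' Run one payoff model: both strategies, comparison and summary table
#'
#' @inheritParams build_status_quo_tree
#' @return A `cea_run` list: `variant`, `status_quo` and `screening`
#'   ([strategy_result()] objects), `comparison`
#'   ([compare_strategies()] on the variant's effect key), `table` (a
#'   two-row strategy/cost/effect data.frame with incremental columns and
#'   the ICER-or-dominated tag) and `families_needed`.
#' @export
run_model <- function(params, variant = "deaf", concordance = 1) {
  variant <- match.arg(variant, MODEL_VARIANTS)
  key <- variant_eff_key(variant)
  sq <- strategy_result(build_status_quo_tree(params, variant, concordance))
  sc <- strategy_result(build_screening_tree(params, variant, concordance))
  cmp <- compare_strategies(sq, sc, key)
  icer_tag <- if (cmp$dominance == "tradeoff_icer") {
    sprintf("%.2f", cmp$icer)
  } else {
    cmp$dominance
  }
  table <- data.frame(
    strategy = c(sq$strategy_name, sc$strategy_name),
    cost = c(sq$expected[["cost"]], sc$expected[["cost"]]),
    incr_cost = c(NA, cmp$delta_cost),
    effectiveness = c(sq$expected[[key]], sc$expected[[key]]),
    incr_eff = c(NA, cmp$delta_eff),
    icer = c(NA_character_, icer_tag),
    stringsAsFactors = FALSE)
  structure(list(variant = variant, status_quo = sq, screening = sc,
                 comparison = cmp, table = table,
                 families_needed = if (cmp$delta_eff != 0)
                   families_needed(cmp) else NA_real_),
            class = "cea_run")
}

#' @export
print.cea_run <- function(x, ...) {
  cat("<cea_run> model:", x$variant, "\n")
  tab <- x$table
  tab$cost <- sprintf("%.2f", tab$cost)
  tab$effectiveness <- sprintf("%.4f", tab$effectiveness)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Number of families screened per outcome event changed
#'
#' Reciprocal of the absolute incremental effect per screened family,
#' rounded to an integer: e.g. families screened to avert one deaf birth or
#' to gain one healthy birth.
#'
#' @param cmp A `cea_comparison` with nonzero `delta_eff`.
#' @return Integer count of families.
#' @export
families_needed <- function(cmp) {
  stopifnot(inherits(cmp, "cea_comparison"))
  if (cmp$delta_eff == 0) {
    stop("incremental effect is zero: families needed is undefined",
         call. = FALSE)
  }
  round(1 / abs(cmp$delta_eff))
}
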