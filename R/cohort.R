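# Individual-level synthetic cohort: genotype generation, the two-step
# screening cascade, prevalence estimation, and family-level decision /
# outcome microsimulation used as an end-to-end oracle for the analytic
# trees.

GENOTYPES <- c("wild", "mono", "bi")

genotype_freqs <- function(params, who = c("wife", "husband")) {
  who <- match.arg(who)
  v <- params$values
  stats::setNames(c(v[[paste0("p.", who, "_neg")]],
                    v[[paste0("p.", who, "_mono")]],
                    v[[paste0("p.", who, "_bi")]]), GENOTYPES)
}

#' Generate a synthetic screening cohort (genotypes only)
#'
#' Independent multinomial genotype draws per spouse (no assortative
#' mating), mirroring the analytic model's product-of-marginals joint
#' distribution.
#'
#' @param n_females Number of couples (>= 1).
#' @param female_freqs,male_freqs Named probability triples over
#'   `c("wild", "mono", "bi")`; default the wife/husband screening
#'   frequencies of [default_parameters()].
#' @param seed Integer seed.
#' @return Data.frame `couple_id`, `wife_genotype`, `husband_genotype`.
#' @export
generate_cohort <- function(n_females,
                            female_freqs = genotype_freqs(default_parameters(), "wife"),
                            male_freqs = genotype_freqs(default_parameters(), "husband"),
                            seed = 1) {
  stopifnot(n_females >= 1)
  check_simplex <- function(f, what) {
    if (length(f) != 3L || any(f < 0) || abs(sum(f) - 1) > 1e-9) {
      stop(what, " frequencies must be a probability triple", call. = FALSE)
    }
  }
  check_simplex(female_freqs, "female")
  check_simplex(male_freqs, "male")
  set.seed(as.integer(seed))
  data.frame(
    couple_id = seq_len(n_females),
    wife_genotype = sample(GENOTYPES, n_females, replace = TRUE,
                           prob = female_freqs),
    husband_genotype = sample(GENOTYPES, n_females, replace = TRUE,
                              prob = male_freqs),
    stringsAsFactors = FALSE)
}

#' Run the two-step screening cascade over a cohort
#'
#' Every wife is tested; husbands are tested iff the wife is mono- or
#' bi-allelic. Risk categories follow [classify_couple()]; the husband's
#' latent genotype is never consulted when he is untested.
#'
#' @param cohort Output of [generate_cohort()].
#' @param params A `cea_params` (per-person screening cost).
#' @return List: `cohort` (with `husband_tested`, `risk`, `screening_cost`
#'   columns) and `log` (`n_female_tests`, `n_male_tests`,
#'   `total_screening_cost`).
#' @export
two_step_screen <- function(cohort, params = default_parameters()) {
  unit <- per_person_screening_cost(params)
  tested <- cohort$wife_genotype != "wild"
  wife_g <- ifelse(cohort$wife_genotype == "wild", "neg",
                   cohort$wife_genotype)
  husb_g <- ifelse(tested,
                   ifelse(cohort$husband_genotype == "wild", "neg",
                          cohort$husband_genotype),
                   "untested")
  risk <- mapply(classify_couple, wife_g, husb_g, USE.NAMES = FALSE)
  cohort$husband_tested <- tested
  cohort$risk <- risk
  cohort$screening_cost <- unit * (1 + tested)
  list(cohort = cohort,
       log = list(n_female_tests = nrow(cohort),
                  n_male_tests = sum(tested),
                  total_screening_cost = sum(cohort$screening_cost)))
}

wilson_ci <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, center - half), upper = min(1, center + half))
}

#' Estimate genotype prevalence from screened counts
#'
#' Maximum-likelihood proportions with Wilson score confidence intervals.
#'
#' @param counts Either a named integer vector over
#'   `c("wild", "mono", "bi")` or a screened cohort data.frame (in which
#'   case `who` selects the spouse; husbands use the tested subset only).
#' @param who `"wife"` or `"husband"` when `counts` is a cohort.
#' @param conf Confidence level.
#' @return Data.frame `genotype`, `count`, `n`, `proportion`, `lower`,
#'   `upper`.
#' @export
estimate_prevalence <- function(counts, who = c("wife", "husband"),
                                conf = 0.95) {
  if (is.data.frame(counts)) {
    who <- match.arg(who)
    g <- if (who == "wife") {
      counts$wife_genotype
    } else {
      if (is.null(counts$husband_tested)) {
        stop("cohort is not screened; run two_step_screen() first",
             call. = FALSE)
      }
      counts$husband_genotype[counts$husband_tested]
    }
    counts <- stats::setNames(
      vapply(GENOTYPES, function(x) sum(g == x), numeric(1)), GENOTYPES)
  }
  n <- sum(counts)
  if (n < 1) stop("zero denominator: no individuals counted", call. = FALSE)
  out <- do.call(rbind, lapply(GENOTYPES, function(g) {
    ci <- wilson_ci(counts[[g]], n, conf)
    data.frame(genotype = g, count = counts[[g]], n = n,
               proportion = counts[[g]] / n,
               lower = ci[["lower"]], upper = ci[["upper"]],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Parameter overrides from an estimated prevalence
#'
#' Maps [estimate_prevalence()] output onto the `p.wife_*` / `p.husband_*`
#' parameter ids for [load_parameters()].
#'
#' @param est Output of [estimate_prevalence()].
#' @param who `"wife"` or `"husband"`.
#' @return Named list of overrides.
#' @export
prevalence_overrides <- function(est, who = c("wife", "husband")) {
  who <- match.arg(who)
  p <- stats::setNames(est$proportion, est$genotype)
  stats::setNames(as.list(c(p[["bi"]], p[["mono"]], p[["wild"]])),
                  paste0("p.", who, c("_bi", "_mono", "_neg")))
}

#' Simulate family-level decisions and birth outcomes
#'
#' For each screened couple, samples the reproductive decision path
#' (high-risk birth/none; medium-risk 4-way choice; Mendelian amniocentesis
#' result; post-positive birth/terminate) and the birth outcome,
#' accumulating exactly the costs the analytic tree assigns to that path.
#' Tallies converge to the screening tree's rollback values.
#'
#' @param cohort Screened cohort (the `cohort` element of
#'   [two_step_screen()]).
#' @param params A `cea_params`.
#' @param variant Payoff model (affects only costs, via the lifetime
#'   financials under `"utility"`).
#' @param seed Integer seed.
#' @return A `cohort_summary` list: `records` (per-couple `risk`,
#'   `decision`, `outcome`, `cost`), `outcome_counts`, `outcome_props`,
#'   `risk_counts`, `mean_cost`, `n`.
#' @export
simulate_families <- function(cohort, params = default_parameters(),
                              variant = "deaf", seed = 1) {
  variant <- match.arg(variant, MODEL_VARIANTS)
  if (is.null(cohort$risk)) {
    stop("cohort is not screened; run two_step_screen() first",
         call. = FALSE)
  }
  v <- params$values
  n <- nrow(cohort)
  set.seed(as.integer(seed))

  decision <- rep("natural", n)
  outcome <- rep(NA_character_, n)
  sunk <- cohort$screening_cost

  # Decision path, sampled in a fixed vectorised order for reproducibility.
  is_high <- cohort$risk == "high"
  is_med <- cohort$risk %in% c("medium_high", "medium_low")
  u_choice <- stats::runif(n)
  decision[is_high] <- ifelse(u_choice[is_high] < v[["p.high_birth"]],
                              "natural", "no_children")
  med_probs <- cumsum(c(v[["p.med_art"]], v[["p.med_amnio"]],
                        v[["p.med_natural"]], v[["p.med_none"]]))
  med_pick <- findInterval(u_choice[is_med], med_probs,
                           left.open = TRUE) + 1L
  decision[is_med] <- c("art_pgt", "amniocentesis", "natural",
                        "no_children")[pmin(med_pick, 4L)]

  # Mendelian deaf / amniocentesis-positive probability by category
  q_cat <- ifelse(cohort$risk == "high", v[["p.deaf_high_natural"]],
           ifelse(cohort$risk == "medium_high", v[["p.amnio_pos_medhigh"]],
           ifelse(cohort$risk == "medium_low", v[["p.amnio_pos_medlow"]],
                  v[["p.deaf_low_natural"]])))

  # Amniocentesis: fetal diagnosis then birth/terminate decision
  amnio <- decision == "amniocentesis"
  sunk[amnio] <- sunk[amnio] + v[["c.amniocentesis"]] +
    v[["c.amnio_productivity_loss"]]
  amnio_pos <- amnio & stats::runif(n) < q_cat
  post_birth <- stats::runif(n) < v[["p.post_amnio_birth"]]

  art <- decision == "art_pgt"
  sunk[art] <- sunk[art] + v[["c.art_pgt"]] + v[["c.art_productivity_loss"]]

  # Birth outcome and deaf probability per path
  births <- (decision == "natural") | art |
    (amnio & !amnio_pos) | (amnio_pos & post_birth)
  p_deaf <- rep(NA_real_, n)
  p_deaf[decision == "natural"] <- q_cat[decision == "natural"]
  p_deaf[art] <- v[["p.deaf_art"]]
  p_deaf[amnio & !amnio_pos] <- v[["p.deaf_amnio_neg_birth"]]
  p_deaf[amnio_pos & post_birth] <- v[["p.deaf_amnio_pos_birth"]]
  deaf <- births & stats::runif(n) < p_deaf
  outcome[!births] <- "no_birth"
  outcome[births & deaf] <- "deaf_birth"
  outcome[births & !deaf] <- "healthy_birth"

  cost <- sunk
  cost[births] <- cost[births] + v[["c.reproductive"]]
  if (variant == "utility") {
    h <- outcome == "healthy_birth"
    d <- outcome == "deaf_birth"
    cost[h] <- cost[h] + v[["c.future_medical_healthy"]] -
      v[["c.future_income_healthy"]]
    cost[d] <- cost[d] + v[["c.future_medical_disabled"]] -
      v[["c.future_income_disabled"]]
  }

  records <- data.frame(couple_id = cohort$couple_id, risk = cohort$risk,
                        decision = decision, outcome = outcome, cost = cost,
                        stringsAsFactors = FALSE)
  counts <- vapply(OUTCOME_LABELS, function(o) sum(outcome == o), numeric(1))
  structure(list(records = records,
                 outcome_counts = counts,
                 outcome_props = counts / n,
                 risk_counts = table(cohort$risk),
                 mean_cost = mean(cost),
                 n = n),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary> n =", x$n, "\n")
  print(round(x$outcome_props, 5))
  cat("mean cost:", sprintf("%.2f", x$mean_cost), "\n")
  invisible(x)
}
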