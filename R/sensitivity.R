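# One-way deterministic sensitivity (tornado), ART-uptake threshold
# analysis, and probabilistic sensitivity analysis with CEAC and
# confidence-ellipse summaries.

#' Perturb one parameter, renormalising its probability block
#'
#' Sets `id` to `value`. If the parameter belongs to a sum-to-one block, the
#' remaining block members are rescaled proportionally so the block still
#' sums to one. Probabilities are clipped to \[0, 1\] with a warning when a
#' span pushes them outside.
#'
#' @param params A `cea_params`.
#' @param id Parameter id.
#' @param value New value.
#' @return A validated `cea_params`.
#' @export
perturb_parameter <- function(params, id, value) {
  v <- params$values
  meta <- params$meta
  if (!id %in% names(v)) stop("unknown parameter id: ", id, call. = FALSE)
  kind <- meta$kind[meta$id == id]
  if (kind %in% c("probability", "utility") &&
      id != "u.healthy_qaly" && id != "u.deaf_qaly" &&
      (value < 0 || value > 1)) {
    warning("span pushes ", id, " outside [0,1]; clipped", call. = FALSE)
    value <- min(max(value, 0), 1)
  }
  if (kind == "cost" && value < 0) {
    warning("negative cost for ", id, " clipped to 0", call. = FALSE)
    value <- 0
  }
  blk <- meta$block[meta$id == id]
  v[[id]] <- value
  if (id == "u.deaf_utility_weight") {
    # the model consumes the derived deaf QALY, so keep it in step
    v[["u.deaf_qaly"]] <- derive_deaf_qaly(v[["u.healthy_qaly"]], value)
  }
  if (id == "u.deaf_qaly") {
    v[[id]] <- min(value, v[["u.healthy_qaly"]])
  }
  if (!is.na(blk)) {
    others <- meta$id[!is.na(meta$block) & meta$block == blk & meta$id != id]
    rest <- sum(v[others])
    if (rest > 0) {
      v[others] <- v[others] * (1 - value) / rest
    } else {
      v[others] <- (1 - value) / length(others)
    }
  }
  params$values <- v
  validate_parameters(params)
  params
}

#' Default one-way span for a parameter
#'
#' Span rule by provenance: survey-derived values move +/- 20%; values from
#' literature, expert opinion or Mendelian calculation move +/- 10%. Both
#' fractions are configurable.
#'
#' @param params A `cea_params`.
#' @param id Parameter id.
#' @param span_survey,span_other Relative half-spans.
#' @return List with `low`, `base`, `high`, `span`.
#' @export
dsa_span <- function(params, id, span_survey = 0.20, span_other = 0.10) {
  meta <- params$meta
  if (!id %in% meta$id) stop("unknown parameter id: ", id, call. = FALSE)
  base <- params$values[[id]]
  prov <- meta$provenance[meta$id == id]
  span <- if (prov == "survey") span_survey else span_other
  list(low = base * (1 - span), base = base, high = base * (1 + span),
       span = span)
}

# ICER presentation per model: signed ratio for the healthy-birth model,
# absolute cost per case averted (deaf) / per QALY lost (utility) otherwise.
icer_value <- function(cmp, variant) {
  if (is.na(cmp$icer_per_averted)) return(NA_real_)
  if (variant == "healthy") cmp$delta_cost / cmp$delta_eff
  else cmp$icer_per_averted
}

#' One-way deterministic sensitivity of the ICER to one parameter
#'
#' Re-runs the model with the parameter at its low / base / high values
#' (block siblings renormalised) and reports the three ICERs and the swing.
#'
#' @param params A `cea_params`.
#' @param id Parameter id.
#' @param variant Payoff model.
#' @param span Optional list with `low` and `high`; defaults to
#'   [dsa_span()].
#' @return One-row data.frame: `id`, `low`, `base`, `high`, `icer_low`,
#'   `icer_base`, `icer_high`, `swing`.
#' @export
one_way <- function(params, id, variant = "deaf", span = NULL) {
  if (is.null(span)) span <- dsa_span(params, id)
  at <- function(value) {
    icer_value(run_model(perturb_parameter(params, id, value),
                         variant)$comparison, variant)
  }
  icer_low <- at(span$low)
  icer_base <- icer_value(run_model(params, variant)$comparison, variant)
  icer_high <- at(span$high)
  data.frame(id = id, low = span$low, base = params$values[[id]],
             high = span$high, icer_low = icer_low, icer_base = icer_base,
             icer_high = icer_high, swing = abs(icer_high - icer_low),
             stringsAsFactors = FALSE)
}

#' Tornado table: one-way sensitivity over a set of parameters
#'
#' @param params A `cea_params`.
#' @param ids Parameter ids (default: every cost, behaviour and outcome
#'   probability, and the utility weight — prevalences excluded as observed
#'   data).
#' @param variant Payoff model.
#' @return Data.frame of [one_way()] rows sorted by `swing`, descending.
#' @export
tornado <- function(params, ids = NULL, variant = "deaf") {
  if (is.null(ids)) {
    meta <- params$meta
    ids <- meta$id[meta$kind %in% c("cost", "probability") &
                   !(meta$block %in% c("wife", "husband") & !is.na(meta$block))]
    ids <- c(ids, "u.deaf_utility_weight")
  }
  stopifnot(length(ids) >= 1)
  out <- do.call(rbind, lapply(ids, function(id)
    one_way(params, id, variant)))
  out[order(-out$swing), , drop = FALSE]
}

# Rebuild the medium-risk 4-way choice distribution at ART uptake `u`.
med_choice_at_uptake <- function(v, u, rule = c("none_absorbing",
                                                "proportional")) {
  rule <- match.arg(rule)
  base <- c(art = v[["p.med_art"]], amnio = v[["p.med_amnio"]],
            natural = v[["p.med_natural"]], none = v[["p.med_none"]])
  if (rule == "none_absorbing") {
    none <- 1 - u - base[["amnio"]] - base[["natural"]]
    if (none >= 0) {
      c(art = u, amnio = base[["amnio"]], natural = base[["natural"]],
        none = none)
    } else {
      # no-children mass exhausted: fall back to rescaling amnio + natural
      rest <- base[["amnio"]] + base[["natural"]]
      if (rest <= 0) stop("infeasible reallocation at uptake ", u,
                          call. = FALSE)
      scale <- (1 - u) / rest
      c(art = u, amnio = base[["amnio"]] * scale,
        natural = base[["natural"]] * scale, none = 0)
    }
  } else {
    rest <- 1 - base[["art"]]
    if (rest <= 0) stop("infeasible reallocation: base uptake is 1",
                        call. = FALSE)
    scale <- (1 - u) / rest
    c(art = u, amnio = base[["amnio"]] * scale,
      natural = base[["natural"]] * scale, none = base[["none"]] * scale)
  }
}

set_med_choice <- function(params, choice) {
  params$values[c("p.med_art", "p.med_amnio", "p.med_natural",
                  "p.med_none")] <-
    choice[c("art", "amnio", "natural", "none")]
  validate_parameters(params)
  params
}

#' Threshold analysis over the medium-risk ART-with-PGT uptake
#'
#' Sweeps the uptake over a grid, rebuilding the medium-risk 4-way choice
#' distribution at each point, and locates the break-even uptake at which
#' the screening strategy's incremental healthy-birth probability versus
#' status quo crosses zero (bisection to 1e-6).
#'
#' Reallocation rules: `none_absorbing` holds the amniocentesis and
#' natural-birth probabilities at base and lets the no-children mass absorb
#' the change (clipping at zero with a proportional fallback);
#' `proportional` rescales all three non-ART choices.
#'
#' @param params A `cea_params`.
#' @param grid Increasing uptake grid in \[0, 1\].
#' @param rule Reallocation rule.
#' @return List of class `cea_threshold`: `curve` (data.frame `uptake`,
#'   `incr_healthy`, `incr_deaf`, `incr_cost`, `icer_healthy`,
#'   `icer_deaf`), `break_even_uptake`, `rule`.
#' @export
art_uptake_sweep <- function(params, grid = seq(0, 1, by = 0.01),
                             rule = c("none_absorbing", "proportional")) {
  rule <- match.arg(rule)
  stopifnot(all(diff(grid) > 0), all(grid >= 0 & grid <= 1))
  at <- function(u) {
    p <- set_med_choice(params, med_choice_at_uptake(params$values, u, rule))
    rh <- run_model(p, "healthy")
    rd <- rh$comparison  # healthy comparison
    cmp_d <- compare_strategies(rh$status_quo, rh$screening, "eff_deaf")
    data.frame(uptake = u,
               incr_healthy = rd$delta_eff,
               incr_deaf = cmp_d$delta_eff,
               incr_cost = rd$delta_cost,
               icer_healthy = rd$delta_cost / rd$delta_eff,
               icer_deaf = abs(rd$delta_cost / cmp_d$delta_eff))
  }
  curve <- do.call(rbind, lapply(grid, at))
  f <- function(u) at(u)$incr_healthy
  break_even <- if (f(0) * f(1) < 0) {
    stats::uniroot(f, c(0, 1), tol = 1e-6)$root
  } else {
    NA_real_
  }
  structure(list(curve = curve, break_even_uptake = break_even, rule = rule),
            class = "cea_threshold")
}

#' Specification of the parameters sampled in the PSA
#'
#' Default distributions follow the probabilistic-sensitivity design: the
#' three key intervention costs are gamma-distributed (method of moments on
#' mean = base value, sd = `cv_cost` x base); the reproductive-decision
#' probabilities are beta (binary blocks, complementary renormalisation) or
#' Dirichlet (the medium-risk 4-way choice, concentration chosen so the
#' largest component has sd = `cv_prob` x base); the deafness utility weight
#' is beta. Genotype prevalences are held fixed (they are observed data).
#'
#' @param params A `cea_params`.
#' @param cv_cost,cv_prob Coefficients of variation (> 0, or 0 for the
#'   degenerate point-mass limit).
#' @return List describing each sampled component.
#' @export
psa_spec <- function(params, cv_cost = 0.2, cv_prob = 0.1) {
  if (cv_cost < 0 || cv_prob < 0) stop("cv must be >= 0", call. = FALSE)
  list(
    gamma_ids = c("c.screening.test", "c.art_pgt", "c.amniocentesis"),
    beta_pairs = list(c("p.high_birth", "p.high_none"),
                      c("p.post_amnio_birth", "p.post_amnio_terminate")),
    dirichlet_block = c("p.med_art", "p.med_amnio", "p.med_natural",
                        "p.med_none"),
    beta_scalars = "u.deaf_utility_weight",
    cv_cost = cv_cost, cv_prob = cv_prob
  )
}

rbeta_mom <- function(n, mean, cv) {
  sd <- cv * mean
  if (sd == 0) return(rep(mean, n))
  v <- sd^2
  if (v >= mean * (1 - mean)) {
    stop("beta cv too large for mean ", mean, call. = FALSE)
  }
  k <- mean * (1 - mean) / v - 1
  stats::rbeta(n, mean * k, (1 - mean) * k)
}

rgamma_mom <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  shape <- 1 / cv^2
  stats::rgamma(n, shape = shape, rate = shape / mean)
}

rdirichlet_cv <- function(n, base, cv) {
  if (cv == 0) {
    return(matrix(base, nrow = n, ncol = length(base), byrow = TRUE))
  }
  pmax_ <- max(base)
  a0 <- (1 - pmax_) / (cv^2 * pmax_) - 1
  if (a0 <= 0) stop("dirichlet cv too large", call. = FALSE)
  g <- matrix(stats::rgamma(n * length(base), shape = a0 * base, rate = 1),
              nrow = n, byrow = TRUE)
  g / rowSums(g)
}

#' Sample parameter sets for probabilistic sensitivity analysis
#'
#' @param params Base `cea_params`.
#' @param n Number of draws.
#' @param seed Integer seed (reproducible).
#' @param spec A [psa_spec()]; `cv = 0` components degenerate to the base
#'   value so the cv -> 0 limit reproduces the base set on every draw.
#' @return An `n` x k matrix of sampled values (columns named by parameter
#'   id) with the base `cea_params` as attribute `"base"`. Apply a row with
#'   [apply_draw()].
#' @export
sample_parameters <- function(params, n, seed, spec = psa_spec(params)) {
  stopifnot(n >= 1)
  set.seed(as.integer(seed))
  v <- params$values
  cols <- list()
  for (id in spec$gamma_ids) {
    cols[[id]] <- rgamma_mom(n, v[[id]], spec$cv_cost)
  }
  for (pair in spec$beta_pairs) {
    x <- rbeta_mom(n, v[[pair[1L]]], spec$cv_prob)
    cols[[pair[1L]]] <- x
    cols[[pair[2L]]] <- 1 - x
  }
  d <- rdirichlet_cv(n, unname(v[spec$dirichlet_block]), spec$cv_prob)
  for (j in seq_along(spec$dirichlet_block)) {
    cols[[spec$dirichlet_block[j]]] <- d[, j]
  }
  for (id in spec$beta_scalars) {
    cols[[id]] <- rbeta_mom(n, v[[id]], spec$cv_prob)
  }
  m <- do.call(cbind, cols)
  rownames(m) <- NULL
  attr(m, "base") <- params
  m
}

#' Apply one sampled draw to the base parameter set
#'
#' The deaf QALY is re-derived from the sampled utility weight when the
#' sampled weight differs from the base value (the degenerate cv = 0 limit
#' therefore keeps the published rounded constant and reproduces the base
#' case exactly).
#'
#' @param params Base `cea_params`.
#' @param draw Named numeric vector (one row of [sample_parameters()]).
#' @return A `cea_params` (not re-validated: draws are simplex-exact by
#'   construction).
#' @export
apply_draw <- function(params, draw) {
  base_weight <- params$values[["u.deaf_utility_weight"]]
  params$values[names(draw)] <- draw
  if ("u.deaf_utility_weight" %in% names(draw) &&
      draw[["u.deaf_utility_weight"]] != base_weight) {
    params$values[["u.deaf_qaly"]] <-
      derive_deaf_qaly(params$values[["u.healthy_qaly"]],
                       draw[["u.deaf_utility_weight"]])
  }
  params
}

#' Probabilistic sensitivity analysis
#'
#' For each of `n` sampled parameter sets, rebuilds both strategy trees and
#' records the incremental cost and effect; summarises with the
#' cost-effectiveness acceptability curve over a WTP grid, the acceptance
#' fraction at the study WTP (net-monetary-benefit criterion
#' `wtp * dE - dC >= 0`, well defined at `dE = 0`), and the 95% coverage
#' ellipse of the (dE, dC) cloud.
#'
#' @param params Base `cea_params`.
#' @param variant Payoff model.
#' @param n Number of Monte Carlo draws (>= 2).
#' @param seed Integer seed.
#' @param wtp Willingness-to-pay threshold (USD per effect unit).
#' @param wtp_grid WTP grid for the CEAC (default 0 to 2 x `wtp`).
#' @param spec A [psa_spec()].
#' @return A `cea_psa` list: `draws` (data.frame `draw`, `delta_cost`,
#'   `delta_eff`, `accept`), `ceac` (data.frame `wtp`, `prob_ce`), `summary`
#'   (means, acceptance fraction, ellipse), `seed`, `variant`, `wtp`.
#' @export
run_psa <- function(params, variant = "utility", n = 10000, seed = 1,
                    wtp = NULL, wtp_grid = NULL, spec = psa_spec(params)) {
  stopifnot(n >= 2)
  variant <- match.arg(variant, MODEL_VARIANTS)
  key <- variant_eff_key(variant)
  if (is.null(wtp)) {
    wtp <- derive_wtp(params$values[["u.gdp_per_capita"]],
                      params$values[["u.wtp_multiplier"]],
                      params$values[["u.healthy_qaly"]])
  }
  if (is.null(wtp_grid)) {
    wtp_grid <- seq(0, 2 * wtp, length.out = 41)
  }
  m <- sample_parameters(params, n, seed, spec)
  dc <- numeric(n)
  de <- numeric(n)
  for (i in seq_len(n)) {
    p <- apply_draw(params, m[i, ])
    sq <- strategy_result(build_status_quo_tree(p, variant))
    sc <- strategy_result(build_screening_tree(p, variant))
    dc[i] <- sc$expected[["cost"]] - sq$expected[["cost"]]
    de[i] <- sc$expected[[key]] - sq$expected[[key]]
  }
  draws <- data.frame(draw = seq_len(n), delta_cost = dc, delta_eff = de,
                      accept = wtp * de - dc >= 0)
  curve <- ceac(draws, wtp_grid)
  ell <- psa_ellipse(draws)
  summary <- list(mean_delta_cost = mean(dc), mean_delta_eff = mean(de),
                  prob_cost_effective = mean(draws$accept), wtp = wtp,
                  ellipse = ell)
  structure(list(draws = draws, ceac = curve, summary = summary,
                 seed = as.integer(seed), variant = variant, wtp = wtp),
            class = "cea_psa")
}

#' Cost-effectiveness acceptability curve
#'
#' Fraction of PSA draws with non-negative net monetary benefit at each WTP
#' grid point.
#'
#' @param draws Data.frame with `delta_cost` and `delta_eff` (e.g.
#'   `run_psa()$draws`).
#' @param wtp_grid Numeric WTP grid.
#' @return Data.frame `wtp`, `prob_ce`.
#' @export
ceac <- function(draws, wtp_grid) {
  stopifnot(nrow(draws) >= 1)
  prob <- vapply(wtp_grid, function(w) {
    mean(w * draws$delta_eff - draws$delta_cost >= 0)
  }, numeric(1))
  data.frame(wtp = wtp_grid, prob_ce = prob)
}

#' Coverage ellipse of the PSA incremental cloud
#'
#' Mean vector and covariance of (`delta_eff`, `delta_cost`) with the
#' chi-square(2) quantile radius: on bivariate-normal draws the ellipse
#' covers `level` of the points.
#'
#' @param draws Data.frame with `delta_eff` and `delta_cost`.
#' @param level Coverage level.
#' @return List `center`, `cov`, `radius2`, `level`.
#' @export
psa_ellipse <- function(draws, level = 0.95) {
  x <- cbind(delta_eff = draws$delta_eff, delta_cost = draws$delta_cost)
  list(center = colMeans(x), cov = stats::cov(x),
       radius2 = stats::qchisq(level, df = 2), level = level)
}

#' Is each point inside a coverage ellipse?
#'
#' @param draws Data.frame with `delta_eff` and `delta_cost`.
#' @param ellipse A [psa_ellipse()].
#' @return Logical vector.
#' @export
in_ellipse <- function(draws, ellipse) {
  x <- cbind(draws$delta_eff, draws$delta_cost)
  stats::mahalanobis(x, ellipse$center, ellipse$cov) <= ellipse$radius2
}
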