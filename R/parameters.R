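# Model inputs: screening/intervention costs (2021 USD), branch
# probabilities, and utility/economic constants, with validation and the
# lifetime-discounting derivations.

#' Parameter metadata table
#'
#' One row per model input: default value, class (`cost`, `probability`,
#' `utility`, `constant`), provenance tag (`survey`, `literature`, `expert`,
#' `mendelian`, `calibrated`) and, for probabilities that must sum to one
#' with their siblings, a renormalisation block label.
#'
#' Provenance drives the default one-way sensitivity spans; blocks drive
#' complementary renormalisation after any perturbation or PSA draw.
#'
#' @return A data.frame with columns `id`, `value`, `kind`, `provenance`,
#'   `block`.
#' @export
parameter_table <- function() {
  row <- function(id, value, kind, provenance, block = NA_character_) {
    data.frame(id = id, value = value, kind = kind, provenance = provenance,
               block = block, stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    # Direct and indirect costs, USD per case
    row("c.screening.test",          52.20, "cost", "survey"),
    row("c.screening.labor",          9.00, "cost", "survey"),
    row("c.screening.promotion",      3.00, "cost", "survey"),
    row("c.reproductive",           651.00, "cost", "literature"),
    row("c.art_pgt",             11940.30, "cost", "survey"),
    row("c.amniocentesis",        2686.60, "cost", "survey"),
    row("c.art_productivity_loss",   28.70, "cost", "literature"),
    row("c.amnio_productivity_loss", 14.40, "cost", "literature"),
    # Discounted lifetime financials, USD per life
    row("c.future_income_healthy",  115622.00, "cost", "literature"),
    row("c.future_income_disabled",  65996.00, "cost", "literature"),
    row("c.future_medical_healthy",   6961.40, "cost", "literature"),
    row("c.future_medical_disabled", 11142.40, "cost", "literature"),
    # Carrier-genotype prevalence (wife / husband marginals)
    row("p.wife_bi",     0.0050, "probability", "survey",   "wife"),
    row("p.wife_mono",   0.1572, "probability", "survey",   "wife"),
    row("p.wife_neg",    0.8378, "probability", "survey",   "wife"),
    row("p.husband_bi",   0.0074, "probability", "survey",  "husband"),
    row("p.husband_mono", 0.1370, "probability", "survey",  "husband"),
    row("p.husband_neg",  0.8556, "probability", "survey",  "husband"),
    # Reproductive decisions
    row("p.high_birth", 0.1930, "probability", "literature", "high_choice"),
    row("p.high_none",  0.8070, "probability", "literature", "high_choice"),
    row("p.med_art",     0.1774, "probability", "expert", "med_choice"),
    row("p.med_amnio",   0.7096, "probability", "expert", "med_choice"),
    row("p.med_natural", 0.0565, "probability", "expert", "med_choice"),
    row("p.med_none",    0.0565, "probability", "expert", "med_choice"),
    row("p.post_amnio_birth",     0.1930, "probability", "literature",
        "post_amnio"),
    row("p.post_amnio_terminate", 0.8070, "probability", "literature",
        "post_amnio"),
    # Fetal/newborn outcome probabilities (complement = healthy)
    row("p.amnio_pos_medhigh", 0.5000, "probability", "mendelian"),
    row("p.amnio_pos_medlow",  0.2500, "probability", "mendelian"),
    row("p.deaf_low_natural",     0.0010, "probability", "literature"),
    row("p.deaf_high_natural",    0.9990, "probability", "expert"),
    row("p.deaf_medhigh_natural", 0.5000, "probability", "mendelian"),
    row("p.deaf_medlow_natural",  0.2500, "probability", "mendelian"),
    row("p.deaf_art",             0.0010, "probability", "literature"),
    row("p.deaf_amnio_pos_birth", 0.9990, "probability", "expert"),
    row("p.deaf_amnio_neg_birth", 0.0010, "probability", "literature"),
    # Utility and economic constants
    row("u.healthy_qaly",        22.1,   "utility",  "literature"),
    row("u.deaf_utility_weight",  0.91,  "utility",  "literature"),
    row("u.deaf_qaly",           20.1,   "utility",  "literature"),
    row("u.discount_rate",        0.05,  "constant", "literature"),
    row("u.lifetime_factor", 115622 / 5243, "constant", "calibrated"),
    row("u.gdp_per_capita",   12086.00,  "constant", "literature"),
    row("u.wtp_multiplier",       3,     "constant", "literature")
  ))
}

#' Default parameter set
#'
#' The calibrated base case: every cost, probability and constant of the
#' screening model at its published default.
#'
#' @return An object of class `cea_params`: a list with `values` (named
#'   numeric vector) and `meta` (the [parameter_table()]).
#' @export
default_parameters <- function() {
  meta <- parameter_table()
  values <- stats::setNames(meta$value, meta$id)
  ps <- structure(list(values = values, meta = meta), class = "cea_params")
  validate_parameters(ps)
  ps
}

#' Load a parameter set, optionally overridden from a configuration file
#'
#' @param config `NULL` for the defaults, a named list of overrides, or the
#'   path to a JSON file. The file may be a flat `{id: value}` map or the
#'   richer structure written by [write_parameters()]. Keys must be a subset
#'   of the published parameter ids.
#' @return A validated `cea_params` object.
#' @export
load_parameters <- function(config = NULL) {
  ps <- default_parameters()
  if (is.null(config)) {
    return(ps)
  }
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
    if (!is.null(config$params)) {
      config <- config$params
    }
  }
  config <- as.list(config)
  if (length(config) == 0L) {
    return(ps)
  }
  ids <- names(config)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("parameter overrides must be named", call. = FALSE)
  }
  unknown <- setdiff(ids, names(ps$values))
  if (length(unknown)) {
    stop("unknown parameter id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  vals <- vapply(config, function(x) as.numeric(x)[1L], numeric(1))
  ps$values[ids] <- vals
  validate_parameters(ps)
  ps
}

#' Write a parameter set to a JSON configuration file
#'
#' The file round-trips bit-for-bit through [load_parameters()] and carries
#' the provenance/kind/block metadata alongside the values.
#'
#' @param params A `cea_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "cea_params"))
  # values serialised at 17 significant digits so reloading is bit-exact
  out <- list(
    params = as.list(stats::setNames(sprintf("%.17g", params$values),
                                     names(params$values))),
    provenance = stats::setNames(as.list(params$meta$provenance),
                                 params$meta$id),
    kind = stats::setNames(as.list(params$meta$kind), params$meta$id),
    block = stats::setNames(as.list(params$meta$block), params$meta$id)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Validate a parameter set
#'
#' Checks non-negativity of costs, the \[0, 1\] range of every probability,
#' that each probability block sums to one within 1e-9, and the ordering
#' constraints on the lifetime financials and utilities. Errors list every
#' offending field.
#'
#' @param params A `cea_params` object.
#' @return `TRUE`, invisibly, when valid.
#' @export
validate_parameters <- function(params) {
  stopifnot(inherits(params, "cea_params"))
  v <- params$values
  meta <- params$meta
  bad <- character(0)
  if (any(!is.finite(v))) {
    bad <- c(bad, paste0("non-finite: ",
                         paste(names(v)[!is.finite(v)], collapse = ", ")))
  }
  costs <- meta$id[meta$kind == "cost"]
  if (any(v[costs] < 0)) {
    bad <- c(bad, paste0("negative cost: ",
                         paste(costs[v[costs] < 0], collapse = ", ")))
  }
  probs <- meta$id[meta$kind == "probability"]
  off <- probs[v[probs] < 0 | v[probs] > 1]
  if (length(off)) {
    bad <- c(bad, paste0("probability outside [0,1]: ",
                         paste(off, collapse = ", ")))
  }
  for (blk in unique(stats::na.omit(meta$block))) {
    ids <- meta$id[!is.na(meta$block) & meta$block == blk]
    s <- sum(v[ids])
    if (abs(s - 1) > 1e-9) {
      bad <- c(bad, sprintf("block '%s' sums to %.12g (ids: %s)", blk, s,
                            paste(ids, collapse = ", ")))
    }
  }
  if (!(v[["c.future_income_healthy"]] > v[["c.future_income_disabled"]])) {
    bad <- c(bad, "c.future_income_healthy must exceed c.future_income_disabled")
  }
  if (!(v[["c.future_medical_disabled"]] > v[["c.future_medical_healthy"]])) {
    bad <- c(bad, "c.future_medical_disabled must exceed c.future_medical_healthy")
  }
  w <- v[["u.deaf_utility_weight"]]
  if (!(w > 0 && w <= 1)) {
    bad <- c(bad, "u.deaf_utility_weight must be in (0, 1]")
  }
  if (v[["u.deaf_qaly"]] > v[["u.healthy_qaly"]]) {
    bad <- c(bad, "u.deaf_qaly must not exceed u.healthy_qaly")
  }
  if (v[["u.discount_rate"]] < 0) {
    bad <- c(bad, "u.discount_rate must be non-negative")
  }
  if (length(bad)) {
    stop("invalid parameter set:\n  ", paste(bad, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.cea_params <- function(x, ...) {
  cat("<cea_params> ", length(x$values), " parameters\n", sep = "")
  print(utils::head(data.frame(id = x$meta$id, value = unname(x$values),
                               provenance = x$meta$provenance), 12L))
  cat("  ...\n")
  invisible(x)
}

#' Per-person screening cost
#'
#' Sum of the genetic test, screening labour and project promotion costs;
#' charged once per screened individual.
#'
#' @param params A `cea_params` object, or a numeric vector of the three
#'   component costs.
#' @return Cost in USD per person.
#' @export
per_person_screening_cost <- function(params = default_parameters()) {
  if (inherits(params, "cea_params")) {
    v <- params$values
    comp <- c(v[["c.screening.test"]], v[["c.screening.labor"]],
              v[["c.screening.promotion"]])
  } else {
    comp <- as.numeric(params)
  }
  sum(comp)
}

#' Discounted lifetime factor
#'
#' Sum of annual discount weights over a life horizon: multiplying a constant
#' annual amount by the factor gives its lifetime present value. With
#' `timing = "start"` (annuity-due) year 0 is undiscounted; with `"end"`
#' every payment is discounted one extra year. An infinite horizon gives the
#' perpetuity limit, e.g. (1 + r)/r for start-of-year timing.
#'
#' @param rate Annual discount rate (fraction/year, >= 0).
#' @param horizon Life-years (>= 0, may be `Inf`).
#' @param timing `"start"` or `"end"` of year.
#' @return Dimensionless factor.
#' @export
discounted_lifetime_factor <- function(rate, horizon,
                                       timing = c("start", "end")) {
  timing <- match.arg(timing)
  if (rate < 0 || horizon < 0) {
    stop("rate and horizon must be non-negative", call. = FALSE)
  }
  if (rate == 0) {
    return(horizon)
  }
  v <- 1 / (1 + rate)
  f <- (1 - v^horizon) / (1 - v)
  if (timing == "end") f <- f * v
  f
}

#' Project an annual amount forward at a constant growth rate
#'
#' @param base Annual amount in the base year.
#' @param annual_rate Growth rate (fraction/year).
#' @param years Number of years to project (>= 0).
#' @return `base * (1 + annual_rate)^years`.
#' @export
project_growth <- function(base, annual_rate, years) {
  if (years < 0) stop("years must be non-negative", call. = FALSE)
  base * (1 + annual_rate)^years
}

#' Implied annual growth rate between two endpoint values
#'
#' Companion inverse of [project_growth()]: the constant annual rate that
#' carries `from` to `to` over `years` years (geometric mean growth).
#'
#' @param from,to Endpoint annual amounts (> 0).
#' @param years Year gap (> 0).
#' @return Annual growth rate as a fraction.
#' @export
growth_rate <- function(from, to, years) {
  stopifnot(from > 0, to > 0, years > 0)
  (to / from)^(1 / years) - 1
}

#' Lifetime present value of an annual amount
#'
#' @param annual Amount per year.
#' @param factor Discounted lifetime factor (>= 0), e.g. from
#'   [discounted_lifetime_factor()] or the calibrated `u.lifetime_factor`.
#' @return `annual * factor`.
#' @export
lifetime_value <- function(annual, factor) {
  if (any(factor < 0)) stop("factor must be non-negative", call. = FALSE)
  annual * factor
}

#' Willingness-to-pay threshold for a whole discounted life
#'
#' GDP per capita times the WTP multiplier times the lifetime QALY of a
#' healthy individual, rounded to the nearest dollar for reporting.
#'
#' @param gdp_per_capita Annual GDP per capita (USD).
#' @param multiplier Dimensionless WTP multiplier (conventionally 3).
#' @param lifetime_qaly Discounted lifetime QALYs of a healthy individual.
#' @return WTP in USD.
#' @export
derive_wtp <- function(gdp_per_capita, multiplier, lifetime_qaly) {
  stopifnot(gdp_per_capita > 0, multiplier > 0, lifetime_qaly > 0)
  round(gdp_per_capita * multiplier * lifetime_qaly)
}

#' Lifetime QALY of a deaf individual
#'
#' Healthy lifetime QALY scaled by the deafness utility weight. The
#' reporting convention rounds to one decimal (`rounded = TRUE`); the model
#' default keeps the published rounded constant.
#'
#' @param healthy_qaly Discounted lifetime QALY of a healthy individual.
#' @param weight Deafness utility weight in (0, 1].
#' @param rounded Round to one decimal for reporting?
#' @return Lifetime QALY.
#' @export
derive_deaf_qaly <- function(healthy_qaly, weight, rounded = FALSE) {
  if (!(weight > 0 && weight <= 1)) {
    stop("weight must be in (0, 1]", call. = FALSE)
  }
  q <- healthy_qaly * weight
  if (rounded) round(q, 1) else q
}
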