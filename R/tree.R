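# Generic multi-payoff decision-tree engine: node constructors, validation,
# expected-value rollback, strategy comparison (ICER / dominance) and a
# path-sampling microsimulation.

PAYOFF_KEYS <- c("cost", "eff_deaf", "eff_healthy", "eff_utility")
OUTCOME_LABELS <- c("healthy_birth", "deaf_birth", "no_birth")

#' Terminal (leaf) node of a decision tree
#'
#' Carries the outcome label and all four payoffs. The binary effect payoffs
#' are derived from the outcome: `eff_deaf = 1` iff a deaf birth,
#' `eff_healthy = 1` iff a healthy birth.
#'
#' @param outcome One of `"healthy_birth"`, `"deaf_birth"`, `"no_birth"`.
#' @param cost Accumulated path cost (USD; may be negative when lifetime
#'   income exceeds expenditure).
#' @param eff_utility Lifetime QALYs attached to the outcome (>= 0).
#' @return A `cea_terminal` node.
#' @export
terminal_node <- function(outcome, cost, eff_utility = 0) {
  outcome <- match.arg(outcome, OUTCOME_LABELS)
  structure(
    list(outcome = outcome,
         payoffs = c(cost = as.numeric(cost),
                     eff_deaf = as.numeric(outcome == "deaf_birth"),
                     eff_healthy = as.numeric(outcome == "healthy_birth"),
                     eff_utility = as.numeric(eff_utility))),
    class = "cea_terminal")
}

#' Chance node with ordered probability-weighted branches
#'
#' @param ... Branches created with [branch()], in order. Branch order is
#'   part of the tree definition: the microsimulation samples by inverse CDF
#'   over it, so seeds are portable.
#' @return A `cea_chance` node.
#' @export
chance_node <- function(...) {
  branches <- list(...)
  if (length(branches) == 1L && is.null(branches[[1L]]$prob)) {
    branches <- branches[[1L]]
  }
  structure(list(branches = branches), class = "cea_chance")
}

#' A single branch of a chance node
#'
#' @param prob Branch probability in \[0, 1\].
#' @param node Child node (`cea_terminal` or `cea_chance`).
#' @param label Branch label for path reporting.
#' @return A branch record.
#' @export
branch <- function(prob, node, label = "") {
  list(prob = as.numeric(prob), node = node, label = label)
}

#' A named strategy tree
#'
#' @param root Root node.
#' @param strategy_name Strategy label.
#' @return A `cea_tree` object.
#' @export
decision_tree <- function(root, strategy_name) {
  structure(list(root = root, strategy_name = strategy_name),
            class = "cea_tree")
}

is_terminal <- function(node) inherits(node, "cea_terminal")

#' Validate a decision tree
#'
#' Checks that every chance node has at least one branch, probabilities in
#' \[0, 1\] summing to one within 1e-9, and that every leaf is a terminal
#' node with the full payoff vector.
#'
#' @param tree A `cea_tree`.
#' @return Character vector of findings; empty when the tree is valid.
#' @export
validate_tree <- function(tree) {
  stopifnot(inherits(tree, "cea_tree"))
  findings <- character(0)
  walk <- function(node, where) {
    if (is_terminal(node)) {
      if (!identical(names(node$payoffs), PAYOFF_KEYS)) {
        findings <<- c(findings, sprintf("%s: terminal payoff keys malformed",
                                         where))
      }
      return(invisible())
    }
    if (!inherits(node, "cea_chance")) {
      findings <<- c(findings, sprintf("%s: leaf is not a terminal node",
                                       where))
      return(invisible())
    }
    probs <- vapply(node$branches, `[[`, numeric(1), "prob")
    if (length(probs) < 1L) {
      findings <<- c(findings, sprintf("%s: chance node has no branches",
                                       where))
      return(invisible())
    }
    if (any(probs < 0 | probs > 1)) {
      findings <<- c(findings, sprintf("%s: branch probability outside [0,1]",
                                       where))
    }
    if (abs(sum(probs) - 1) > 1e-9) {
      findings <<- c(findings, sprintf("%s: sum=%.10g", where, sum(probs)))
    }
    for (i in seq_along(node$branches)) {
      walk(node$branches[[i]]$node, paste0(where, "/", i))
    }
  }
  walk(tree$root, tree$strategy_name)
  findings
}

#' Expected payoff of a tree by rollback
#'
#' Probability-weighted sum of terminal payoffs under one payoff key,
#' computed by depth-first accumulation.
#'
#' @param tree A valid `cea_tree`.
#' @param key One of `"cost"`, `"eff_deaf"`, `"eff_healthy"`,
#'   `"eff_utility"`.
#' @return Expected payoff (scalar).
#' @export
rollback <- function(tree, key) {
  if (!key %in% PAYOFF_KEYS) {
    stop("unknown payoff key: ", key, call. = FALSE)
  }
  ev <- function(node) {
    if (is_terminal(node)) {
      return(node$payoffs[[key]])
    }
    s <- 0
    for (b in node$branches) s <- s + b$prob * ev(b$node)
    s
  }
  ev(tree$root)
}

#' Expected payoffs and outcome mass of a strategy in one pass
#'
#' @param tree A valid `cea_tree`.
#' @return A `cea_strategy_result`: list with `strategy_name`, `expected`
#'   (named vector over the four payoff keys) and `outcome_mass` (named
#'   vector over the three outcome labels, summing to one).
#' @export
strategy_result <- function(tree) {
  acc <- function(node) {
    if (is_terminal(node)) {
      mass <- stats::setNames(as.numeric(OUTCOME_LABELS == node$outcome),
                              OUTCOME_LABELS)
      return(c(node$payoffs, mass))
    }
    s <- numeric(7L)
    for (b in node$branches) s <- s + b$prob * acc(b$node)
    s
  }
  v <- acc(tree$root)
  names(v) <- c(PAYOFF_KEYS, OUTCOME_LABELS)
  structure(list(strategy_name = tree$strategy_name,
                 expected = v[PAYOFF_KEYS],
                 outcome_mass = v[OUTCOME_LABELS]),
            class = "cea_strategy_result")
}

#' @export
print.cea_strategy_result <- function(x, ...) {
  cat("<strategy>", x$strategy_name, "\n")
  print(round(x$expected, 6))
  print(round(x$outcome_mass, 6))
  invisible(x)
}

#' Compare two strategies: incremental cost, effect, ICER and dominance
#'
#' Deltas are alternative minus reference. Dominance is labelled
#' `alt_dominated` iff the alternative costs more and is less effective,
#' `alt_dominant` iff it costs less and is more effective, and
#' `tradeoff_icer` otherwise, in which case `icer = delta_cost / delta_eff`.
#' `icer_per_averted = |delta_cost / delta_eff|` is always reported when the
#' effect delta is nonzero: it is the "cost per case averted" presentation
#' used when the effect is counted in events averted. A zero effect delta
#' leaves both ICERs `NA` with dominance resolved by the cost sign alone.
#'
#' @param reference,alternative `cea_strategy_result` objects.
#' @param key Payoff key to compare on.
#' @return A `cea_comparison` list: `delta_cost`, `delta_eff`, `icer`,
#'   `icer_per_averted`, `dominance`, `key`.
#' @export
compare_strategies <- function(reference, alternative, key) {
  stopifnot(inherits(reference, "cea_strategy_result"),
            inherits(alternative, "cea_strategy_result"),
            key %in% PAYOFF_KEYS)
  dc <- unname(alternative$expected[["cost"]] - reference$expected[["cost"]])
  de <- unname(alternative$expected[[key]] - reference$expected[[key]])
  if (de == 0) {
    dominance <- if (dc > 0) "alt_dominated_on_cost"
                 else if (dc < 0) "alt_dominant_on_cost" else "tradeoff_icer"
    icer <- NA_real_
    per_averted <- NA_real_
  } else if (dc > 0 && de < 0) {
    dominance <- "alt_dominated"
    icer <- NA_real_
    per_averted <- abs(dc / de)
  } else if (dc < 0 && de > 0) {
    dominance <- "alt_dominant"
    icer <- NA_real_
    per_averted <- abs(dc / de)
  } else {
    dominance <- "tradeoff_icer"
    icer <- dc / de
    per_averted <- abs(dc / de)
  }
  structure(list(delta_cost = dc, delta_eff = de, icer = icer,
                 icer_per_averted = per_averted, dominance = dominance,
                 key = key),
            class = "cea_comparison")
}

#' @export
print.cea_comparison <- function(x, ...) {
  cat(sprintf("<comparison on %s>  dC = %.4f  dE = %.7f  [%s]\n",
              x$key, x$delta_cost, x$delta_eff, x$dominance))
  if (!is.na(x$icer)) cat(sprintf("  ICER = %.2f\n", x$icer))
  if (!is.na(x$icer_per_averted)) {
    cat(sprintf("  |dC/dE| (per case averted) = %.2f\n", x$icer_per_averted))
  }
  invisible(x)
}

#' Enumerate all root-to-leaf paths of a tree
#'
#' Depth-first, in branch order, multiplying branch probabilities along each
#' path.
#'
#' @param tree A `cea_tree`.
#' @return A data.frame with one row per path: `path` (slash-joined branch
#'   labels), `prob`, `outcome` and the four payoff columns.
#' @export
enumerate_paths <- function(tree) {
  rows <- list()
  walk <- function(node, prob, labels) {
    if (is_terminal(node)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        path = paste(labels, collapse = "/"),
        prob = prob, outcome = node$outcome,
        cost = node$payoffs[["cost"]],
        eff_deaf = node$payoffs[["eff_deaf"]],
        eff_healthy = node$payoffs[["eff_healthy"]],
        eff_utility = node$payoffs[["eff_utility"]],
        stringsAsFactors = FALSE)
      return(invisible())
    }
    for (b in node$branches) {
      walk(b$node, prob * b$prob, c(labels, b$label))
    }
  }
  walk(tree$root, 1, character(0))
  do.call(rbind, rows)
}

#' Monte Carlo microsimulation of a decision tree
#'
#' Samples `n` root-to-leaf paths (inverse CDF over the depth-first path
#' distribution, which respects branch order) and reports empirical mean
#' payoffs with standard errors and empirical outcome mass. Used as a
#' stochastic oracle for [rollback()].
#'
#' @param tree A valid `cea_tree`.
#' @param n Number of sampled paths (>= 1).
#' @param seed Integer seed; identical seeds give identical output.
#' @return List with `expected`, `se`, `outcome_mass`, `n`, `seed`.
#' @export
microsimulate <- function(tree, n, seed) {
  stopifnot(n >= 1)
  paths <- enumerate_paths(tree)
  set.seed(as.integer(seed))
  u <- stats::runif(n)
  idx <- findInterval(u, cumsum(paths$prob), left.open = TRUE) + 1L
  idx[idx > nrow(paths)] <- nrow(paths)
  draws <- paths[idx, PAYOFF_KEYS]
  expected <- vapply(draws, mean, numeric(1))
  se <- vapply(draws, function(x) {
    if (n == 1L) 0 else stats::sd(x) / sqrt(n)
  }, numeric(1))
  mass <- vapply(OUTCOME_LABELS, function(o) mean(paths$outcome[idx] == o),
                 numeric(1))
  list(expected = expected, se = se, outcome_mass = mass,
       n = as.integer(n), seed = as.integer(seed))
}
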