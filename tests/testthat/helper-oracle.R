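# Independent brute-force oracle: exhaustively enumerates root-to-leaf
# paths of a tree by explicit stack traversal (no recursion shared with the
# engine's rollback) and sums probability-weighted payoffs.
oracle_expected <- function(tree, key) {
  total <- 0
  stack <- list(list(node = tree$root, prob = 1))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    if (inherits(node, "cea_terminal")) {
      total <- total + top$prob * node$payoffs[[key]]
    } else {
      for (b in node$branches) {
        stack[[length(stack) + 1L]] <- list(node = b$node,
                                            prob = top$prob * b$prob)
      }
    }
  }
  total
}

oracle_outcome_mass <- function(tree) {
  mass <- c(healthy_birth = 0, deaf_birth = 0, no_birth = 0)
  stack <- list(list(node = tree$root, prob = 1))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    if (inherits(node, "cea_terminal")) {
      mass[[node$outcome]] <- mass[[node$outcome]] + top$prob
    } else {
      for (b in node$branches) {
        stack[[length(stack) + 1L]] <- list(node = b$node,
                                            prob = top$prob * b$prob)
      }
    }
  }
  mass
}

# Small hand-built fixture trees
tiny_tree <- function(cost1 = 1, cost0 = 0, p = 0.3) {
  decision_tree(
    chance_node(
      branch(p, terminal_node("deaf_birth", cost = cost1, eff_utility = 20.1),
             "deaf"),
      branch(1 - p, terminal_node("healthy_birth", cost = cost0,
                                  eff_utility = 22.1), "healthy")),
    "tiny")
}
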