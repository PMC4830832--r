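## Shared test fixtures: small Boolean networks built in code.

## two-node negative feedback loop: B copies A, A negates B
negative_loop <- function() boolean_network(c(B = "A", A = "!B"))

## random rule-based network: each node gets 1-3 random parents combined by
## a random connective with random negations
random_rule_network <- function(n, seed) {
  set.seed(seed)
  nodes <- sprintf("X%02d", seq_len(n))
  rules <- sapply(nodes, function(nd) {
    k <- sample(1:3, 1)
    par <- sample(nodes, k)
    lit <- ifelse(runif(k) < 0.3, paste0("!", par), par)
    paste(lit, collapse = sample(c(" & ", " | "), 1))
  })
  boolean_network(rules, nodes = nodes)
}

all_states <- function(net) {
  n <- length(net$nodes)
  m <- as.matrix(expand.grid(rep(list(0:1), n)))
  colnames(m) <- net$nodes
  m
}

attractor_ids <- function(atts) vapply(atts, `[[`, character(1), "id")

zero_state <- function(net) setNames(rep(0L, length(net$nodes)), net$nodes)
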