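# Small mechanism builders used across the suite.

# Linear chain a -> b -> ... -> central, all edges `relation`, extracted.
chain_mechanism <- function(labels = c("A", "B", "X"),
                            relation = "increases") {
  n <- length(labels)
  net <- causal_network(data.frame(
    source = labels[-n], relation = relation, target = labels[-1]
  ))
  extract_mechanism(net, labels[n])
}

# Two parents with opposite signs converging on X: A -(+)-> X, B -(-)-> X.
star_mechanism <- function() {
  net <- causal_network(data.frame(
    source = c("A", "B"),
    relation = c("increases", "decreases"),
    target = "X"
  ))
  extract_mechanism(net, "X")
}

# Random small DAG mechanism with mixed signs, for property tests.
random_mechanism <- function(seed, max_nodes = 15L) {
  set.seed(seed)
  n <- sample(2:max_nodes, 1)
  spec <- synthetic_spec(
    n_nodes = n,
    extra_edge_prob = runif(1, 0, 0.4),
    negative_sign_prob = 0.5,
    fraction_unmeasured = 0,
    seed = seed
  )
  generate_mechanism(spec)
}

random_weights <- function(net, seed) {
  set.seed(seed)
  labels <- network_labels(net)
  stats::setNames(rnorm(length(labels)), labels)
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
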