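#' Specification for a synthetic mechanism
#'
#' Parameters of the synthetic mechanism generator. The generator emulates
#' the structure the scoring algorithm assumes: a DAG of signed causal
#' edges in which every node has a directed path to a single central node,
#' node weights are log2 fold changes, and some nodes are unmeasured.
#'
#' Defaults emulate curated neurodegeneration mechanism subgraphs: about 30
#' nodes with roughly 1.7 causal edges per node, an even mix of activating
#' and inhibitory statements, and a tenth of the entities unmeasured
#' (process nodes, genes absent from the expression platform).
#'
#' @param n_nodes total number of nodes including the central node (>= 2).
#' @param extra_edge_prob probability of each optional DAG-respecting edge
#'   beyond the spanning in-tree.
#' @param negative_sign_prob probability that an edge is inhibitory (-1).
#' @param effect_size mean absolute log2 fold change planted on perturbed
#'   nodes (0 = no signal).
#' @param noise_sd standard deviation of Gaussian noise added to each
#'   measured weight.
#' @param fraction_unmeasured fraction of nodes omitted from the weight
#'   table, in `[0, 1)`.
#' @param seed integer seed; the network and weights are reproducible.
#' @return validated list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_nodes = 30L, extra_edge_prob = 0.06,
                           negative_sign_prob = 0.5, effect_size = 1.0,
                           noise_sd = 0.5, fraction_unmeasured = 0.1,
                           seed = 1L) {
  n_nodes <- as.integer(n_nodes)
  if (is.na(n_nodes) || n_nodes < 2L) stop("n_nodes must be >= 2", call. = FALSE)
  stopifnot(
    extra_edge_prob >= 0, extra_edge_prob <= 1,
    negative_sign_prob >= 0, negative_sign_prob <= 1,
    is.finite(effect_size), noise_sd >= 0,
    fraction_unmeasured >= 0, fraction_unmeasured < 1
  )
  structure(
    list(n_nodes = n_nodes, extra_edge_prob = extra_edge_prob,
         negative_sign_prob = negative_sign_prob, effect_size = effect_size,
         noise_sd = noise_sd, fraction_unmeasured = fraction_unmeasured,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic mechanism network
#'
#' Builds a random spanning in-tree toward a designated central node `"X"`
#' (every node has a directed path to it), then adds forward,
#' DAG-respecting extra edges with probability `extra_edge_prob`. Each edge
#' is inhibitory (`decreases`, sign -1) with probability
#' `negative_sign_prob`, otherwise activating (`increases`, +1). The
#' central node has out-degree 0 by construction and the result is already
#' a valid extracted mechanism.
#'
#' @param spec a [synthetic_spec()].
#' @return a `causal_network` with `central = "X"`.
#' @export
generate_mechanism <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_nodes
  set.seed(spec$seed)
  labels <- c(sprintf("N%02d", seq_len(n - 1)), "X")
  # topological position: node i may only point at nodes i+1..n; node n is X
  parent <- integer(n - 1)
  for (i in seq_len(n - 1)) {
    parent[i] <- if (i == n - 1) n else sample((i + 1):n, 1)
  }
  src <- seq_len(n - 1)
  dst <- parent
  tree_edge <- rep(TRUE, n - 1)
  if (spec$extra_edge_prob > 0 && n > 2) {
    for (i in seq_len(n - 2)) {
      for (j in (i + 1):n) {
        if (j == parent[i]) next
        if (stats::runif(1) < spec$extra_edge_prob) {
          src <- c(src, i); dst <- c(dst, j); tree_edge <- c(tree_edge, FALSE)
        }
      }
    }
  }
  sign <- ifelse(stats::runif(length(src)) < spec$negative_sign_prob, -1L, 1L)
  edges <- data.frame(
    source = labels[src], target = labels[dst],
    relation = ifelse(sign == 1L, "increases", "decreases")
  )
  causal_network(edges, nodes = data.frame(label = labels, kind = "gene"),
                 central = "X")
}

# Sign of each node's net influence on the CMPA score. The score is linear
# in the weight vector, so the influence coefficient of node v is the score
# of the indicator weight vector e_v; its sign is the path-sign parity of v
# toward the central node, aggregated over all paths (0 -> +1).
.influence_parity <- function(net, propagate = TRUE) {
  labels <- net$nodes$label
  plan <- .score_plan(net)
  parity <- vapply(seq_along(labels), function(i) {
    e <- numeric(length(labels))
    e[i] <- 1
    c_v <- .eval_plan(plan, e, propagate = propagate)$score
    if (c_v < 0) -1 else 1
  }, numeric(1))
  setNames(parity, labels)
}

#' Generate a synthetic weight table with a planted perturbation
#'
#' Each measured node receives `effect_size * parity + N(0, noise_sd)`,
#' where `parity` is the sign of the node's path-sign parity toward the
#' central node, aggregated over all causal paths (the sign of its net
#' influence coefficient on the score, which is linear in the weights).
#' With this convention every perturbed node pushes the score upward,
#' planting a coherently upregulated mechanism that is positive and
#' significant when `effect_size` dominates `noise_sd`. A fraction of
#' nodes (`fraction_unmeasured`) is omitted from the table, emulating
#' unmeasured genes and process nodes.
#'
#' Weight generation is reproducible from `spec$seed` independently of
#' network generation (the internal stream is seeded with `seed + 1`).
#'
#' @param net a network from [generate_mechanism()].
#' @param spec the same [synthetic_spec()].
#' @return named numeric weight table (possibly missing some node labels).
#' @export
generate_weights <- function(net, spec) {
  stopifnot(inherits(net, "causal_network"), inherits(spec, "synthetic_spec"))
  labels <- net$nodes$label
  parity <- .influence_parity(net)
  set.seed(spec$seed + 1L)
  w <- spec$effect_size * unname(parity[labels]) +
    rnorm(length(labels), 0, spec$noise_sd)
  names(w) <- labels
  n_unmeasured <- floor(spec$fraction_unmeasured * length(labels))
  if (n_unmeasured > 0) {
    drop <- sample(labels, n_unmeasured)
    w <- w[!names(w) %in% drop]
  }
  w
}

#' Independent recursive scoring oracle
#'
#' Reference implementation of the CMPA score by memoized recursion, used
#' to cross-check [cmpa_score()]: it shares no scheduling machinery with
#' the engine. The value of a node is its weight; the value of a hub under
#' propagation is its weight plus the signed sum of its incoming values,
#' resolved recursively. The score is the sum of hub Impact Factors.
#'
#' @param net a `causal_network` (extracted; must be a DAG).
#' @param weights named numeric vector over the nodes.
#' @param propagate logical, as in [cmpa_score()].
#' @return the CMPA score, a single number.
#' @export
oracle_score <- function(net, weights, propagate = TRUE) {
  stopifnot(inherits(net, "causal_network"))
  edges <- net$edges[!is.na(net$edges$sign), , drop = FALSE]
  labels <- net$nodes$label
  w <- setNames(as.numeric(weights[labels]), labels)
  indeg <- table(factor(edges$target, levels = labels))
  outdeg <- table(factor(edges$source, levels = labels))
  is_hub <- setNames(indeg >= 1 & outdeg >= 1, labels)
  if (!is.na(net$central)) is_hub[net$central] <- TRUE

  memo <- new.env(parent = emptyenv())
  state <- new.env(parent = emptyenv())  # cycle detection

  impact <- function(v) {
    if (!is.null(memo[[v]])) return(memo[[v]])
    if (isTRUE(state[[v]])) stop("cycle detected at node ", v, call. = FALSE)
    state[[v]] <- TRUE
    inc <- edges[edges$target == v, , drop = FALSE]
    contrib <- 0
    if (nrow(inc)) {
      vals <- vapply(inc$source, function(s) {
        if (propagate && is_hub[[s]]) impact(s) else w[[s]]
      }, numeric(1))
      contrib <- sum(inc$sign * vals)
    }
    res <- w[[v]] + contrib
    state[[v]] <- FALSE
    memo[[v]] <- res
    res
  }

  sum(vapply(labels[is_hub], impact, numeric(1)))
}
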