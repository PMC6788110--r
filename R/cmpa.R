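# Deterministic content hash (31-polynomial over UTF-8 bytes, mod 2^31-1);
# used only to fingerprint a network in result JSON.
.content_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 0
  m <- 2^31 - 1
  for (b in bytes) h <- (h * 31 + b) %% m
  sprintf("%08x", h)
}

.network_hash <- function(net) {
  edges <- net$edges[order(net$edges$source, net$edges$target,
                           net$edges$relation), , drop = FALSE]
  .content_hash(c(
    paste(edges$source, edges$relation, edges$target, sep = "\t"),
    paste0("central=", net$central)
  ))
}

#' Identify the hubs of a mechanism network
#'
#' A hub is a node with at least one incoming and at least one outgoing
#' causal edge -- a node that both receives and passes on a value. The
#' central node is always a hub: it is the node whose perturbation amplitude
#' is being measured, and its outgoing edges have been removed by
#' [extract_mechanism()], so it would otherwise never qualify.
#'
#' @param net a `causal_network` with `central` set and central out-degree 0.
#' @return character vector of hub labels (unordered).
#' @examples
#' net <- extract_mechanism(causal_network(data.frame(
#'   source = c("H", "G", "D"), relation = "increases",
#'   target = c("G", "D", "X")
#' )), "X")
#' identify_hubs(net)
#' @export
identify_hubs <- function(net) {
  stopifnot(inherits(net, "causal_network"))
  if (is.na(net$central)) {
    stop("network has no central node; run extract_mechanism() first",
         call. = FALSE)
  }
  edges <- net$edges[!is.na(net$edges$sign), , drop = FALSE]
  if (any(edges$source == net$central)) {
    stop("central node still has outgoing edges; run extract_mechanism() first",
         call. = FALSE)
  }
  labels <- net$nodes$label
  indeg <- table(factor(edges$target, levels = labels))
  outdeg <- table(factor(edges$source, levels = labels))
  hubs <- labels[indeg >= 1 & outdeg >= 1]
  union(hubs, net$central)
}

# Kahn-style scheduling over the hub-to-hub edge relation. Returns the
# evaluation order plus any feedback edges removed under break_cycles.
.schedule <- function(edges, hubs, weights = NULL, break_cycles = FALSE) {
  hh <- edges[edges$source %in% hubs & edges$target %in% hubs, , drop = FALSE]
  removed <- hh[0, , drop = FALSE]
  repeat {
    order <- character(0)
    remaining <- sort(hubs)
    active <- hh
    while (length(remaining)) {
      blocked <- unique(active$target[active$source %in% remaining])
      ready <- setdiff(remaining, blocked)
      if (!length(ready)) break
      order <- c(order, ready)  # remaining is sorted, so ready is lexicographic
      remaining <- setdiff(remaining, ready)
      active <- active[active$source %in% remaining, , drop = FALSE]
    }
    if (!length(remaining)) {
      return(list(order = order, removed = removed))
    }
    # a cycle among the remaining hubs: locate a non-trivial SCC
    g <- igraph::graph_from_data_frame(
      active[active$target %in% remaining, c("source", "target"), drop = FALSE],
      directed = TRUE, vertices = remaining
    )
    comp <- igraph::components(g, mode = "strong")
    sizes <- comp$csize[comp$membership]
    cyc <- sort(names(comp$membership)[sizes > 1])
    if (!break_cycles) {
      stop("cycle among hubs: ", paste(cyc, collapse = ", "),
           "; rerun with break_cycles = TRUE to remove feedback edges",
           call. = FALSE)
    }
    if (is.null(weights)) {
      stop("break_cycles requires node weights", call. = FALSE)
    }
    memb <- comp$membership
    in_cycle <- hh$source %in% cyc & hh$target %in% cyc &
      memb[hh$source] == memb[hh$target]
    cand <- hh[in_cycle, , drop = FALSE]
    ord <- order(abs(weights[cand$source]), cand$source, cand$target)
    drop_edge <- cand[ord[1], , drop = FALSE]
    message(sprintf("schedule_hubs: breaking cycle by removing edge %s -> %s",
                    drop_edge$source, drop_edge$target))
    removed <- rbind(removed, drop_edge)
    at <- which(hh$source == drop_edge$source & hh$target == drop_edge$target &
                  hh$relation == drop_edge$relation)[1]
    hh <- hh[-at, , drop = FALSE]
  }
}

#' Order hubs for evaluation
#'
#' Produces a total evaluation order over the hubs such that every hub is
#' emitted only after all hubs with an edge into it: a hub must receive the
#' values of its upstream hubs before passing its own value on. Among
#' simultaneously ready hubs the order is lexicographic by label, which
#' makes runs reproducible and does not affect the score.
#'
#' A cycle among hubs is an error by default. With `break_cycles = TRUE`
#' the in-cycle edge whose source has the smallest absolute weight (ties
#' broken lexicographically by source then target) is removed and
#' scheduling retried; each removal is logged.
#'
#' @param net a `causal_network`.
#' @param hubs character vector of hub labels (see [identify_hubs()]).
#' @param weights named numeric node weights; required for `break_cycles`.
#' @param break_cycles logical, remove feedback edges instead of failing.
#' @return character vector: the hubs in evaluation order.
#' @export
schedule_hubs <- function(net, hubs, weights = NULL, break_cycles = FALSE) {
  stopifnot(inherits(net, "causal_network"), all(hubs %in% net$nodes$label))
  edges <- net$edges[!is.na(net$edges$sign), , drop = FALSE]
  .schedule(edges, hubs, weights, break_cycles)$order
}

#' Impact Factor of a single hub
#'
#' The Impact Factor (IF) of a hub is its own value plus the signed sum of
#' the current values of its incoming neighbours:
#' `IF = value(hub) + sum_i sign_i * value(source_i)` over the hub's
#' incoming causal edges. Parallel edges each contribute a term.
#'
#' @param hub hub label.
#' @param net a `causal_network`.
#' @param values named numeric vector of current node values (raw log2 fold
#'   changes, or propagated Impact Factors for already-scored hubs).
#' @return the Impact Factor, a single number.
#' @examples
#' net <- causal_network(data.frame(
#'   source = c("A", "B"), relation = c("increases", "decreases"),
#'   target = "X"
#' ))
#' impact_factor("X", net, c(A = 1.0, B = 0.25, X = 0.5))
#' @export
impact_factor <- function(hub, net, values) {
  stopifnot(inherits(net, "causal_network"))
  edges <- net$edges[!is.na(net$edges$sign), , drop = FALSE]
  inc <- edges[edges$target == hub, , drop = FALSE]
  need <- c(hub, inc$source)
  if (!all(need %in% names(values))) {
    stop("internal invariant violated: no value for ",
         paste(setdiff(need, names(values)), collapse = ", "), call. = FALSE)
  }
  unname(values[hub] + sum(inc$sign * values[inc$source]))
}

# Precomputed scoring plan: hub order plus integer-indexed incoming edge
# lists, so that thousands of permuted weight vectors can be scored without
# touching the graph again.
.score_plan <- function(net, weights = NULL, break_cycles = FALSE) {
  hubs <- identify_hubs(net)
  edges <- net$edges[!is.na(net$edges$sign), , drop = FALSE]
  sched <- .schedule(edges, hubs, weights, break_cycles)
  if (nrow(sched$removed)) {
    for (i in seq_len(nrow(sched$removed))) {
      at <- which(edges$source == sched$removed$source[i] &
                    edges$target == sched$removed$target[i] &
                    edges$relation == sched$removed$relation[i])[1]
      edges <- edges[-at, , drop = FALSE]
    }
  }
  labels <- net$nodes$label
  idx <- setNames(seq_along(labels), labels)
  incoming <- lapply(sched$order, function(h) {
    inc <- edges[edges$target == h, , drop = FALSE]
    list(src = unname(idx[inc$source]), sign = inc$sign)
  })
  list(labels = labels, order = sched$order, hub_idx = unname(idx[sched$order]),
       incoming = incoming, removed = sched$removed)
}

# Evaluate a plan on a weight vector (ordered as plan$labels).
.eval_plan <- function(plan, w, propagate = TRUE) {
  values <- w
  ifs <- numeric(length(plan$order))
  for (k in seq_along(plan$order)) {
    inc <- plan$incoming[[k]]
    contrib <- if (propagate) values[inc$src] else w[inc$src]
    ifs[k] <- values[plan$hub_idx[k]] + sum(inc$sign * contrib)
    if (propagate) values[plan$hub_idx[k]] <- ifs[k]
  }
  list(score = sum(ifs), impact_factors = setNames(ifs, plan$order))
}

#' Candidate Mechanism Perturbation Amplitude (CMPA) score
#'
#' Scores a mechanism network from node weights (gene-level log2 fold
#' changes). Hubs are identified and ordered so that each hub is evaluated
#' after its upstream hubs; each hub's Impact Factor is its value plus the
#' signed sum of its incoming values, and the CMPA score is the sum of
#' Impact Factors over all hubs. A positive score means the mechanism is
#' upregulated for the dataset, a negative score downregulated, and zero no
#' change.
#'
#' With `propagate = TRUE` (default) a scored hub passes its Impact Factor
#' downstream -- each downstream node receives the accumulated value of its
#' upstream subnetwork. With `propagate = FALSE` every incoming contribution
#' is the raw log2 fold change, the literal reading of the Impact Factor
#' formula.
#'
#' @param net a `causal_network`, already extracted around its central node
#'   (see [extract_mechanism()]).
#' @param weights named numeric vector with one weight per network node
#'   (see [attach_weights()]).
#' @param propagate logical; pass hub Impact Factors downstream.
#' @param break_cycles logical; see [schedule_hubs()].
#' @return an object of class `"cmpa"`: list with `score`,
#'   `impact_factors` (named, in evaluation order), `order`, `n_hubs`,
#'   `unmeasured`, `propagate`, `central` and `network_hash`.
#' @examples
#' net <- extract_mechanism(causal_network(data.frame(
#'   source = c("A", "B"), relation = c("increases", "decreases"),
#'   target = "X"
#' )), "X")
#' fit <- cmpa_score(net, c(A = 2.0, B = 0.5, X = 0.1))
#' fit$score  # 0.1 + 2.0 - 0.5 = 1.6
#' @export
cmpa_score <- function(net, weights, propagate = TRUE, break_cycles = FALSE) {
  stopifnot(inherits(net, "causal_network"))
  labels <- net$nodes$label
  weights <- unlist(weights)
  if (!all(labels %in% names(weights))) {
    stop("weights missing for node(s): ",
         paste(setdiff(labels, names(weights)), collapse = ", "),
         call. = FALSE)
  }
  w <- as.numeric(weights[labels])
  plan <- .score_plan(net, weights = setNames(w, labels),
                      break_cycles = break_cycles)
  ev <- .eval_plan(plan, w, propagate = propagate)
  unmeasured <- attr(weights, "unmeasured")
  if (is.null(unmeasured)) unmeasured <- character(0)
  structure(
    list(
      score = ev$score,
      impact_factors = ev$impact_factors,
      order = plan$order,
      n_hubs = length(plan$order),
      unmeasured = unmeasured,
      propagate = propagate,
      central = net$central,
      network_hash = .network_hash(net)
    ),
    class = "cmpa"
  )
}

#' @export
print.cmpa <- function(x, ...) {
  cat(sprintf("CMPA score: %.6g  (%s)\n", x$score,
              if (x$score > 0) "upregulated" else if (x$score < 0)
                "downregulated" else "no change"))
  cat(sprintf("  central node: %s;  hubs: %d;  unmeasured nodes: %d\n",
              x$central, x$n_hubs, length(x$unmeasured)))
  invisible(x)
}

#' @export
summary.cmpa <- function(object, ...) {
  print(object)
  cat("Impact Factors (evaluation order):\n")
  print(round(object$impact_factors, 6))
  cat("propagate:", object$propagate, "\n")
  invisible(object)
}

#' Per-hub Impact Factors of a fitted CMPA score
#' @param object a `"cmpa"` object.
#' @param ... unused.
#' @return named numeric vector of Impact Factors in evaluation order.
#' @export
coef.cmpa <- function(object, ...) object$impact_factors

#' Serialize a CMPA result to JSON
#'
#' @param result a `"cmpa"` object.
#' @param path optional output path; if `NULL` the JSON string is returned.
#' @return the JSON string (invisibly when written to `path`).
#' @export
cmpa_json <- function(result, path = NULL) {
  stopifnot(inherits(result, "cmpa"))
  obj <- list(
    score = result$score,
    impact_factors = as.list(result$impact_factors),
    hub_order = result$order,
    n_hubs = result$n_hubs,
    unmeasured = result$unmeasured,
    propagate = result$propagate,
    network_hash = result$network_hash
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(txt)
  writeLines(txt, path, useBytes = TRUE)
  invisible(txt)
}
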