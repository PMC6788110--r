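#' @importFrom stats setNames rnorm sd pt
#' @importFrom utils head
NULL

# BEL causal relation keywords and their edge signs. Everything else
# ("association", "hasComponent", "biomarkerFor", ...) is non-causal.
.relation_signs <- c(
  increases = 1L, directlyIncreases = 1L,
  decreases = -1L, directlyDecreases = -1L
)

#' Relation-to-sign mapping for causal edges
#'
#' Maps a BEL-style relation keyword to its edge sign: `increases` and
#' `directlyIncreases` give `+1`, `decreases` and `directlyDecreases` give
#' `-1`, and any other relation gives `NA` (non-causal).
#'
#' @param relation character vector of relation keywords.
#' @return integer vector of signs (`+1`, `-1`, or `NA` for non-causal).
#' @examples
#' relation_sign(c("increases", "directlyDecreases", "association"))
#' @export
relation_sign <- function(relation) {
  out <- unname(.relation_signs[as.character(relation)])
  storage.mode(out) <- "integer"
  out
}

.valid_kinds <- c("gene", "protein", "bioprocess", "other")

#' Construct a signed causal network
#'
#' A causal network holds the entities of a mechanism (genes, proteins,
#' biological processes) and the signed causal edges between them, together
#' with an optional designated central node -- the convergence point of the
#' mechanism whose perturbation amplitude is scored.
#'
#' Self-loops are dropped with a warning: the hub scoring recursion is
#' undefined on them. Parallel edges between the same ordered pair are
#' allowed; each contributes its own signed term. Labels are matched
#' case-sensitively after whitespace trimming.
#'
#' @param edges data.frame with columns `source`, `target`, `relation`
#'   (character). A `sign` column is derived from `relation` via
#'   [relation_sign()] unless already present.
#' @param nodes optional data.frame with columns `label` and `kind`
#'   (one of `"gene"`, `"protein"`, `"bioprocess"`, `"other"`). Nodes
#'   appearing only in `edges` are added with kind `"other"`.
#' @param central label of the central node, or `NA` if not yet designated.
#' @return an object of class `"causal_network"`: a list with elements
#'   `nodes` (data.frame `label`, `kind`), `edges` (data.frame `source`,
#'   `target`, `relation`, `sign`) and `central`.
#' @examples
#' net <- causal_network(data.frame(
#'   source = c("A", "B"), relation = c("increases", "decreases"),
#'   target = c("B", "C")
#' ))
#' net
#' @export
causal_network <- function(edges = NULL, nodes = NULL, central = NA_character_) {
  if (is.null(edges)) {
    edges <- data.frame(
      source = character(), target = character(),
      relation = character(), sign = integer()
    )
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("source", "target", "relation") %in% names(edges)))
  edges$source <- trimws(as.character(edges$source))
  edges$target <- trimws(as.character(edges$target))
  edges$relation <- trimws(as.character(edges$relation))
  if (any(!nzchar(edges$source)) || any(!nzchar(edges$target))) {
    stop("edge endpoints must be non-empty labels", call. = FALSE)
  }
  loops <- edges$source == edges$target
  if (any(loops)) {
    warning(sprintf("dropping %d self-loop edge(s): %s", sum(loops),
                    paste(unique(edges$source[loops]), collapse = ", ")),
            call. = FALSE)
    edges <- edges[!loops, , drop = FALSE]
  }
  if (is.null(edges$sign)) edges$sign <- relation_sign(edges$relation)
  edges$sign <- as.integer(edges$sign)
  if (any(!is.na(edges$sign) & !edges$sign %in% c(-1L, 1L))) {
    stop("edge sign must be +1, -1 or NA", call. = FALSE)
  }

  if (is.null(nodes)) {
    nodes <- data.frame(label = character(), kind = character())
  }
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (is.null(nodes$kind)) nodes$kind <- rep("other", nrow(nodes))
  nodes$label <- trimws(as.character(nodes$label))
  nodes$kind <- as.character(nodes$kind)
  if (anyDuplicated(nodes$label)) {
    stop("duplicate node labels: ",
         paste(unique(nodes$label[duplicated(nodes$label)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!nodes$kind %in% .valid_kinds)) {
    stop("node kind must be one of: ", paste(.valid_kinds, collapse = ", "),
         call. = FALSE)
  }
  implied <- setdiff(unique(c(edges$source, edges$target)), nodes$label)
  if (length(implied)) {
    nodes <- rbind(nodes, data.frame(label = implied, kind = "other"))
  }
  central <- if (length(central) == 1 && !is.na(central)) {
    trimws(as.character(central))
  } else {
    NA_character_
  }
  if (!is.na(central) && !central %in% nodes$label) {
    stop(sprintf("central node '%s' is not in the network", central),
         call. = FALSE)
  }
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(
    list(nodes = nodes, edges = edges[, c("source", "target", "relation", "sign")],
         central = central),
    class = "causal_network"
  )
}

#' @export
print.causal_network <- function(x, ...) {
  n_causal <- sum(!is.na(x$edges$sign))
  cat(sprintf("causal_network: %d nodes, %d edges (%d causal)\n",
              nrow(x$nodes), nrow(x$edges), n_causal))
  if (!is.na(x$central)) cat("  central node:", x$central, "\n")
  invisible(x)
}

#' Node labels of a causal network
#' @param net a `causal_network`.
#' @return character vector of node labels.
#' @export
network_labels <- function(net) {
  stopifnot(inherits(net, "causal_network"))
  net$nodes$label
}

# igraph view of the causal edges (multigraph; non-causal edges optionally
# included). Isolated nodes are preserved as vertices.
.as_igraph <- function(net, causal_only = TRUE) {
  edges <- net$edges
  if (causal_only) edges <- edges[!is.na(edges$sign), , drop = FALSE]
  igraph::graph_from_data_frame(
    edges[, c("source", "target", "relation", "sign")],
    directed = TRUE, vertices = net$nodes$label
  )
}

#' Read a causal network from file
#'
#' Supported formats:
#' \describe{
#'   \item{`edge_list`}{UTF-8 TSV with header `source<TAB>relation<TAB>target`,
#'     one edge per row; lines starting with `#` are comments.}
#'   \item{`graphml`}{GraphML with a string edge attribute `relation`; the
#'     node `id` is the label, an optional node attribute `kind` is kept.}
#'   \item{`node_link`}{JSON with keys `nodes` (list of `{id, kind}`),
#'     `links` (list of `{source, target, relation}`) and `central`
#'     (string or null).}
#' }
#' Relation keywords are kept verbatim; signs are attached for recognized
#' causal relations and `NA` marks non-causal edges (see [filter_causal()]).
#'
#' @param path path to the network file.
#' @param format one of `"edge_list"`, `"graphml"`, `"node_link"`.
#' @return a [causal_network()].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("source\trelation\ttarget", "A\tincreases\tB"), tf)
#' read_network(tf)
#' @export
read_network <- function(path, format = c("edge_list", "graphml", "node_link")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(format,
    edge_list = .read_edge_list(path),
    graphml = .read_graphml(path),
    node_link = .read_node_link(path)
  )
}

.read_edge_list <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    stop("edge list is empty (no header): ", path, call. = FALSE)
  }
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (!identical(trimws(header), c("source", "relation", "target"))) {
    stop("edge list header must be 'source<TAB>relation<TAB>target', got: ",
         lines[[1]], call. = FALSE)
  }
  if (length(lines) == 1) return(causal_network())
  parts <- strsplit(lines[-1], "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) != 3L)
  if (length(bad)) {
    stop(sprintf("malformed edge row at line %d (expected 3 tab-separated columns): %s",
                 lineno[bad[1] + 1], lines[bad[1] + 1]), call. = FALSE)
  }
  m <- do.call(rbind, parts)
  causal_network(data.frame(
    source = m[, 1], relation = m[, 2], target = m[, 3]
  ))
}

.read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  labels <- igraph::vertex_attr(g, "id")
  if (is.null(labels)) labels <- igraph::vertex_attr(g, "name")
  if (is.null(labels)) stop("GraphML nodes carry no id attribute", call. = FALSE)
  kind <- igraph::vertex_attr(g, "kind")
  if (is.null(kind)) kind <- rep("other", length(labels))
  kind[is.na(kind) | !kind %in% .valid_kinds] <- "other"
  el <- igraph::as_edgelist(g, names = FALSE)
  relation <- igraph::edge_attr(g, "relation")
  if (is.null(relation)) stop("GraphML edges carry no 'relation' attribute",
                              call. = FALSE)
  central <- igraph::graph_attr(g, "central")
  if (is.null(central) || !nzchar(central)) central <- NA_character_
  causal_network(
    edges = data.frame(source = labels[el[, 1]], target = labels[el[, 2]],
                       relation = relation),
    nodes = data.frame(label = labels, kind = kind),
    central = central
  )
}

.read_node_link <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  nodes <- as.data.frame(j$nodes, stringsAsFactors = FALSE)
  if (nrow(nodes)) {
    names(nodes)[names(nodes) == "id"] <- "label"
    if (is.null(nodes$kind)) nodes$kind <- "other"
    nodes$kind[is.na(nodes$kind)] <- "other"
  } else {
    nodes <- NULL
  }
  links <- as.data.frame(j$links, stringsAsFactors = FALSE)
  edges <- if (nrow(links)) {
    data.frame(source = links$source, target = links$target,
               relation = links$relation)
  } else {
    NULL
  }
  central <- j$central
  if (is.null(central)) central <- NA_character_
  causal_network(edges = edges, nodes = nodes, central = central)
}

#' Write a causal network
#'
#' Writes the edge-list TSV (`source<TAB>relation<TAB>target`) or the JSON
#' node-link form documented in [read_network()].
#'
#' @param net a `causal_network`.
#' @param path output path.
#' @param format `"edge_list"` or `"node_link"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("edge_list", "node_link")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "causal_network"))
  if (format == "edge_list") {
    lines <- c("source\trelation\ttarget",
               sprintf("%s\t%s\t%s", net$edges$source, net$edges$relation,
                       net$edges$target))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    obj <- list(
      nodes = lapply(seq_len(nrow(net$nodes)), function(i) {
        list(id = net$nodes$label[i], kind = net$nodes$kind[i])
      }),
      links = lapply(seq_len(nrow(net$edges)), function(i) {
        list(source = net$edges$source[i], target = net$edges$target[i],
             relation = net$edges$relation[i])
      }),
      central = if (is.na(net$central)) NULL else net$central
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null",
                         digits = NA)
  }
  invisible(path)
}

#' Keep only causal edges
#'
#' Retains edges whose relation maps to a sign (`increases`,
#' `directlyIncreases` to `+1`; `decreases`, `directlyDecreases` to `-1`),
#' drops all other relations, and removes nodes left isolated (the central
#' node, if designated, is always kept). The number of dropped edges is
#' reported via [message()]. Idempotent.
#'
#' @param net a `causal_network`.
#' @return the filtered `causal_network`.
#' @examples
#' net <- causal_network(data.frame(
#'   source = c("A", "A"), relation = c("increases", "association"),
#'   target = c("B", "C")
#' ))
#' filter_causal(net)
#' @export
filter_causal <- function(net) {
  stopifnot(inherits(net, "causal_network"))
  causal <- !is.na(net$edges$sign)
  dropped <- sum(!causal)
  if (dropped > 0) {
    message(sprintf("filter_causal: dropped %d non-causal edge(s)", dropped))
  }
  edges <- net$edges[causal, , drop = FALSE]
  used <- unique(c(edges$source, edges$target))
  keep <- net$nodes$label %in% used |
    (!is.na(net$central) & net$nodes$label == net$central)
  causal_network(edges = edges, nodes = net$nodes[keep, , drop = FALSE],
                 central = net$central)
}

#' Extract the mechanism subgraph around a central node
#'
#' Returns the subgraph induced by all nodes that can reach `central` along
#' causal edges in at most `radius` hops (upstream neighbourhood), plus the
#' central node itself. All edges outgoing from the central node are removed:
#' the central node connects onward only to other mechanisms and is not
#' scored downstream. The default radius of 5 nearest neighbours is the
#' conventional mechanism network size.
#'
#' @param net a `causal_network` (non-causal edges are ignored; run
#'   [filter_causal()] first to drop them explicitly).
#' @param central label of the central node.
#' @param radius positive integer, maximum number of upstream hops.
#' @return a `causal_network` with `central` set and central out-degree 0.
#' @examples
#' net <- causal_network(data.frame(
#'   source = c("H", "G", "D"), relation = "increases",
#'   target = c("G", "D", "X")
#' ))
#' extract_mechanism(net, "X")
#' @export
extract_mechanism <- function(net, central, radius = 5L) {
  stopifnot(inherits(net, "causal_network"))
  central <- trimws(as.character(central))
  if (!central %in% net$nodes$label) {
    stop(sprintf("central node '%s' is not in the network", central),
         call. = FALSE)
  }
  radius <- as.integer(radius)
  if (is.na(radius) || radius < 1L) stop("radius must be >= 1", call. = FALSE)

  g <- .as_igraph(net, causal_only = TRUE)
  # hop distance from every node to the central node, following edge direction
  d <- igraph::distances(g, to = central, mode = "out")[, 1]
  keep <- names(d)[is.finite(d) & d <= radius]
  keep <- union(keep, central)

  edges <- net$edges[!is.na(net$edges$sign), , drop = FALSE]
  edges <- edges[edges$source %in% keep & edges$target %in% keep, , drop = FALSE]
  edges <- edges[edges$source != central, , drop = FALSE]
  nodes <- net$nodes[net$nodes$label %in% keep, , drop = FALSE]
  causal_network(edges = edges, nodes = nodes, central = central)
}
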