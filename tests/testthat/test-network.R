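test_that("edge-list reader parses rows, keeps raw relations, flags causality", {
  path <- write_lines_tmp(c(
    "source\trelation\ttarget",
    "A\tincreases\tB",
    "B\tdecreases\tC",
    "A\tassociation\tC"
  ))
  net <- read_network(path)
  expect_s3_class(net, "causal_network")
  expect_setequal(network_labels(net), c("A", "B", "C"))
  expect_equal(nrow(net$edges), 3)
  expect_equal(sum(!is.na(net$edges$sign)), 2)
  expect_equal(net$edges$relation, c("increases", "decreases", "association"))
  expect_equal(net$edges$sign, c(1L, -1L, NA_integer_))
})

test_that("edge-list reader handles empty and malformed input", {
  empty <- read_network(write_lines_tmp("source\trelation\ttarget"))
  expect_equal(nrow(empty$nodes), 0)
  expect_equal(nrow(empty$edges), 0)

  bad <- write_lines_tmp(c("source\trelation\ttarget", "A\tincreases"))
  expect_error(read_network(bad), "line 2")
  expect_error(read_network(write_lines_tmp("x\ty\tz")), "header")
  expect_error(read_network(tempfile()), "not found")
})

test_that("comment lines are skipped and reported line numbers stay true", {
  path <- write_lines_tmp(c(
    "# a comment", "source\trelation\ttarget", "A\tincreases\tB",
    "# another", "B\tbroken"
  ))
  expect_error(read_network(path), "line 5")
})

test_that("labels are trimmed but matched case-sensitively", {
  path <- write_lines_tmp(c(
    "source\trelation\ttarget",
    " A \tincreases\tB",
    "a\tincreases\tB"
  ))
  net <- read_network(path)
  expect_setequal(network_labels(net), c("A", "a", "B"))
})

test_that("self-loops are rejected with a warning at load", {
  expect_warning(
    net <- causal_network(data.frame(
      source = c("A", "B"), relation = "increases", target = c("A", "X")
    )),
    "self-loop"
  )
  expect_equal(nrow(net$edges), 1)
})

test_that("parallel edges between the same pair are kept", {
  net <- causal_network(data.frame(
    source = "A", relation = c("increases", "decreases"), target = "X"
  ))
  expect_equal(nrow(net$edges), 2)
  mech <- extract_mechanism(net, "X")
  w <- c(A = 1, X = 0)
  # both parallel edges contribute their own signed term
  expect_equal(cmpa_score(mech, w)$score, 0)
})

test_that("GraphML round trip preserves labels, kinds and relations", {
  path <- write_lines_tmp(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="d0" for="edge" attr.name="relation" attr.type="string"/>',
    '  <key id="d1" for="node" attr.name="kind" attr.type="string"/>',
    '  <graph id="G" edgedefault="directed">',
    '    <node id="SNCA"><data key="d1">gene</data></node>',
    '    <node id="X"/>',
    '    <edge source="SNCA" target="X"><data key="d0">increases</data></edge>',
    '  </graph>',
    '</graphml>'
  ), ext = ".graphml")
  net <- read_network(path, format = "graphml")
  expect_setequal(network_labels(net), c("SNCA", "X"))
  expect_equal(net$nodes$kind[net$nodes$label == "SNCA"], "gene")
  expect_equal(net$edges$sign, 1L)
})

test_that("JSON node-link round trip preserves the network and central node", {
  net <- causal_network(
    edges = data.frame(source = c("A", "B"), relation = c("increases", "association"),
                       target = "X"),
    nodes = data.frame(label = c("A", "B", "X"),
                       kind = c("gene", "protein", "bioprocess")),
    central = "X"
  )
  path <- tempfile(fileext = ".json")
  write_network(net, path, format = "node_link")
  back <- read_network(path, format = "node_link")
  expect_equal(back$nodes, net$nodes)
  expect_equal(back$edges, net$edges)
  expect_equal(back$central, "X")
})

test_that("filter_causal keeps signed edges, drops the rest and isolated nodes", {
  net <- causal_network(data.frame(
    source = c("A", "A"), relation = c("increases", "association"),
    target = c("B", "C")
  ))
  expect_message(flt <- filter_causal(net), "dropped 1")
  expect_setequal(network_labels(flt), c("A", "B"))
  expect_equal(flt$edges$sign, 1L)

  neg <- filter_causal(causal_network(data.frame(
    source = "A", relation = "directlyDecreases", target = "B"
  )))
  expect_equal(neg$edges$sign, -1L)
})

test_that("filter_causal is idempotent and keeps the central node", {
  net <- causal_network(
    edges = data.frame(source = c("A", "B"), relation = c("increases", "biomarkerFor"),
                       target = c("B", "C")),
    central = "C"
  )
  once <- suppressMessages(filter_causal(net))
  twice <- suppressMessages(filter_causal(once))
  expect_equal(once, twice)
  expect_true("C" %in% network_labels(once))

  all_causal <- causal_network(data.frame(
    source = "A", relation = "increases", target = "B"
  ))
  expect_equal(filter_causal(all_causal), all_causal)
})

test_that("extract_mechanism keeps the upstream radius around the central node", {
  chain <- causal_network(data.frame(
    source = c("H", "G", "D"), relation = "increases", target = c("G", "D", "X")
  ))
  full <- extract_mechanism(chain, "X", radius = 5)
  expect_setequal(network_labels(full), c("H", "G", "D", "X"))

  abc <- causal_network(data.frame(
    source = c("A", "B", "C"), relation = "increases", target = c("B", "C", "X")
  ))
  near <- extract_mechanism(abc, "X", radius = 2)
  expect_setequal(network_labels(near), c("B", "C", "X"))
})

test_that("extract_mechanism removes edges outgoing from the central node", {
  net <- causal_network(data.frame(
    source = c("X", "Q"), relation = "increases", target = c("P", "X")
  ))
  mech <- extract_mechanism(net, "X")
  expect_false(any(mech$edges$source == "X"))
  expect_true(any(mech$edges$source == "Q" & mech$edges$target == "X"))
  expect_equal(mech$central, "X")
})

test_that("extract_mechanism errors on an unknown central node", {
  net <- causal_network(data.frame(source = "A", relation = "increases",
                                   target = "B"))
  expect_error(extract_mechanism(net, "Z"), "'Z'")
  expect_error(extract_mechanism(net, "B", radius = 0), "radius")
})

test_that("extraction is monotone in radius and leaves central out-degree 0", {
  for (seed in 1:20) {
    net <- random_mechanism(seed)
    # rebuild an unextracted variant with some spurious central out-edges
    raw <- causal_network(
      rbind(net$edges,
            data.frame(source = "X", target = net$nodes$label[1],
                       relation = "increases", sign = 1L)),
      nodes = net$nodes
    )
    prev <- character(0)
    for (r in 1:4) {
      mech <- extract_mechanism(raw, "X", radius = r)
      expect_true(all(prev %in% network_labels(mech)))
      expect_equal(sum(mech$edges$source == "X"), 0)
      prev <- network_labels(mech)
    }
  }
})
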