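#' Read a log2 fold-change weight table
#'
#' Reads a delimited table with header columns `label` and `log2fc` (tab for
#' `.tsv`/`.txt`, comma for `.csv`; lines starting with `#` are comments).
#' Duplicate labels -- typically multi-probe artifacts of expression arrays --
#' are resolved by their arithmetic mean with a warning. Non-numeric or
#' non-finite weights are a parse error naming the offending line.
#'
#' @param path path to the table.
#' @return a named numeric vector of log2 fold changes (a weight table);
#'   empty input yields an empty vector.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("label\tlog2fc", "SNCA\t1.5", "MAPT\t-0.7"), tf)
#' read_weights(tf)
#' @export
read_weights <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("weight table is empty (no header): ", path,
                           call. = FALSE)
  header <- trimws(strsplit(lines[[1]], sep, fixed = TRUE)[[1]])
  if (!identical(header[1:2], c("label", "log2fc"))) {
    stop("weight table header must start with 'label", sep, "log2fc', got: ",
         lines[[1]], call. = FALSE)
  }
  if (length(lines) == 1) return(setNames(numeric(), character()))
  parts <- strsplit(lines[-1], sep, fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad)) {
    stop(sprintf("malformed weight row at line %d (expected 2 columns): %s",
                 lineno[bad[1] + 1], lines[bad[1] + 1]), call. = FALSE)
  }
  labels <- trimws(vapply(parts, `[`, "", 1L))
  raw <- trimws(vapply(parts, `[`, "", 2L))
  vals <- suppressWarnings(as.numeric(raw))
  bad <- which(!is.finite(vals))
  if (length(bad)) {
    stop(sprintf("non-numeric or non-finite weight at line %d: '%s'",
                 lineno[bad[1] + 1], raw[bad[1]]), call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    dups <- unique(labels[duplicated(labels)])
    warning(sprintf("averaging %d duplicated label(s): %s", length(dups),
                    paste(head(dups, 5), collapse = ", ")), call. = FALSE)
    agg <- tapply(vals, labels, mean)
    # tapply sorts by label; restore first-appearance order
    ord <- unique(labels)
    return(setNames(as.numeric(agg[ord]), ord))
  }
  setNames(vals, labels)
}

#' Write a weight table
#'
#' @param weights named numeric vector of log2 fold changes.
#' @param path output path (`.csv` for comma-separated, tab otherwise).
#' @return `path`, invisibly.
#' @export
write_weights <- function(weights, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  lines <- c(paste("label", "log2fc", sep = sep),
             paste(names(weights), format(weights, digits = 17, trim = TRUE,
                                          scientific = FALSE), sep = sep))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Attach expression weights to network nodes
#'
#' Every node of the network receives a weight. Nodes absent from the table
#' are unmeasured: under `missing_policy = "zero"` (the default) they get
#' weight 0 -- the neutral element of the Impact Factor sum -- and are
#' recorded in the `"unmeasured"` attribute of the result. Under
#' `missing_policy = "error"`, an unmeasured node of kind `gene`, `protein`
#' or `other` aborts with a message listing the unmatched labels
#' (`bioprocess` nodes are never expression-measured and are always
#' zero-filled). Table labels absent from the network are ignored with a
#' message.
#'
#' @param net a `causal_network`.
#' @param weights named numeric weight table (see [read_weights()]).
#' @param missing_policy `"zero"` or `"error"`.
#' @return named numeric vector with one weight per network node, in node
#'   order, carrying attribute `"unmeasured"` (character vector of
#'   zero-filled labels).
#' @examples
#' net <- causal_network(data.frame(source = "A", relation = "increases",
#'                                  target = "B"))
#' attach_weights(net, c(A = 1.2))
#' @export
attach_weights <- function(net, weights, missing_policy = c("zero", "error")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(net, "causal_network"))
  if (nrow(net$nodes) == 0) stop("network has no nodes", call. = FALSE)
  weights <- unlist(weights)
  stopifnot(is.numeric(weights))
  if (length(weights) && is.null(names(weights))) {
    stop("weights must be a named vector", call. = FALSE)
  }
  labels <- net$nodes$label
  extra <- setdiff(names(weights), labels)
  if (length(extra)) {
    message(sprintf("attach_weights: ignoring %d table label(s) not in the network",
                    length(extra)))
  }
  hit <- labels %in% names(weights)
  unmeasured <- labels[!hit]
  if (missing_policy == "error") {
    measurable <- unmeasured[net$nodes$kind[!hit] != "bioprocess"]
    if (length(measurable)) {
      stop("unmeasured node(s) with missing_policy = 'error': ",
           paste(measurable, collapse = ", "), call. = FALSE)
    }
  }
  if (length(unmeasured)) {
    message(sprintf("attach_weights: %d unmeasured node(s) set to 0",
                    length(unmeasured)))
  }
  out <- setNames(numeric(length(labels)), labels)
  out[labels[hit]] <- as.numeric(weights[labels[hit]])
  attr(out, "unmeasured") <- unmeasured
  out
}
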