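#' Declare a single network node
#'
#' A node in a threshold-logic Boolean network. Dynamic nodes update by the
#' synchronous rules (on next step iff at least `threshold` activators are on
#' and no inhibitor is on). A `constant_one` node is pinned at 1 (the always-on
#' excitatory drive `E`); an `external_input` node takes its value from a
#' supplied periodic spike stream (a control signal `C_i`).
#'
#' @param id Unique node identifier (character scalar).
#' @param kind One of `"dynamic"`, `"constant_one"`, `"external_input"`.
#' @param activators Character vector of activating node ids.
#' @param inhibitors Character vector of inhibiting node ids (disjoint from
#'   `activators`).
#' @param threshold Positive integer: number of simultaneously active
#'   activators required to turn the node on.
#' @return A `node_spec` object.
#' @examples
#' node_spec("X1", activators = c("S1", "S2"), threshold = 2)
#' @export
node_spec <- function(id, kind = c("dynamic", "constant_one", "external_input"),
                      activators = character(), inhibitors = character(),
                      threshold = 1L) {
  kind <- match.arg(kind)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  activators <- as.character(activators)
  inhibitors <- as.character(inhibitors)
  threshold <- as.integer(threshold)
  if (kind == "dynamic" && (is.na(threshold) || threshold < 1L))
    stop("invalid-spec: dynamic node '", id, "' needs threshold >= 1")
  if (kind != "dynamic" && (length(activators) || length(inhibitors)))
    stop("invalid-spec: node '", id, "' of kind '", kind,
         "' must not have incoming edges")
  if (length(intersect(activators, inhibitors)))
    stop("invalid-spec: node '", id, "' has overlapping activators/inhibitors")
  structure(list(id = id, kind = kind, activators = activators,
                 inhibitors = inhibitors, threshold = threshold),
            class = "node_spec")
}

#' Assemble a Boolean network from node declarations
#'
#' @param nodes List of [node_spec()] objects (order is preserved and defines
#'   the column order of trajectories).
#' @param inputs Character vector of control-input node ids (must all be
#'   `external_input` nodes). Defaults to every `external_input` node.
#' @param outputs Character vector of observable output node ids.
#' @return A `network_spec` object.
#' @examples
#' net <- network_spec(list(
#'   node_spec("E", "constant_one"),
#'   node_spec("A", activators = "E")
#' ), outputs = "A")
#' @export
network_spec <- function(nodes, inputs = NULL, outputs = character()) {
  stopifnot(is.list(nodes), all(vapply(nodes, inherits, TRUE, "node_spec")))
  ids <- vapply(nodes, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("invalid-spec: duplicate node ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  kind <- vapply(nodes, `[[`, "", "kind")
  if (is.null(inputs)) inputs <- ids[kind == "external_input"]
  bad_ep <- setdiff(unlist(lapply(nodes, function(n)
    c(n$activators, n$inhibitors))), ids)
  if (length(bad_ep))
    stop("invalid-spec: edge refers to undeclared node(s): ",
         paste(bad_ep, collapse = ", "))
  bad_ref <- setdiff(c(inputs, outputs), ids)
  if (length(bad_ref))
    stop("invalid-spec: undeclared node(s) in inputs/outputs: ",
         paste(bad_ref, collapse = ", "))
  if (!all(kind[match(inputs, ids)] == "external_input"))
    stop("invalid-spec: inputs must be external_input nodes")
  structure(list(nodes = stats::setNames(nodes, ids), ids = ids,
                 inputs = as.character(inputs),
                 outputs = as.character(outputs)),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  kind <- vapply(x$nodes, `[[`, "", "kind")
  n_edges <- sum(vapply(x$nodes, function(n)
    length(n$activators) + length(n$inhibitors), 0L))
  cat("<network_spec> ", length(x$ids), " nodes (",
      sum(kind == "dynamic"), " dynamic), ", n_edges, " edges\n", sep = "")
  if (length(x$inputs))
    cat("  inputs:  ", paste(x$inputs, collapse = ", "), "\n", sep = "")
  if (length(x$outputs))
    cat("  outputs: ", paste(x$outputs, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Flatten a network_spec into the CSR arrays the C++ kernel consumes.
compile_network <- function(spec) {
  ids <- spec$ids
  n <- length(ids)
  kind_code <- c(dynamic = 0L, constant_one = 1L, external_input = 2L)
  kind <- unname(kind_code[vapply(spec$nodes, `[[`, "", "kind")])
  thr <- vapply(spec$nodes, `[[`, 1L, "threshold")
  acts <- lapply(spec$nodes, function(nd) match(nd$activators, ids) - 1L)
  inhs <- lapply(spec$nodes, function(nd) match(nd$inhibitors, ids) - 1L)
  list(kind = kind, thr = unname(thr),
       act_ptr = c(0L, cumsum(lengths(acts))),
       act_idx = as.integer(unlist(acts, use.names = FALSE)),
       inh_ptr = c(0L, cumsum(lengths(inhs))),
       inh_idx = as.integer(unlist(inhs, use.names = FALSE)),
       in_nodes = match(spec$inputs, ids) - 1L,
       n = n, ids = ids)
}

#' Write / read a network specification as JSON
#'
#' The document has the shape
#' `{nodes: [{id, kind, activators, inhibitors, threshold}], inputs, outputs}`
#' and round-trips losslessly.
#'
#' @param spec A [network_spec()].
#' @param path File path.
#' @return `write_network_json` returns `path` invisibly; `read_network_json`
#'   returns a `network_spec`.
#' @export
write_network_json <- function(spec, path) {
  stopifnot(inherits(spec, "network_spec"))
  doc <- list(
    nodes = lapply(unname(spec$nodes), function(nd)
      list(id = nd$id, kind = nd$kind,
           activators = I(nd$activators), inhibitors = I(nd$inhibitors),
           threshold = nd$threshold)),
    inputs = I(spec$inputs), outputs = I(spec$outputs))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  nodes <- lapply(doc$nodes, function(nd)
    node_spec(nd$id, nd$kind,
              activators = unlist(nd$activators),
              inhibitors = unlist(nd$inhibitors),
              threshold = if (is.null(nd$threshold)) 1L else nd$threshold))
  network_spec(nodes, inputs = unlist(doc$inputs),
               outputs = if (length(doc$outputs)) unlist(doc$outputs)
                         else character())
}
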