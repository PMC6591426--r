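#' One synchronous update step (reference implementation)
#'
#' Applies the threshold-logic update rules to every node simultaneously:
#' a dynamic node is 1 in the next step iff at least `threshold` of its
#' activators are 1 in the current step and none of its inhibitors is
#' (inhibition dominates); constant nodes stay 1; external inputs take the
#' supplied bits. This pure-R stepper reads only the current state (two
#' buffers by construction) and serves as the reference against which the
#' compiled simulation kernel is checked.
#'
#' @param spec A [network_spec()].
#' @param state Named integer vector of bits covering every node.
#' @param input_bits Named bits for every external input node (their value at
#'   the *next* step).
#' @return Named integer state vector for the next step.
#' @examples
#' ring <- build_generator_ring(2)
#' st <- init_state(ring)
#' next_state(ring, st)
#' @export
next_state <- function(spec, state, input_bits = integer()) {
  stopifnot(inherits(spec, "network_spec"))
  miss <- setdiff(spec$ids, names(state))
  if (length(miss))
    stop("invalid-state: state is missing node(s): ",
         paste(miss, collapse = ", "))
  miss_in <- setdiff(spec$inputs, names(input_bits))
  if (length(miss_in))
    stop("invalid-state: missing input bit(s) for: ",
         paste(miss_in, collapse = ", "))
  nxt <- stats::setNames(integer(length(spec$ids)), spec$ids)
  for (nd in spec$nodes) {
    nxt[[nd$id]] <- switch(nd$kind,
      constant_one = 1L,
      external_input = as.integer(input_bits[[nd$id]]),
      dynamic = {
        if (length(nd$inhibitors) && any(state[nd$inhibitors] == 1L)) 0L
        else as.integer(sum(state[nd$activators] == 1L) >= nd$threshold)
      })
  }
  nxt
}

#' Initial state helper
#'
#' All-zero state with constant nodes at 1 and external inputs at their
#' stream value for step 0; any named bits in `active` are set to 1.
#'
#' @param spec A [network_spec()].
#' @param active Character vector of node ids to set to 1.
#' @param inputs Named list of [periodic_input()] streams (one per input node).
#' @return Named integer state vector (step 0).
#' @export
init_state <- function(spec, active = character(), inputs = list()) {
  st <- stats::setNames(integer(length(spec$ids)), spec$ids)
  kind <- vapply(spec$nodes, `[[`, "", "kind")
  st[kind == "constant_one"] <- 1L
  bad <- setdiff(active, spec$ids)
  if (length(bad))
    stop("invalid-state: unknown node(s): ", paste(bad, collapse = ", "))
  st[active] <- 1L
  for (id in spec$inputs)
    if (!is.null(inputs[[id]])) st[[id]] <- input_stream(inputs[[id]], 0L)
  st
}

check_inputs <- function(spec, inputs) {
  miss <- setdiff(spec$inputs, names(inputs))
  if (length(miss))
    stop("invalid-state: no input stream supplied for: ",
         paste(miss, collapse = ", "))
  for (id in spec$inputs)
    stopifnot(inherits(inputs[[id]], "periodic_input"))
  invisible(TRUE)
}

lcm2 <- function(a, b) {
  g <- function(x, y) if (y == 0) x else Recall(y, x %% y)
  a %/% g(a, b) * b
}

input_lcm <- function(spec, inputs) {
  if (!length(spec$inputs)) return(1L)
  Reduce(lcm2, vapply(inputs[spec$inputs], `[[`, 1L, "period"), 1L)
}

kernel_args <- function(spec, inputs, init) {
  cn <- compile_network(spec)
  if (is.null(init)) init <- init_state(spec, inputs = inputs)
  if (!all(spec$ids %in% names(init)))
    stop("invalid-state: init must cover every node")
  ip <- vapply(spec$inputs, function(id) inputs[[id]]$period, 1L)
  iph <- vapply(spec$inputs, function(id) inputs[[id]]$phase, 1L)
  c(cn[c("kind", "thr", "act_ptr", "act_idx", "inh_ptr", "inh_idx",
         "in_nodes")],
    list(in_period = as.integer(ip), in_phase = as.integer(iph),
         init = as.integer(init[spec$ids])))
}

#' Simulate a network for a fixed number of steps
#'
#' Runs the synchronous update from `init` (step 0) for `steps` steps,
#' driving every external input node from its periodic stream. Deterministic
#' given `init` and `inputs`.
#'
#' @inheritParams next_state
#' @param inputs Named list of [periodic_input()] streams, one per input node.
#' @param init Initial named state (defaults to [init_state()]: all zeros,
#'   constants on).
#' @param steps Number of update steps (`>= 1`).
#' @param record Node ids to record (default: all).
#' @return A `bn_trajectory`: list with `series` (a `(steps+1) x
#'   length(record)` 0/1 matrix, rows = steps starting at 0) and the run
#'   metadata.
#' @examples
#' net <- build_net_a(net_a_params(k = 4, N = 2))
#' tr <- simulate_network(net, inputs = list(C1 = periodic_input(3)), steps = 20)
#' node_series(tr, "X1")
#' @export
simulate_network <- function(spec, inputs = list(), init = NULL, steps,
                             record = NULL) {
  stopifnot(inherits(spec, "network_spec"), steps >= 1)
  check_inputs(spec, inputs)
  if (is.null(record)) record <- spec$ids
  bad <- setdiff(record, spec$ids)
  if (length(bad)) stop("unknown node id(s): ", paste(bad, collapse = ", "))
  ka <- kernel_args(spec, inputs, init)
  m <- do.call(.sim_kernel, c(ka, list(
    steps = as.integer(steps),
    record = match(record, spec$ids) - 1L)))
  colnames(m) <- record
  structure(list(series = m, steps = as.integer(steps), inputs = inputs),
            class = "bn_trajectory")
}

#' @export
print.bn_trajectory <- function(x, ...) {
  cat("<bn_trajectory> ", x$steps, " steps, ", ncol(x$series),
      " recorded node(s)\n", sep = "")
  invisible(x)
}

#' Detect the eventual repeating cycle of a driven network
#'
#' A finite deterministic Boolean network must revisit a state, after which
#' the trajectory repeats. The augmented state hashed here is the exact bit
#' vector of all nodes plus the input phase counter (`t mod lcm` of the input
#' periods), so the detected cycle is exact for periodically driven networks.
#'
#' @inheritParams simulate_network
#' @param cap Step cap before giving up; defaults to
#'   `50 * lcm(input periods) + #nodes`.
#' @return A `bn_cycle`: `transient_length`, `cycle_length`, and `cycle`
#'   (a `cycle_length x #nodes` 0/1 matrix; applying one update step to its
#'   last row reproduces its first row).
#' @examples
#' find_cycle(build_generator_ring(3))$cycle_length
#' @export
find_cycle <- function(spec, inputs = list(), init = NULL, cap = NULL) {
  stopifnot(inherits(spec, "network_spec"))
  check_inputs(spec, inputs)
  L <- input_lcm(spec, inputs)
  if (is.null(cap)) cap <- 50L * L + length(spec$ids)
  stopifnot(cap >= 1)
  ka <- kernel_args(spec, inputs, init)
  res <- do.call(.cycle_kernel, c(ka, list(
    lcm_period = as.integer(L), cap = as.integer(cap))))
  if (!isTRUE(res$found))
    stop("cycle-not-found: no state recurrence within cap = ", cap, " steps")
  cyc <- res$cycle
  colnames(cyc) <- spec$ids
  structure(list(transient_length = res$transient,
                 cycle_length = res$cycle_length, cycle = cyc,
                 inputs = inputs),
            class = "bn_cycle")
}

#' @export
print.bn_cycle <- function(x, ...) {
  cat("<bn_cycle> transient ", x$transient_length, ", cycle length ",
      x$cycle_length, "\n", sep = "")
  invisible(x)
}

#' Extract one node's bit sequence
#'
#' @param x A `bn_trajectory` or `bn_cycle`.
#' @param node Node id.
#' @return Integer bit vector: the recorded series (trajectory) or the cyclic
#'   pattern of length `cycle_length` (cycle).
#' @export
node_series <- function(x, node) UseMethod("node_series")

#' @export
node_series.bn_trajectory <- function(x, node) {
  if (!node %in% colnames(x$series)) stop("unknown node id: ", node)
  unname(x$series[, node])
}

#' @export
node_series.bn_cycle <- function(x, node) {
  if (!node %in% colnames(x$cycle)) stop("unknown node id: ", node)
  unname(x$cycle[, node])
}

#' Write a trajectory as TSV
#'
#' One row per step; first column `step`, then one 0/1 column per recorded
#' node.
#'
#' @param x A `bn_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_tsv <- function(x, path) {
  stopifnot(inherits(x, "bn_trajectory"))
  df <- data.frame(step = 0:x$steps, x$series, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
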