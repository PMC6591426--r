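#' Periodic tonic-spiking input stream
#'
#' A control signal that emits a single spike (1) every `period` steps: the
#' bit at step `t` is 1 iff `(t - phase) mod period == 0`. This is the compact
#' equivalent of embedding an autonomous generator ring
#' (see [build_generator_ring()]) and is how control inputs `C_i` are driven.
#'
#' @param period Positive integer spike period `p`.
#' @param phase Integer phase offset in `[0, period)`.
#' @return A `periodic_input` object.
#' @examples
#' input_stream(periodic_input(3), 0:8)
#' @export
periodic_input <- function(period, phase = 0L) {
  period <- as.integer(period)
  phase <- as.integer(phase)
  if (is.na(period) || period < 1L)
    stop("invalid-parameter: period must be a positive integer")
  if (is.na(phase) || phase < 0L || phase >= period)
    stop("invalid-parameter: phase must lie in [0, period)")
  structure(list(period = period, phase = phase), class = "periodic_input")
}

#' @rdname periodic_input
#' @param input A `periodic_input`.
#' @param t Non-negative integer step index (vectorised).
#' @return `input_stream` returns the emitted bit(s) at step(s) `t`.
#' @export
input_stream <- function(input, t) {
  stopifnot(inherits(input, "periodic_input"), all(t >= 0))
  as.integer((t - input$phase) %% input$period == 0L)
}

#' @export
print.periodic_input <- function(x, ...) {
  cat("<periodic_input> period ", x$period, ", phase ", x$phase, "\n", sep = "")
  invisible(x)
}

#' Autonomous spike-train generator ring
#'
#' Builds a Boolean network whose output node `C1` settles, from any initial
#' state, into tonic spiking of period `p` (one 1 followed by `p - 1` zeros).
#' For `p >= 2` the network is the inductive ring construction: a constant
#' drive `E` excites `S1`, which is inhibited by every chain node `S1..S(p-1)`;
#' each `S(i+1)` is excited by `S(i)`; the output `C1` follows `S1`. For
#' `p = 1` the output is wired directly to `E` and spikes every step.
#'
#' @param p Positive integer output period.
#' @return A [network_spec()] with output node `"C1"`.
#' @examples
#' ring <- build_generator_ring(3)
#' find_cycle(ring)$cycle_length
#' @export
build_generator_ring <- function(p) {
  p <- as.integer(p)
  if (is.na(p) || p < 1L)
    stop("invalid-parameter: p must be a positive integer")
  nodes <- list(node_spec("E", "constant_one"))
  if (p == 1L) {
    nodes <- c(nodes, list(node_spec("C1", activators = "E")))
  } else {
    chain <- paste0("S", seq_len(p - 1L))
    nodes <- c(nodes, list(
      node_spec("S1", activators = "E", inhibitors = chain)))
    if (p > 2L)
      nodes <- c(nodes, lapply(2:(p - 1L), function(i)
        node_spec(paste0("S", i), activators = paste0("S", i - 1L))))
    nodes <- c(nodes, list(node_spec("C1", activators = "S1")))
  }
  network_spec(nodes, outputs = "C1")
}
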