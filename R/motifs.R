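#' Parameters of the excitatory memory-chain motif (Net A)
#'
#' Net A is a chain of `k` memory nodes `S1..Sk` fed by the control input
#' `C1`, all exciting the output `X1`, which fires when at least `N` chain
#' nodes are simultaneously active. The memory is preserved after the output
#' fires.
#'
#' @param k Memory length (number of chain nodes), `k >= 1`.
#' @param N Activation threshold of the output, `N >= 1`.
#' @return A `net_a_params` object.
#' @export
net_a_params <- function(k, N) {
  k <- as.integer(k); N <- as.integer(N)
  if (is.na(k) || k < 1L) stop("invalid-parameter: k must be >= 1")
  if (is.na(N) || N < 1L) stop("invalid-parameter: N must be >= 1")
  structure(list(k = k, N = N), class = "net_a_params")
}

#' Parameters of the memory-loss / self-excitation motif (Net B)
#'
#' Net B extends the memory chain with partial memory erasure and
#' self-excitation: the output `X1` inhibits the chain nodes beyond position
#' `m` (an output spike erases all but the first `m` memory slots) and feeds
#' itself back through the node `I1`, which relays `X1` with one step of lag
#' and counts as one activator.
#'
#' @param k Memory length, `k > m`.
#' @param m Retained memory length, `1 <= m < k`.
#' @param N Activation threshold (the closed-form steady-state oracle covers
#'   `N = 2` only).
#' @return A `net_b_params` object.
#' @export
net_b_params <- function(k, m, N = 2L) {
  k <- as.integer(k); m <- as.integer(m); N <- as.integer(N)
  if (is.na(k) || k < 2L) stop("invalid-parameter: k must be >= 2")
  if (is.na(m) || m < 1L || m >= k)
    stop("invalid-parameter: m must satisfy 1 <= m < k")
  if (is.na(N) || N < 1L) stop("invalid-parameter: N must be >= 1")
  structure(list(k = k, m = m, N = N), class = "net_b_params")
}

# Node ids get an optional suffix so motifs can be composed with disjoint
# namespaces (used by build_cpg).
motif_ids <- function(suffix = "") {
  list(C = paste0("C1", suffix), S = function(i) paste0("S", i, suffix),
       I = paste0("I1", suffix), X = paste0("X1", suffix))
}

#' Build the Net A motif
#'
#' Nodes `C1` (external input), chain `S1..Sk` (each excited by its
#' predecessor, `S1` by `C1`), and output `X1` excited by the whole chain
#' with threshold `N`. No inhibitory edges.
#'
#' @param params A [net_a_params()].
#' @param suffix Optional id suffix for namespacing when composing motifs.
#' @return A [network_spec()] with input `C1` and output `X1`.
#' @examples
#' build_net_a(net_a_params(k = 4, N = 2))
#' @export
build_net_a <- function(params, suffix = "") {
  stopifnot(inherits(params, "net_a_params"))
  id <- motif_ids(suffix)
  chain <- id$S(seq_len(params$k))
  nodes <- c(
    list(node_spec(id$C, "external_input"),
         node_spec(chain[1L], activators = id$C)),
    lapply(seq_len(params$k - 1L), function(i)
      node_spec(chain[i + 1L], activators = chain[i])),
    list(node_spec(id$X, activators = chain, threshold = params$N)))
  network_spec(nodes, outputs = id$X)
}

#' Build the Net B motif
#'
#' As [build_net_a()] plus memory loss and self-excitation: chain nodes
#' `S(m+1)..Sk` are inhibited by the output `X1`; `I1` is excited by `X1`
#' (one-step lag) and counts as an ordinary activator of `X1`, whose
#' threshold `N` is taken over the chain plus `I1`.
#'
#' @param params A [net_b_params()].
#' @param suffix Optional id suffix for namespacing when composing motifs.
#' @return A [network_spec()] with input `C1` and output `X1`.
#' @export
build_net_b <- function(params, suffix = "") {
  stopifnot(inherits(params, "net_b_params"))
  id <- motif_ids(suffix)
  chain <- id$S(seq_len(params$k))
  nodes <- c(
    list(node_spec(id$C, "external_input"),
         node_spec(chain[1L], activators = id$C)),
    lapply(seq_len(params$k - 1L), function(i)
      node_spec(chain[i + 1L], activators = chain[i],
                inhibitors = if (i + 1L > params$m) id$X else character())),
    list(node_spec(id$I, activators = id$X),
         node_spec(id$X, activators = c(chain, id$I),
                   threshold = params$N)))
  network_spec(nodes, outputs = id$X)
}

#' The feasible initial condition of Net B
#'
#' The distinguished initial state under which the Net B steady states are
#' characterised: two chain spikes `p` apart (`S1 = 1`, `S(p+1) = 1`, all
#' other chain nodes 0), output and self-excitation off, with the input
#' stream phased so its next spike arrives `p` steps after the one sitting
#' at `S1` (phase `p - 1`).
#'
#' @param params A [net_b_params()].
#' @param p Input period; requires `p + 1 <= k` so the second spike has a
#'   chain slot.
#' @param suffix Optional id suffix matching [build_net_b()].
#' @return List with `state` (named bit vector) and `inputs` (named list
#'   holding the phased [periodic_input()] for `C1`).
#' @examples
#' feasible_state(net_b_params(k = 6, m = 3), p = 3)$state
#' @export
feasible_state <- function(params, p, suffix = "") {
  stopifnot(inherits(params, "net_b_params"))
  p <- as.integer(p)
  if (is.na(p) || p < 1L) stop("invalid-parameter: p must be >= 1")
  if (p + 1L > params$k)
    stop("invalid-parameter: feasible state needs p + 1 <= k (second chain ",
         "spike has no slot for p = ", p, ", k = ", params$k, ")")
  id <- motif_ids(suffix)
  spec <- build_net_b(params, suffix)
  inputs <- stats::setNames(list(periodic_input(p, phase = p - 1L)), id$C)
  st <- init_state(spec, active = c(id$S(1L), id$S(p + 1L)), inputs = inputs)
  list(state = st, inputs = inputs)
}

new_steady_prediction <- function(regime, pattern) {
  pattern <- as.integer(pattern)
  structure(list(regime = regime, pattern = pattern,
                 on_length = sum(pattern), cycle_length = length(pattern)),
            class = "steady_prediction")
}

#' @export
print.steady_prediction <- function(x, ...) {
  cat("<steady_prediction> ", x$regime, ": cycle length ", x$cycle_length,
      ", ", x$on_length, " spike step(s) per cycle\n", sep = "")
  invisible(x)
}

#' Closed-form steady state of Net A under a periodic drive
#'
#' For a drive of period `p`: tonic (`X1` constantly 1) when `p <= k/N`;
#' bursting with `s = k - (N-1) p` ones followed by `p - s` zeros (cycle
#' length `p`) when `k/N < p < k/(N-1)`; silent when `p >= k/(N-1)`. At
#' `N = 1` the silent bound is infinite: a threshold-one network cannot be
#' silenced and bursts with `k` ones per period for every `p > k`. The
#' regime label comes from [classify_pattern()], so the degenerate burst at
#' the upper boundary (`s = 1`, a uniform period-`p` spike train) is
#' reported as tonic.
#'
#' @param params A [net_a_params()].
#' @param p Drive period, `p >= 1`.
#' @return A `steady_prediction` (regime, cyclic pattern, on-length,
#'   cycle length).
#' @examples
#' predict_net_a(net_a_params(k = 4, N = 2), p = 3)
#' @export
predict_net_a <- function(params, p) {
  stopifnot(inherits(params, "net_a_params"))
  p <- as.integer(p)
  if (is.na(p) || p < 1L) stop("invalid-parameter: p must be >= 1")
  k <- params$k; N <- params$N
  if (N * p <= k) return(new_steady_prediction("tonic", 1L))
  if (N > 1L && (N - 1L) * p >= k)
    return(new_steady_prediction("silent", 0L))
  s <- k - (N - 1L) * p
  pred <- new_steady_prediction("bursting", rep(c(1L, 0L), c(s, p - s)))
  # at the upper boundary (s = 1) the burst degenerates to a uniform
  # period-p spike train; let the classifier name the regime
  cls <- classify_pattern(pred$pattern)
  pred$regime <- if (cls$label == "mixed_mode") "mixed" else cls$label
  pred
}

#' Closed-form steady state of Net B from the feasible state
#'
#' For `N = 2`, `m >= 3` and a drive of period `p`, starting from the
#' feasible state:
#' \itemize{
#'   \item `p <= m`: tonic (`X1` constantly 1);
#'   \item `p = m + 1`, `p` even: the alternating pattern `10` (cycle 2);
#'   \item `p = m + 1`, `p` odd: `m` ones, an alternating `01` block, then a
#'     zero run, over a cycle of `3m + 3`;
#'   \item `m + 2 <= p < k - 1`: `m` ones then `2p - m` zeros (cycle `2p`);
#'   \item `p = k - 1` (and `>= m + 2`): cycle `2p` opening with `1,0`
#'     alternation (spikes at odd steps up to `m`), zeros thereafter;
#'   \item `p >= k`: silent.
#' }
#' The regime label is assigned by [classify_pattern()] on the predicted
#' pattern.
#'
#' @param params A [net_b_params()] with `N = 2` and `m >= 3`; other
#'   parameters raise an unsupported-regime error (fall back to simulation).
#' @param p Drive period, `p >= 1`.
#' @return A `steady_prediction`.
#' @examples
#' predict_net_b(net_b_params(k = 400, m = 100), p = 110)
#' @export
predict_net_b <- function(params, p) {
  stopifnot(inherits(params, "net_b_params"))
  p <- as.integer(p)
  if (is.na(p) || p < 1L) stop("invalid-parameter: p must be >= 1")
  if (params$N != 2L)
    stop("unsupported-regime: closed-form prediction requires N = 2")
  if (params$m < 3L)
    stop("unsupported-regime: closed-form prediction requires m >= 3")
  k <- params$k; m <- params$m
  pat <-
    if (p <= m) 1L
    else if (p == m + 1L && p %% 2L == 0L) c(1L, 0L)
    else if (p == m + 1L) {
      # p odd (m even): from the feasible state, spikes at steps 1..m, then
      # alternation 0,1,...,0,1 over steps p..2p-2, then zeros to step 3p.
      c(rep(1L, m), rep(c(0L, 1L), m %/% 2L), rep(0L, m + 3L))
    }
    else if (p < k - 1L) rep(c(1L, 0L), c(m, 2L * p - m))
    else if (p == k - 1L) {
      # spikes at odd steps t <= m within a cycle of 2p starting at step 1
      t <- seq_len(2L * p)
      as.integer(t %% 2L == 1L & t <= m)
    }
    else 0L
  pred <- new_steady_prediction("pending", pat)
  cls <- classify_pattern(pred$pattern)
  pred$regime <- if (cls$label == "mixed_mode") "mixed" else cls$label
  pred
}

#' Steady-state output pattern of a motif by direct simulation
#'
#' Runs exact cycle detection and returns the output node's cyclic pattern
#' reduced to its minimal period. For Net A the canonical start is the empty
#' chain; for Net B supply the feasible state via `init`/`inputs` (or any
#' other initial condition).
#'
#' @param spec Motif network from [build_net_a()] or [build_net_b()].
#' @param p Drive period for `C1` (ignored when `inputs` is given).
#' @param init,inputs Optional initial state and input streams (defaults:
#'   all-zero chain, phase-0 drive).
#' @param node Output node id (default: the spec's first output).
#' @param cap Passed to [find_cycle()].
#' @return Integer bit vector: the minimal repeating output pattern.
#' @export
steady_output <- function(spec, p = NULL, init = NULL, inputs = NULL,
                          node = NULL, cap = NULL) {
  if (is.null(inputs)) {
    stopifnot(!is.null(p))
    inputs <- stats::setNames(list(periodic_input(p)), spec$inputs[1L])
  }
  if (is.null(node)) node <- spec$outputs[1L]
  cyc <- find_cycle(spec, inputs = inputs, init = init, cap = cap)
  bits <- node_series(cyc, node)
  bits[seq_len(minimal_period(bits))]
}
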