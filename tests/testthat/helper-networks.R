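# Shared fixtures and small utilities for the suite. Everything is built in
# code; no data files.

bits <- function(s) as.integer(strsplit(s, "")[[1L]])

# Enumerate every 0/1 assignment of the given nodes (columns) as a matrix.
all_assignments <- function(ids) {
  m <- as.matrix(expand.grid(rep(list(0:1), length(ids)), KEEP.OUT.ATTRS = FALSE))
  colnames(m) <- ids
  m
}

# Steady X1 pattern of Net B simulated from the appropriate start: the
# feasible state when it exists (p + 1 <= k), otherwise the all-zero chain
# (for p >= k at most one chain spike can ever be present, so the steady
# state matches the feasible-start one).
net_b_steady <- function(params, p, spec = NULL) {
  if (is.null(spec)) spec <- build_net_b(params)
  if (p + 1L <= params$k) {
    fs <- feasible_state(params, p)
    steady_output(spec, init = fs$state, inputs = fs$inputs)
  } else {
    steady_output(spec, p = p)
  }
}

# Random small threshold-logic network for property tests: `n` dynamic nodes
# plus one constant drive, random disjoint activator/inhibitor sets.
random_network <- function(n = 6L) {
  ids <- c("E", paste0("V", seq_len(n)))
  nodes <- list(node_spec("E", "constant_one"))
  for (i in seq_len(n)) {
    k_in <- sample(0:min(3L, n), 1L)
    act <- sample(ids, k_in)
    inh <- sample(setdiff(ids[-1L], act), sample(0:2L, 1L))
    nodes[[i + 1L]] <- node_spec(paste0("V", i), activators = act,
                                 inhibitors = inh,
                                 threshold = sample(1:2, 1L))
  }
  network_spec(nodes)
}

random_state <- function(spec, p_on = 0.5) {
  st <- init_state(spec)
  dyn <- names(which(vapply(spec$nodes, `[[`, "", "kind") == "dynamic"))
  st[dyn] <- as.integer(stats::runif(length(dyn)) < p_on)
  st
}

# Iterate the pure-R reference stepper, driving inputs from their streams.
simulate_reference <- function(spec, inputs, init, steps) {
  st <- init
  out <- matrix(0L, steps + 1L, length(spec$ids),
                dimnames = list(NULL, spec$ids))
  out[1L, ] <- st[spec$ids]
  for (t in seq_len(steps)) {
    ib <- vapply(spec$inputs, function(id) input_stream(inputs[[id]], t), 1L)
    st <- next_state(spec, st, stats::setNames(ib, spec$inputs))
    out[t + 1L, ] <- st[spec$ids]
  }
  out
}
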