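#' Parameters of the composed respiratory central pattern generator
#'
#' One memory-preserving motif (Net A, the post-I population `X4`) composed
#' with two memory-loss/self-excitation motifs (Net B: the inspiratory
#' population `X1` / pre-I and the late-expiratory population `X3` / aug-E),
#' each driven by its own tonic control input (`C1`, `C3`, `C4`: NTS, RTN,
#' Pons). Defaults are the reference parameter set of the composed network:
#' `x1 = x3 = (k = 400, N = 2, m = 100)`, `x4 = (k = 800, N = 3)`, control
#' periods `(p1, p3, p4) = (5, 110, 32)`.
#'
#' @param x1,x3 [net_b_params()] for the `X1` and `X3` sub-networks.
#' @param x4 [net_a_params()] for the `X4` sub-network.
#' @param p1,p3,p4 Control-signal periods (positive integers).
#' @param phases Integer phase offsets for `C1`, `C3`, `C4` (length 3).
#' @return A `cpg_params` object.
#' @export
cpg_params <- function(x1 = net_b_params(400, 100, 2),
                       x3 = net_b_params(400, 100, 2),
                       x4 = net_a_params(800, 3),
                       p1 = 5L, p3 = 110L, p4 = 32L,
                       phases = c(0L, 0L, 0L)) {
  stopifnot(inherits(x1, "net_b_params"), inherits(x3, "net_b_params"),
            inherits(x4, "net_a_params"), length(phases) == 3L)
  p1 <- as.integer(p1); p3 <- as.integer(p3); p4 <- as.integer(p4)
  if (any(is.na(c(p1, p3, p4))) || any(c(p1, p3, p4) < 1L))
    stop("invalid-parameter: control periods must be positive integers")
  phases <- as.integer(phases)
  if (any(phases < 0L) || any(phases >= c(p1, p3, p4)))
    stop("invalid-parameter: phases must lie in [0, period)")
  structure(list(x1 = x1, x3 = x3, x4 = x4, p1 = p1, p3 = p3, p4 = p4,
                 phases = phases), class = "cpg_params")
}

cpg_inputs <- function(params) {
  list(C1 = periodic_input(params$p1, params$phases[1L]),
       C3 = periodic_input(params$p3, params$phases[2L]),
       C4 = periodic_input(params$p4, params$phases[3L]))
}

#' Build the composed three-population network
#'
#' Wires the three motif sub-networks with disjoint node namespaces
#' (`Sj_1`, `Sj_3`, `Sj_4`, `I1_1`, `I1_3`) and the cross-population
#' inhibition: `X3` inhibits `X1`, `X4` and every memory-chain node of
#' sub-networks 1 and 4; `X4` inhibits `X1` and every chain node of
#' sub-network 1. Sub-network 3 receives no edges from the others (`X3` is
#' autonomous given `C3`), and the self-excitation nodes `I1_*` are not
#' inhibited directly (they trail their output by one step). Inhibiting the
#' whole chain, not just the output, is what resets the released
#' population's memory and produces the post-release activation delays of
#' the three-phase mechanism.
#'
#' @param params A [cpg_params()].
#' @return A [network_spec()] with inputs `C1`, `C3`, `C4` and outputs
#'   `X1`, `X3`, `X4`.
#' @export
build_cpg <- function(params) {
  stopifnot(inherits(params, "cpg_params"))
  chain_b <- function(idx, kb, m, X, C, extra_inh) {
    S <- paste0("S", seq_len(kb), "_", idx)
    c(list(node_spec(C, "external_input"),
           node_spec(S[1L], activators = C, inhibitors = extra_inh)),
      lapply(2:kb, function(j)
        node_spec(S[j], activators = S[j - 1L],
                  inhibitors = c(if (j > m) X, extra_inh))),
      list(node_spec(paste0("I1_", idx), activators = X)))
  }
  k1 <- params$x1$k; k4 <- params$x4$k
  S1 <- paste0("S", seq_len(k1), "_1")
  S4 <- paste0("S", seq_len(k4), "_4")
  S3 <- paste0("S", seq_len(params$x3$k), "_3")
  nodes <- c(
    chain_b(1L, k1, params$x1$m, "X1", "C1", c("X3", "X4")),
    list(node_spec("X1", activators = c(S1, "I1_1"),
                   inhibitors = c("X3", "X4"),
                   threshold = params$x1$N)),
    chain_b(3L, params$x3$k, params$x3$m, "X3", "C3", character()),
    list(node_spec("X3", activators = c(S3, "I1_3"),
                   threshold = params$x3$N)),
    list(node_spec("C4", "external_input"),
         node_spec(S4[1L], activators = "C4", inhibitors = "X3")),
    lapply(2:k4, function(j)
      node_spec(S4[j], activators = S4[j - 1L], inhibitors = "X3")),
    list(node_spec("X4", activators = S4, inhibitors = "X3",
                   threshold = params$x4$N)))
  network_spec(nodes, outputs = c("X1", "X3", "X4"))
}

# Window-level regime of one output node: silent (no spikes), tonic
# (uninterrupted activity or a uniform spike train), or bursting (recurrent
# active phases separated by quiescent runs). Active phases of the composed
# network are solid runs of 1s, so no gap tolerance is needed here.
node_regime <- function(x) {
  x <- as.integer(x)
  if (!any(x == 1L)) return("silent")
  r <- rle(x)
  if (all(r$values == 1L)) return("tonic")
  if (all(r$lengths[r$values == 1L] == 1L)) {
    # uniform spike train? compare internal gaps (boundary runs may be cut)
    inner <- r$lengths[r$values == 0L]
    if (r$values[1L] == 0L) inner <- inner[-1L]
    if (r$values[length(r$values)] == 0L) inner <- inner[-length(inner)]
    if (length(inner) && length(unique(inner)) == 1L) return("tonic")
  }
  "bursting"
}

# Gap tolerance for merging flickers when delimiting active phases in the
# timing analysis. Active phases are solid in practice; a tolerance of a few
# steps (capped by the control period) absorbs onset flicker without ever
# reaching the length of a genuine quiescent phase.
cpg_gaps <- function(params)
  c(X1 = min(params$p1 + 1L, 6L), X3 = min(params$p3 + 1L, 6L),
    X4 = min(params$p4 + 1L, 6L))

#' Classify the steady regime of the composed network
#'
#' Decision table over the per-population regimes in a steady observation
#' window: all three burst in the cyclic order `X1 -> X4 -> X3` =
#' `three_phase`; `X1` and `X3` burst with `X4` silent = `two_phase_E2`;
#' `X1` and `X4` burst with `X3` silent = `two_phase_E1`; only `X1` bursts =
#' `one_phase`; `X1` tonic = `tonic`; `X1` silent = `silence`.
#'
#' @param x1,x3,x4 Steady-window 0/1 series of the three outputs (equal
#'   length).
#' @return Character label.
#' @export
classify_phase_pattern <- function(x1, x3, x4) {
  if (length(x1) != length(x3) || length(x1) != length(x4))
    stop("inconsistent-input: series lengths differ")
  r1 <- node_regime(x1)
  if (r1 == "silent") return("silence")
  if (r1 == "tonic") return("tonic")
  r3 <- node_regime(x3)
  r4 <- node_regime(x4)
  if (r3 == "bursting" && r4 == "bursting") "three_phase"
  else if (r3 == "bursting") "two_phase_E2"
  else if (r4 == "bursting") "two_phase_E1"
  else "one_phase"
}

#' Run the composed network to a steady observation window
#'
#' Simulates the CPG from the default deterministic initial condition (all
#' chains, outputs and self-excitation nodes zero; control phases as given)
#' for `burn_in + window` steps and keeps the final `window` steps of the
#' three outputs and three controls. The burn-in absorbs the transient; the
#' window is sized to contain many breaths.
#'
#' @param params A [cpg_params()].
#' @param burn_in Steps discarded as transient.
#' @param window Steps kept for analysis.
#' @param spec Optional prebuilt [build_cpg()] network (it does not depend
#'   on the control periods, so sweeps and ensembles reuse one build).
#' @return A `cpg_run`: `series` (window x 6 matrix: `C1,C3,C4,X1,X3,X4`),
#'   `label`, `params`, `burn_in`, `window`.
#' @examples
#' \donttest{
#' run <- run_cpg(cpg_params())
#' run$label
#' }
#' @export
run_cpg <- function(params, burn_in = 3000L, window = 4400L, spec = NULL) {
  stopifnot(inherits(params, "cpg_params"))
  if (is.null(spec)) spec <- build_cpg(params)
  rec <- c("C1", "C3", "C4", "X1", "X3", "X4")
  tr <- simulate_network(spec, inputs = cpg_inputs(params),
                         steps = burn_in + window, record = rec)
  win <- tr$series[(burn_in + 2L):(burn_in + window + 1L), , drop = FALSE]
  lab <- classify_phase_pattern(win[, "X1"], win[, "X3"], win[, "X4"])
  structure(list(series = win, label = lab, params = params,
                 burn_in = as.integer(burn_in), window = as.integer(window)),
            class = "cpg_run")
}

#' @export
print.cpg_run <- function(x, ...) {
  cat("<cpg_run> label ", x$label, " (window ", x$window, " steps after ",
      x$burn_in, " burn-in)\n", sep = "")
  invisible(x)
}

timing_stats <- function(v) {
  if (!length(v)) return(c(min = NA_real_, max = NA_real_, mean = NA_real_,
                           sd = NA_real_))
  c(min = min(v), max = max(v), mean = mean(v),
    sd = if (length(v) > 1L) stats::sd(v) else 0)
}

#' Per-breath inspiration/expiration timing of a CPG run
#'
#' Breaths are delimited by successive onsets of `X1` activity (merged
#' bursts at the control-period gap tolerance). Within each breath the
#' phase boundaries are the onsets of the successor populations, so the
#' durations tile the breath exactly: in a 3-phase breath
#' `T_I = onset(X4) - onset(X1)`, `T_E1 = onset(X3) - onset(X4)`,
#' `T_E2 = next onset(X1) - onset(X3)` and `T = T_I + T_E1 + T_E2`; in a
#' 2-phase breath the single expiratory onset splits the breath; in a
#' 1-phase breath `T_I` is the merged `X1` burst span itself. `T_E` always
#' denotes `T - T_I`. Breaths missing an expected successor onset (window
#' edges) are dropped.
#'
#' @param run A [run_cpg()] result with a bursting label (`three_phase`,
#'   `two_phase_E2`, `two_phase_E1` or `one_phase`); tonic or silence yields
#'   an empty no-timing result.
#' @return A `phase_timing`: `breaths` (data.frame with per-breath `T_I`,
#'   `T_E`, `T_E1`, `T_E2`, `T`) and `stats` (min/max/mean/SD per quantity).
#' @export
phase_timing <- function(run) {
  stopifnot(inherits(run, "cpg_run"))
  empty <- structure(list(
    breaths = data.frame(T_I = numeric(), T_E = numeric(), T_E1 = numeric(),
                         T_E2 = numeric(), T = numeric()),
    stats = NULL, label = run$label), class = "phase_timing")
  if (!run$label %in% c("three_phase", "two_phase_E2", "two_phase_E1",
                        "one_phase")) {
    empty$stats <- lapply(empty$breaths, timing_stats)
    return(empty)
  }
  g <- cpg_gaps(run$params)
  b1 <- merged_bursts(run$series[, "X1"], g[["X1"]])
  if (nrow(b1) && run$series[1L, "X1"] == 1L) b1 <- b1[-1L, ]  # partial
  if (nrow(b1) < 2L) { empty$stats <- lapply(empty$breaths, timing_stats)
                       return(empty) }
  o4 <- merged_bursts(run$series[, "X4"], g[["X4"]])$onset
  o3 <- merged_bursts(run$series[, "X3"], g[["X3"]])$onset
  rows <- lapply(seq_len(nrow(b1) - 1L), function(j) {
    t0 <- b1$onset[j]; t1 <- b1$onset[j + 1L]
    TT <- t1 - t0
    t4 <- o4[o4 > t0 & o4 <= t1][1L]
    t3 <- o3[o3 > t0 & o3 <= t1][1L]
    out <- c(T_I = NA_real_, T_E = NA_real_, T_E1 = NA_real_,
             T_E2 = NA_real_, T = TT, ord = NA)
    if (run$label == "three_phase") {
      if (is.na(t4) || is.na(t3)) return(NULL)
      out["T_I"] <- t4 - t0; out["T_E1"] <- t3 - t4; out["T_E2"] <- t1 - t3
      out["ord"] <- as.numeric(t0 < t4 && t4 < t3)
    } else if (run$label == "two_phase_E2") {
      if (is.na(t3)) return(NULL)
      out["T_I"] <- t3 - t0; out["T_E2"] <- t1 - t3
    } else if (run$label == "two_phase_E1") {
      if (is.na(t4)) return(NULL)
      out["T_I"] <- t4 - t0; out["T_E1"] <- t1 - t4
    } else {
      out["T_I"] <- b1$span[j]
    }
    out["T_E"] <- TT - out[["T_I"]]
    out
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) { empty$stats <- lapply(empty$breaths, timing_stats)
                       return(empty) }
  breaths <- as.data.frame(do.call(rbind, rows))
  structure(list(
    breaths = breaths[c("T_I", "T_E", "T_E1", "T_E2", "T")],
    order_ok = if (run$label == "three_phase") all(breaths$ord == 1) else NA,
    stats = lapply(breaths[c("T_I", "T_E", "T_E1", "T_E2", "T")],
                   timing_stats),
    label = run$label), class = "phase_timing")
}

#' @export
print.phase_timing <- function(x, ...) {
  cat("<phase_timing> ", x$label, ", ", nrow(x$breaths), " breath(s)\n",
      sep = "")
  if (nrow(x$breaths)) {
    s <- vapply(x$stats, function(q) q[["mean"]], 0)
    cat("  mean T_I ", round(s[["T_I"]], 1), ", T_E ", round(s[["T_E"]], 1),
        ", T ", round(s[["T"]], 1), "\n", sep = "")
  }
  invisible(x)
}

#' Sweep one control period and tabulate timing
#'
#' Re-runs the composed network for each value of the chosen control period
#' (all other parameters fixed, one shared network build) and tabulates the
#' regime label plus mean and SD of the per-breath timing quantities.
#'
#' @param params Base [cpg_params()].
#' @param which One of `"p1"`, `"p3"`, `"p4"`.
#' @param values Integer vector of periods to sweep.
#' @param burn_in,window Passed to [run_cpg()].
#' @return A data.frame with one row per period value.
#' @export
sweep_control <- function(params, which = c("p1", "p3", "p4"), values,
                          burn_in = 3000L, window = 4400L) {
  which <- match.arg(which)
  stopifnot(inherits(params, "cpg_params"), length(values) >= 1L)
  spec <- build_cpg(params)
  rows <- lapply(as.integer(values), function(v) {
    pp <- params; pp[[which]] <- v
    pp$phases <- pmin(pp$phases, c(pp$p1, pp$p3, pp$p4) - 1L)
    run <- run_cpg(pp, burn_in = burn_in, window = window, spec = spec)
    tm <- phase_timing(run)
    st <- tm$stats
    data.frame(period = v, label = run$label, n_breaths = nrow(tm$breaths),
               mean_T_I = st$T_I[["mean"]], sd_T_I = st$T_I[["sd"]],
               mean_T_E = st$T_E[["mean"]], sd_T_E = st$T_E[["sd"]],
               mean_T_E1 = st$T_E1[["mean"]], mean_T_E2 = st$T_E2[["mean"]],
               mean_T = st$T[["mean"]], sd_T = st$T[["sd"]])
  })
  do.call(rbind, rows)
}

#' Timing variability over an ensemble of control phases
#'
#' Runs the composed network from `n_runs` random combinations of control
#' phases (uniform over each period, seeded) and pools the per-breath timing
#' quantities; the spread across the pool quantifies the rhythm variability
#' induced by spike-arrival order.
#'
#' @param params A [cpg_params()]; its `phases` entry is ignored.
#' @param n_runs Number of phase combinations (`>= 2`).
#' @param seed Integer seed fixing the sampled phases.
#' @param burn_in,window Passed to [run_cpg()].
#' @return List with `stats` (min/max/mean/sd per quantity over the pooled
#'   breaths), `n_breaths`, and the sampled `phases` matrix.
#' @export
ensemble_variability <- function(params, n_runs = 50L, seed = 1L,
                                 burn_in = 3000L, window = 4400L) {
  stopifnot(inherits(params, "cpg_params"), n_runs >= 2L)
  set.seed(seed)
  spec <- build_cpg(params)
  phases <- cbind(sample.int(params$p1, n_runs, replace = TRUE) - 1L,
                  sample.int(params$p3, n_runs, replace = TRUE) - 1L,
                  sample.int(params$p4, n_runs, replace = TRUE) - 1L)
  pool <- list()
  for (r in seq_len(n_runs)) {
    pp <- params; pp$phases <- phases[r, ]
    run <- run_cpg(pp, burn_in = burn_in, window = window, spec = spec)
    tm <- phase_timing(run)
    pool[[r]] <- tm$breaths
  }
  breaths <- do.call(rbind, pool)
  list(stats = lapply(breaths[c("T_I", "T_E", "T_E1", "T_E2", "T")],
                      timing_stats),
       n_breaths = nrow(breaths), phases = phases)
}
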