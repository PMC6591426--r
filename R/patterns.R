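#' Minimal period of an exact cyclic pattern
#'
#' Smallest divisor `d` of `length(bits)` such that the pattern is `d`
#' periodic. Intended for patterns returned by exact cycle detection, where
#' the minimal period necessarily divides the cycle length.
#'
#' @param bits Integer 0/1 vector (one cycle).
#' @return Integer minimal period.
#' @export
minimal_period <- function(bits) {
  L <- length(bits)
  stopifnot(L >= 1L)
  for (d in seq_len(L)) {
    if (L %% d != 0L) next
    if (all(bits == rep_len(bits[seq_len(d)], L))) return(d)
  }
  L
}

#' Minimal repeat length of a steady windowed series
#'
#' Smallest `L <= length(x) / 2` with `x[i] == x[i + L]` for every valid `i`
#' (the window is assumed fully post-transient). Returns `NA` if no repeat
#' fits in the window.
#'
#' @param x Integer 0/1 vector.
#' @return Integer period or `NA`.
#' @export
series_period <- function(x) {
  n <- length(x)
  for (L in seq_len(n %/% 2L)) {
    if (all(x[seq_len(n - L)] == x[seq_len(n - L) + L])) return(L)
  }
  NA_integer_
}

#' Are two cyclic bit patterns equal up to rotation?
#'
#' Both patterns are reduced to their minimal period first, so repeated
#' writings of the same cycle compare equal.
#'
#' @param a,b Integer 0/1 vectors (one or more repeats of a cycle each).
#' @return Logical.
#' @export
cyclic_equal <- function(a, b) {
  a <- a[seq_len(minimal_period(a))]
  b <- b[seq_len(minimal_period(b))]
  if (length(a) != length(b)) return(FALSE)
  L <- length(a)
  if (L == 1L) return(a == b)
  d <- c(b, b)
  any(vapply(seq_len(L), function(r)
    all(a == d[r:(r + L - 1L)]), TRUE))
}

#' Canonical rotation of a cyclic spike pattern
#'
#' Rotates a cyclic bit pattern so that it ends with its longest zero run
#' (wrap-aware; ties broken by the earliest rotation), which makes the
#' decomposition into an active segment followed by a quiescent run unique.
#' The active segment (`active_length` leading steps) then starts and ends
#' with 1; `tail_zeros` is the trailing quiescent run and
#' `max_zero_run_active` the longest zero run inside the active segment.
#'
#' @param bits Integer 0/1 vector, one cycle of the pattern.
#' @return A `cyclic_pattern`: `bits` (canonical rotation), `rotation`
#'   (0-based index of the original position now first), `active_length`,
#'   `tail_zeros`, `max_zero_run_active`.
#' @examples
#' cyclic_pattern(c(0, 0, 1, 1, 1, 0))
#' @export
cyclic_pattern <- function(bits) {
  bits <- as.integer(bits)
  L <- length(bits)
  stopifnot(L >= 1L, all(bits %in% c(0L, 1L)))
  ones <- which(bits == 1L)
  if (!length(ones)) {
    return(structure(list(bits = bits, rotation = 0L, active_length = 0L,
                          tail_zeros = L, max_zero_run_active = 0L),
                     class = "cyclic_pattern"))
  }
  # cyclic zero gap preceding each 1 that follows a gap
  prev <- c(ones[length(ones)] - L, ones[-length(ones)])
  gaps <- ones - prev - 1L
  n <- max(gaps)
  start <- ones[which.max(gaps)]  # earliest 1 preceded by a maximal gap
  rot <- if (start == 1L) bits else bits[c(start:L, seq_len(start - 1L))]
  m_d <- L - n
  active <- rot[seq_len(m_d)]
  runs <- rle(active)
  mz <- if (any(runs$values == 0L)) max(runs$lengths[runs$values == 0L]) else 0L
  structure(list(bits = rot, rotation = start - 1L, active_length = m_d,
                 tail_zeros = n, max_zero_run_active = mz),
            class = "cyclic_pattern")
}

#' @export
print.cyclic_pattern <- function(x, ...) {
  cat("<cyclic_pattern> ", paste0(x$bits, collapse = ""),
      " (active ", x$active_length, ", tail zeros ", x$tail_zeros, ")\n",
      sep = "")
  invisible(x)
}

#' Classify a cyclic spike pattern
#'
#' Labels one node's repeating pattern as `silent` (no spikes), `tonic`
#' (a uniform spike train: exactly one 1 per minimal period, which includes
#' the all-ones period-1 train), `bursting` (the trailing quiescent run is
#' strictly longer than any zero run inside the active segment), or
#' `mixed_mode` (otherwise). The decision is invariant under rotation of the
#' cycle.
#'
#' @param x Integer 0/1 vector (one or more repeats of the cycle) or a
#'   [cyclic_pattern()].
#' @return A `pattern_class`: list with `label` and, for tonic patterns,
#'   `period`.
#' @examples
#' classify_pattern(c(1, 1, 1, 0, 0, 0))$label      # bursting
#' classify_pattern(c(1, 1, 1, 0, 1, 0, 1, 0))$label # mixed_mode
#' classify_pattern(c(1, 0, 0))                      # tonic, period 3
#' @export
classify_pattern <- function(x) {
  bits <- if (inherits(x, "cyclic_pattern")) x$bits else as.integer(x)
  stopifnot(length(bits) >= 1L, all(bits %in% c(0L, 1L)))
  if (!any(bits == 1L))
    return(structure(list(label = "silent", period = NA_integer_),
                     class = "pattern_class"))
  d <- minimal_period(bits)
  if (sum(bits[seq_len(d)]) == 1L)
    return(structure(list(label = "tonic", period = d),
                     class = "pattern_class"))
  cp <- if (inherits(x, "cyclic_pattern")) x else cyclic_pattern(bits)
  lab <- if (cp$tail_zeros > cp$max_zero_run_active) "bursting" else
    "mixed_mode"
  structure(list(label = lab, period = NA_integer_), class = "pattern_class")
}

#' @export
print.pattern_class <- function(x, ...) {
  cat("<pattern_class> ", x$label,
      if (!is.na(x$period)) paste0(" (period ", x$period, ")"), "\n", sep = "")
  invisible(x)
}

# Maximal runs of 1s in a linear series, absorbing internal zero runs
# shorter than `g`; returns onset/end/span (span counts absorbed zeros).
merged_bursts <- function(x, g = 1L) {
  r <- rle(as.integer(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values == 1L)
  if (!length(on)) return(data.frame(onset = integer(), end = integer(),
                                     span = integer()))
  bs <- starts[on[1L]]; be <- ends[on[1L]]
  onset <- integer(); end <- integer()
  for (j in on[-1L]) {
    gap <- starts[j] - be - 1L
    if (gap < g) be <- ends[j]
    else { onset <- c(onset, bs); end <- c(end, be); bs <- starts[j]; be <- ends[j] }
  }
  onset <- c(onset, bs); end <- c(end, be)
  data.frame(onset = onset, end = end, span = end - onset + 1L)
}

#' Burst timing of a steady-state cycle
#'
#' Decomposes one cycle of a spike pattern (treated cyclically) into active
#' phases and quiescent gaps: zero runs shorter than the gap tolerance `g`
#' are absorbed into a burst, each burst's span is an inspiration time
#' `T_I`, the gap to the next burst an expiration time `T_E`, and
#' `T = T_I + T_E` a breathing period. Tonic or silent input yields an empty
#' (no-bursts) result rather than an error; per cycle the inspirations and
#' expirations sum exactly to the cycle length.
#'
#' @param series Integer 0/1 vector: a steady-state cycle (possibly written
#'   out more than once).
#' @param g Gap tolerance `>= 1`; zero runs of length `< g` are merged into
#'   the surrounding burst (`g = 1` merges nothing).
#' @return A `burst_timing`: `inspiration`, `expiration`,
#'   `breathing_period` (one entry per burst), `gap_tolerance`.
#' @examples
#' burst_timing(rep(c(1, 0), c(100, 120)))
#' @export
burst_timing <- function(series, g = 1L) {
  series <- as.integer(series)
  g <- as.integer(g)
  stopifnot(g >= 1L, all(series %in% c(0L, 1L)))
  empty <- structure(list(inspiration = integer(), expiration = integer(),
                          breathing_period = integer(), gap_tolerance = g),
                     class = "burst_timing")
  cls <- classify_pattern(series)
  if (cls$label == "silent" || cls$label == "tonic") return(empty)
  L <- length(series)
  cp <- cyclic_pattern(series)
  if (cp$tail_zeros < g) return(empty)  # continuously active at tolerance g
  b <- merged_bursts(cp$bits, g)
  gaps <- c(b$onset[-1L], L + b$onset[1L]) - b$end - 1L
  structure(list(inspiration = b$span, expiration = gaps,
                 breathing_period = b$span + gaps, gap_tolerance = g),
            class = "burst_timing")
}

#' @export
print.burst_timing <- function(x, ...) {
  if (!length(x$inspiration)) {
    cat("<burst_timing> no bursts\n")
  } else {
    cat("<burst_timing> ", length(x$inspiration), " burst(s): mean T_I ",
        round(mean(x$inspiration), 2), ", mean T_E ",
        round(mean(x$expiration), 2), ", mean T ",
        round(mean(x$breathing_period), 2), "\n", sep = "")
  }
  invisible(x)
}
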