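test_that("single steps reproduce the generator truth tables", {
  g2 <- build_generator_ring(2)
  # (S1, C1) = (0, *) -> (1, 0)
  st <- init_state(g2)
  expect_equal(unname(next_state(g2, st)[c("S1", "C1")]), c(1L, 0L))
  # (S1, C1) = (1, *) -> (0, 1)
  st["S1"] <- 1L
  expect_equal(unname(next_state(g2, st)[c("S1", "C1")]), c(0L, 1L))

  g3 <- build_generator_ring(3)
  # (S1, S2, C1) = (1, 0, *) -> (0, 1, 1)
  st3 <- init_state(g3, active = "S1")
  expect_equal(unname(next_state(g3, st3)[c("S1", "S2", "C1")]),
               c(0L, 1L, 1L))
  # (0, 1, *) -> (0, 0, 0); (1, 1, *) -> (0, 1, 1); (0, 0, *) -> (1, 0, 0)
  expect_equal(unname(next_state(g3, init_state(g3, "S2"))[2:4]), c(0L, 0L, 0L))
  expect_equal(unname(next_state(g3, init_state(g3, c("S1", "S2")))[2:4]),
               c(0L, 1L, 1L))
  expect_equal(unname(next_state(g3, init_state(g3))[2:4]), c(1L, 0L, 0L))
})

test_that("inhibition dominates activation on random networks", {
  set.seed(42)
  for (rep in 1:25) {
    spec <- random_network(sample(4:8, 1L))
    st <- random_state(spec)
    nxt <- next_state(spec, st)
    nxt2 <- next_state(spec, st)
    expect_identical(nxt, nxt2)  # determinism
    for (nd in spec$nodes) {
      if (nd$kind != "dynamic") next
      if (length(nd$inhibitors) && any(st[nd$inhibitors] == 1L))
        expect_identical(unname(nxt[nd$id]), 0L)
    }
  }
})

test_that("compiled kernel agrees with the two-buffer reference stepper", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(4:7, 1L)
    spec <- random_network(n)
    # append an external input wired into the first dynamic node
    nodes <- c(unname(spec$nodes), list(node_spec("Cin", "external_input")))
    nodes[[2L]] <- node_spec(nodes[[2L]]$id, "dynamic",
                             activators = c(nodes[[2L]]$activators, "Cin"),
                             inhibitors = nodes[[2L]]$inhibitors,
                             threshold = nodes[[2L]]$threshold)
    spec <- network_spec(nodes)
    inputs <- list(Cin = periodic_input(sample(1:4, 1L)))
    init <- random_state(spec)
    init["Cin"] <- input_stream(inputs$Cin, 0L)
    tr <- simulate_network(spec, inputs = inputs, init = init, steps = 30)
    ref <- simulate_reference(spec, inputs, init, 30)
    expect_identical(unname(tr$series), unname(ref))
  }
})

test_that("trajectories are deterministic and start at the initial state", {
  spec <- build_net_a(net_a_params(6, 2))
  inputs <- list(C1 = periodic_input(3))
  t1 <- simulate_network(spec, inputs = inputs, steps = 40)
  t2 <- simulate_network(spec, inputs = inputs, steps = 40)
  expect_identical(t1$series, t2$series)
  expect_equal(nrow(t1$series), 41L)
  expect_equal(sum(t1$series[1L, setdiff(spec$ids, "C1")]), 0)
})

test_that("an all-zero network without constant drive stays silent", {
  spec <- network_spec(list(
    node_spec("A", activators = "B"),
    node_spec("B", activators = "A")))
  tr <- simulate_network(spec, steps = 10)
  expect_true(all(tr$series == 0L))
})

test_that("find_cycle returns a sound, re-simulable cycle", {
  set.seed(11)
  for (rep in 1:8) {
    spec <- random_network(sample(4:7, 1L))
    init <- random_state(spec)
    cyc <- find_cycle(spec, init = init)
    tr <- simulate_network(spec, init = init,
                           steps = cyc$transient_length +
                             2L * cyc$cycle_length)
    seg <- tr$series[cyc$transient_length + seq_len(cyc$cycle_length), ,
                     drop = FALSE]
    expect_identical(unname(seg), unname(cyc$cycle))
    # one more turn of the cycle reproduces it exactly
    seg2 <- tr$series[cyc$transient_length + cyc$cycle_length +
                        seq_len(cyc$cycle_length), , drop = FALSE]
    expect_identical(unname(seg2), unname(cyc$cycle))
    # no cycle state may appear in the transient
    if (cyc$transient_length > 0) {
      tra <- tr$series[seq_len(cyc$transient_length), , drop = FALSE]
      key <- function(m) apply(m, 1L, paste0, collapse = "")
      expect_length(intersect(key(tra), key(cyc$cycle)), 0L)
    }
  }
})

test_that("a constant-only network is a fixed point", {
  spec <- network_spec(list(node_spec("E", "constant_one")))
  cyc <- find_cycle(spec)
  expect_equal(cyc$transient_length, 0L)
  expect_equal(cyc$cycle_length, 1L)
})

test_that("find_cycle reports the cap when no recurrence is found", {
  spec <- build_net_a(net_a_params(50, 2))
  expect_error(find_cycle(spec, inputs = list(C1 = periodic_input(7)),
                          cap = 3L),
               "cycle-not-found.*cap = 3")
})

test_that("invalid specs and states are rejected with informative errors", {
  expect_error(node_spec("A", threshold = 0), "threshold")
  expect_error(node_spec("A", "constant_one", activators = "B"),
               "incoming edges")
  expect_error(node_spec("A", activators = "B", inhibitors = "B"),
               "overlapping")
  expect_error(network_spec(list(node_spec("A", activators = "zz"))),
               "undeclared")
  expect_error(network_spec(list(node_spec("A"), node_spec("A"))),
               "duplicate")
  spec <- build_net_a(net_a_params(3, 1))
  expect_error(next_state(spec, c(S1 = 0L)), "missing node")
  st <- init_state(spec)
  expect_error(next_state(spec, st), "missing input")
  expect_error(simulate_network(spec, steps = 5), "no input stream")
  expect_error(node_series(simulate_network(
    spec, inputs = list(C1 = periodic_input(2)), steps = 3), "nope"),
    "unknown node")
})

test_that("network JSON round-trips losslessly", {
  spec <- build_net_b(net_b_params(5, 3))
  path <- withr::local_tempfile(fileext = ".json")
  write_network_json(spec, path)
  back <- read_network_json(path)
  expect_identical(back$ids, spec$ids)
  expect_identical(back$inputs, spec$inputs)
  expect_identical(back$outputs, spec$outputs)
  for (id in spec$ids) {
    expect_identical(back$nodes[[id]]$activators, spec$nodes[[id]]$activators)
    expect_identical(back$nodes[[id]]$inhibitors, spec$nodes[[id]]$inhibitors)
    expect_identical(back$nodes[[id]]$threshold, spec$nodes[[id]]$threshold)
    expect_identical(back$nodes[[id]]$kind, spec$nodes[[id]]$kind)
  }
})

test_that("trajectory TSV export has the step column and bit values", {
  spec <- build_generator_ring(3)
  tr <- simulate_network(spec, steps = 6)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory_tsv(tr, path)
  df <- read.delim(path)
  expect_equal(names(df), c("step", "E", "S1", "S2", "C1"))
  expect_equal(df$step, 0:6)
  expect_true(all(as.matrix(df[-1L]) %in% 0:1))
})
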