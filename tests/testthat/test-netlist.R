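test_that("parsing mirrors the declared circuit", {
  txt <- c("node n1",
           "node ground reference=0",
           "component flow_source q ground n1 1e-6",
           "component resistor r n1 ground 1e8",
           "component capacitor c n1 ground 1e-8")
  n <- parse_netlist(txt)
  expect_length(n$components, 3L)
  expect_length(n$nodes, 2L)
  expect_identical(vapply(n$components, `[[`, "", "id"), c("q", "r", "c"))
  expect_identical(n$nodes[[2L]]$role, "reference")
})

test_that("a two-sub-circuit boundary-condition set parses into two graph components", {
  n <- two_bc_netlist()
  membership <- netlist_components(n)
  expect_identical(length(unique(membership)), 2L)
  # independent traversal oracle
  skip_if_not_installed("igraph")
  edges <- do.call(rbind, lapply(n$components, function(cc)
    c(cc$start, cc$end)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  expect_identical(length(unique(membership)),
                   as.integer(igraph::count_components(g)))
})

test_that("parser reports malformed input with line context", {
  expect_error(parse_netlist("node a\ncomponent resistor r a nX 1"),
               "nX")
  expect_error(parse_netlist(""), "empty")
  expect_error(
    parse_netlist("node a\nnode a\ncomponent resistor r a a 1"),
    "duplicate")
  expect_error(parse_netlist("node a\ncomponent gadget g a a 1"),
               "unknown component kind")
  expect_error(
    parse_netlist("node a\nnode b\ncomponent resistor r a b -2"),
    "negative")
  expect_error(parse_netlist("nonsense line here"), "line 1")
})

random_netlist <- function(seed) {
  set.seed(seed)
  n_nodes <- sample(2:5, 1)
  ids <- c(paste0("n", seq_len(n_nodes - 1L)), "gnd")
  nodes <- c(lapply(ids[-n_nodes], lpn_node),
             list(lpn_node("gnd", "reference", stats::runif(1, 0, 100))))
  kinds <- c("resistor", "capacitor", "inductor", "diode")
  comps <- lapply(seq_len(sample(1:6, 1)), function(i) {
    ab <- sample(ids, 2L)
    lpn_component(sample(kinds, 1), paste0("x", i), ab[1L], ab[2L],
                  stats::runif(1, 0, 10),
                  tag = if (stats::runif(1) < 0.3) paste0("tag", i)
                        else NA_character_)
  })
  lpn_netlist(comps, nodes)
}

test_that("parse-write-parse round trip is the identity", {
  fixtures <- list(make_windkessel2(1, 1), make_windkessel3(0.1, 1, 1),
                   make_coronary_bc(1, 1, 1, 1),
                   make_closed_loop()$netlist)
  for (seed in 1:20) fixtures <- c(fixtures, list(random_netlist(seed)))
  for (n in fixtures) {
    rt <- parse_netlist(write_netlist(n))
    expect_equal(rt$components, n$components)
    expect_equal(rt$nodes, n$nodes)
    expect_identical(write_netlist(rt), write_netlist(n))
  }
})

test_that("serialising a corrupted component kind fails", {
  n <- make_windkessel2(1, 1)
  n$components[[1L]]$kind <- "unobtainium"
  expect_error(write_netlist(n), "unknown kind")
})

test_that("validation separates solvable circuits from floating ones", {
  expect_false(has_errors(validate_netlist(make_windkessel2(1, 1))))
  # closed loop of two resistors, no reference, no storage: pressure level
  # undetermined
  floaty <- lpn_netlist(
    list(lpn_component("resistor", "r1", "a", "b", 1),
         lpn_component("resistor", "r2", "b", "a", 1)),
    list(lpn_node("a"), lpn_node("b")))
  diags <- validate_netlist(floaty)
  expect_true(has_errors(diags))
  codes <- vapply(diags, `[[`, "", "code")
  expect_true("floating_pressure" %in% codes)
  # independent oracle: nodal admittance matrix of the sub-circuit
  Y <- matrix(0, 2, 2)
  for (idx in list(c(1, 2), c(2, 1))) {
    Y[idx[1], idx[1]] <- Y[idx[1], idx[1]] + 1
    Y[idx[1], idx[2]] <- Y[idx[1], idx[2]] - 1
  }
  expect_lt(qr(Y)$rank, 2L)
})

test_that("a negative forward resistance injected in memory is flagged", {
  n <- make_windkessel2(1, 1)
  n$components[[1L]] <- lpn_component("diode", "d", "inlet", "ground", 0)
  n$components[[1L]]$r_fwd <- -1
  diags <- validate_netlist(n)
  codes <- vapply(diags, `[[`, "", "code")
  expect_true("negative_r_fwd" %in% codes)
})

test_that("validation rank check agrees with an admittance-matrix oracle", {
  # random resistive/capacitive circuits, sometimes without a reference
  for (seed in 1:25) {
    set.seed(100 + seed)
    n_free <- sample(2:4, 1)
    has_ref <- stats::runif(1) < 0.5
    ids <- paste0("n", seq_len(n_free))
    all_ids <- c(ids, if (has_ref) "gnd")
    nodes <- c(lapply(ids, lpn_node),
               if (has_ref) list(lpn_node("gnd", "reference", 0)))
    n_comp <- sample(2:6, 1)
    comps <- lapply(seq_len(n_comp), function(i) {
      ab <- sample(all_ids, 2L)
      lpn_component(sample(c("resistor", "capacitor"), 1),
                    paste0("x", i), ab[1L], ab[2L], stats::runif(1, .5, 2))
    })
    n <- lpn_netlist(comps, nodes)
    # oracle: BE-discretised admittance matrix over non-reference nodes,
    # assembled independently, rank-checked per connected sub-circuit
    dt <- 1
    membership <- netlist_components(n)
    ok_oracle <- TRUE
    for (k in unique(membership)) {
      sub_ids <- names(membership)[membership == k]
      free <- setdiff(sub_ids, "gnd")
      if (!length(free)) next
      Y <- matrix(0, length(free), length(free),
                  dimnames = list(free, free))
      touched <- FALSE
      for (comp in comps) {
        if (!(comp$start %in% sub_ids)) next
        touched <- TRUE
        g <- if (comp$kind == "resistor") 1 / comp$param
             else comp$param / dt
        for (a in c(comp$start, comp$end)) {
          if (a %in% free) Y[a, a] <- Y[a, a] + g
        }
        if (comp$start %in% free && comp$end %in% free) {
          Y[comp$start, comp$end] <- Y[comp$start, comp$end] - g
          Y[comp$end, comp$start] <- Y[comp$end, comp$start] - g
        }
      }
      if (!touched) next
      if (qr(Y, tol = 1e-10)$rank < nrow(Y)) ok_oracle <- FALSE
    }
    diags <- validate_netlist(n)
    codes <- vapply(diags, `[[`, "", "code")
    expect_identical(!"floating_pressure" %in% codes, ok_oracle,
                     info = sprintf("seed %d", seed))
  }
})

test_that("topology export is DOT with the declared structure", {
  n <- parse_netlist(c("node inlet interface",
                       "node ground reference=0",
                       "component flow_source q ground inlet 1",
                       "component resistor r inlet ground 1",
                       "component capacitor c inlet ground 1"))
  dot <- export_topology(n)
  expect_match(dot, "^graph lpn \\{")
  expect_identical(length(gregexpr(" -- ", dot)[[1L]]), 3L)  # 3 edges
  expect_match(dot, "\"inlet\" \\[role=interface, color=red")
  expect_match(dot, "\"ground\" \\[role=reference")
  kinds <- regmatches(dot, gregexpr("kind=[a-z_]+", dot))[[1L]]
  expect_true(all(sub("kind=", "", kinds) %in%
                    c("resistor", "capacitor", "inductor", "diode",
                      "pressure_source", "flow_source", "chamber")))
  expect_error(export_topology(
    structure(list(components = list(), nodes = list(),
                   metadata = list()), class = "lpn_netlist")), "empty")
})

test_that("two-sub-circuit topology keeps both components and flags interfaces", {
  n <- two_bc_netlist()
  dot <- export_topology(n)
  expect_identical(length(gregexpr("interface=true", dot)[[1L]]), 2L)
  skip_if_not_installed("igraph")
  edges <- do.call(rbind, lapply(n$components, function(cc)
    c(cc$start, cc$end)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  expect_identical(as.integer(igraph::count_components(g)), 2L)
})

test_that("netlist round trip preserves file I/O and hashing", {
  n <- make_windkessel3(0.1, 1, 1)
  tf <- withr::local_tempfile(fileext = ".netlist")
  write_netlist_file(n, tf)
  n2 <- read_netlist(tf)
  expect_identical(netlist_hash(n), netlist_hash(n2))
  expect_error(read_netlist(file.path(tempdir(), "nope.netlist")),
               "file not found")
})
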