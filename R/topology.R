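#' Connected components of the circuit graph
#'
#' Plain breadth-first traversal over the node set, treating every
#' two-terminal component as an undirected edge. Single-node sources touch
#' only their start node.
#'
#' @param n an \code{\link{lpn_netlist}}.
#' @return integer vector of component membership, named by node id;
#'   components numbered in order of first appearance.
#' @export
netlist_components <- function(n) {
  nid <- netlist_node_ids(n)
  adj <- stats::setNames(vector("list", length(nid)), nid)
  for (comp in n$components) {
    if (!is.na(comp$end)) {
      adj[[comp$start]] <- c(adj[[comp$start]], comp$end)
      adj[[comp$end]] <- c(adj[[comp$end]], comp$start)
    }
  }
  membership <- stats::setNames(rep(NA_integer_, length(nid)), nid)
  k <- 0L
  for (seed in nid) {
    if (!is.na(membership[[seed]])) next
    k <- k + 1L
    queue <- seed
    membership[[seed]] <- k
    while (length(queue)) {
      cur <- queue[[1L]]; queue <- queue[-1L]
      for (nb in adj[[cur]]) {
        if (is.na(membership[[nb]])) {
          membership[[nb]] <- k
          queue <- c(queue, nb)
        }
      }
    }
  }
  membership
}

diagnostic <- function(severity, code, message, subject = NA_character_) {
  structure(list(severity = severity, code = code, message = message,
                 subject = subject), class = "lpn_diagnostic")
}

#' @export
format.lpn_diagnostic <- function(x, ...) {
  sprintf("%s %s %s: %s", x$severity, x$code,
          if (is.na(x$subject)) "-" else x$subject, x$message)
}

#' @export
print.lpn_diagnostic <- function(x, ...) {
  cat(format(x), "\n"); invisible(x)
}

valid_tag_re <- "^[A-Za-z][A-Za-z0-9_.-]*$"

#' Validate a netlist
#'
#' Structural and solvability checks. A netlist is simulation-ready when the
#' returned list contains no \code{error}-severity diagnostics. Solvability
#' is checked per connected component by assembling the implicit step system
#' at a test operating point (all diodes open, unit time step, zero state)
#' and testing its rank: a rank-deficient system means the pressure level of
#' some sub-circuit is undetermined (no reference node reachable and no
#' pressure-fixing element), or the circuit is otherwise degenerate.
#'
#' @param n an \code{\link{lpn_netlist}}.
#' @return list of diagnostics (class \code{lpn_diagnostic}); each has
#'   severity \code{"error"} or \code{"warning"}.
#' @export
validate_netlist <- function(n) {
  stopifnot(inherits(n, "lpn_netlist"))
  diags <- list()
  add <- function(d) diags[[length(diags) + 1L]] <<- d

  for (comp in n$components) {
    if (comp$kind == "diode" && comp$r_fwd < 0)
      add(diagnostic("error", "negative_r_fwd",
                     "negative forward resistance", comp$id))
    if (comp$param < 0)
      add(diagnostic("error", "negative_parameter",
                     "negative parameter", comp$id))
    if (!is.na(comp$tag) && !grepl(valid_tag_re, comp$tag))
      add(diagnostic("error", "bad_control_tag",
                     sprintf("control tag '%s' is not a valid identifier",
                             comp$tag), comp$id))
    if (comp$kind == "chamber" && comp$param == 0)
      add(diagnostic("warning", "zero_elastance",
                     "chamber has zero elastance", comp$id))
  }

  tags <- vapply(n$components, `[[`, "", "tag")
  dup <- unique(tags[!is.na(tags) & duplicated(tags)])
  for (tg in dup)
    add(diagnostic("warning", "duplicate_tag",
                   sprintf("control tag '%s' appears on several components",
                           tg), tg))

  membership <- netlist_components(n)
  roles <- stats::setNames(vapply(n$nodes, `[[`, "", "role"),
                           netlist_node_ids(n))
  for (iface in names(roles)[roles == "interface"]) {
    touched <- any(vapply(n$components, function(comp)
      identical(comp$start, iface) || identical(comp$end, iface), logical(1)))
    if (!touched)
      add(diagnostic("warning", "dangling_interface",
                     "interface node attached to no component", iface))
  }

  # rank check per connected component, all diodes open
  for (k in unique(membership)) {
    sub_nodes <- names(membership)[membership == k]
    sub <- subset_netlist(n, sub_nodes)
    if (length(sub$components) == 0L) {
      add(diagnostic("warning", "isolated_node",
                     "node attached to no component", sub_nodes[1L]))
      next
    }
    mdl <- build_model(sub)
    states <- stats::setNames(rep("open", length(mdl$diode_ids)),
                              mdl$diode_ids)
    sys <- assemble_step_system(sub, initial_state(sub, mdl), forcing_none(),
                                dt = 1, diode_states = states,
                                scheme = "backward_euler",
                                model = mdl, check_singular = FALSE)
    if (equilibrated_rank(sys$M) < nrow(sys$M)) {
      add(diagnostic("error", "floating_pressure",
                     sprintf(paste0("floating pressure level or degenerate ",
                                    "sub-circuit on nodes {%s}"),
                             paste(sub_nodes, collapse = ",")),
                     sub_nodes[1L]))
    }
  }
  diags
}

# restrict a netlist to the components touching the given node set
subset_netlist <- function(n, node_ids) {
  comps <- Filter(function(comp) comp$start %in% node_ids ||
                    (!is.na(comp$end) && comp$end %in% node_ids),
                  n$components)
  nds <- Filter(function(nd) nd$id %in% node_ids, n$nodes)
  if (length(comps) == 0L)
    return(structure(list(components = list(), nodes = nds,
                          metadata = n$metadata), class = "lpn_netlist"))
  lpn_netlist(comps, nds, n$metadata)
}

#' Has the validation any errors?
#' @param diags result of \code{\link{validate_netlist}}.
#' @return logical.
#' @export
has_errors <- function(diags) {
  any(vapply(diags, function(d) d$severity == "error", logical(1)))
}

kind_colour <- c(resistor = "firebrick", capacitor = "royalblue",
                 inductor = "darkgreen", diode = "darkorange",
                 pressure_source = "purple", flow_source = "deeppink",
                 chamber = "goldenrod")

#' Export circuit topology as DOT
#'
#' One vertex per node and one edge per two-terminal component; edges carry
#' the component kind and id, with a colour per kind. Interface nodes (the
#' attachment points for external forcing) are drawn red; reference nodes
#' are squares. Single-node sources annotate their node. The output is valid
#' Graphviz DOT.
#'
#' @param n an \code{\link{lpn_netlist}}.
#' @return a single DOT string.
#' @export
export_topology <- function(n) {
  stopifnot(inherits(n, "lpn_netlist"))
  if (length(n$components) == 0L) stop("empty netlist")
  out <- c("graph lpn {", "  node [shape=point, width=0.12];")
  for (nd in n$nodes) {
    attrs <- sprintf("role=%s", nd$role)
    if (nd$role == "interface")
      attrs <- paste0(attrs, ", color=red, interface=true")
    if (nd$role == "reference")
      attrs <- paste0(attrs, ", shape=square")
    out <- c(out, sprintf("  \"%s\" [%s];", nd$id, attrs))
  }
  for (comp in n$components) {
    if (is.na(comp$end)) {
      out <- c(out, sprintf("  \"%s\" [source=\"%s:%s\"];",
                            comp$start, comp$kind, comp$id))
    } else {
      out <- c(out, sprintf(
        "  \"%s\" -- \"%s\" [kind=%s, id=\"%s\", color=%s, label=\"%s\"];",
        comp$start, comp$end, comp$kind, comp$id,
        kind_colour[[comp$kind]], comp$id))
    }
  }
  paste0(paste(c(out, "}"), collapse = "\n"), "\n")
}
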