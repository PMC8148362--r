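#' @keywords internal
"_PACKAGE"

COMPONENT_KINDS <- c("resistor", "capacitor", "inductor", "diode",
                     "pressure_source", "flow_source", "chamber")
NODE_ROLES <- c("internal", "reference", "interface")

#' Create a lumped-parameter-network component
#'
#' A component is one edge of the hydraulic circuit: a resistor, capacitor,
#' inductor, ideal-diode valve, pressure or flow source, or a time-varying
#' elastance heart chamber. Positive flow runs from \code{start} to
#' \code{end}; diodes conduct in that direction only. Sources may be
#' single-node (omit \code{end}), in which case a pressure source pins the
#' node pressure and a flow source injects flow into the node.
#'
#' @param kind one of \code{"resistor"}, \code{"capacitor"},
#'   \code{"inductor"}, \code{"diode"}, \code{"pressure_source"},
#'   \code{"flow_source"}, \code{"chamber"}.
#' @param id unique component identifier.
#' @param start,end terminal node ids (\code{end = NA} for single-node
#'   sources).
#' @param param component parameter in SI hydraulic units: resistance
#'   Pa.s/m^3, compliance m^3/Pa, inertance Pa.s^2/m^3, elastance Pa/m^3,
#'   source value Pa or m^3/s. Must be non-negative.
#' @param tag optional control tag; controllers address components by tag.
#' @param r_fwd diode forward resistance (Pa.s/m^3, >= 0); diodes only.
#' @param init_dp initial pressure difference across a capacitor (Pa).
#' @param init_q initial flow through an inductor (m^3/s).
#' @param init_v initial chamber volume (m^3).
#' @param v0 chamber unstressed volume (m^3).
#' @return an object of class \code{lpn_component}.
#' @export
lpn_component <- function(kind, id, start, end = NA_character_, param = 0,
                          tag = NA_character_, r_fwd = 0,
                          init_dp = NA_real_, init_q = NA_real_,
                          init_v = NA_real_, v0 = 0) {
  kind <- match.arg(kind, COMPONENT_KINDS)
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("component id must be a non-empty string")
  if (!is.finite(param) || param < 0)
    stop(sprintf("component '%s': parameter must be finite and >= 0", id))
  if (is.na(end) && !kind %in% c("pressure_source", "flow_source"))
    stop(sprintf("component '%s': only sources may be single-node", id))
  if (kind == "diode" && (!is.finite(r_fwd) || r_fwd < 0))
    stop(sprintf("diode '%s': forward resistance must be >= 0", id))
  if (!is.na(init_dp) && kind != "capacitor")
    stop(sprintf("component '%s': init_dp only valid for capacitors", id))
  if (!is.na(init_q) && kind != "inductor")
    stop(sprintf("component '%s': init_q only valid for inductors", id))
  if ((!is.na(init_v) || v0 != 0) && kind != "chamber")
    stop(sprintf("component '%s': volume fields only valid for chambers", id))
  structure(list(id = id, kind = kind, start = start, end = end,
                 param = param, tag = tag, r_fwd = r_fwd,
                 init_dp = init_dp, init_q = init_q,
                 init_v = init_v, v0 = v0),
            class = "lpn_component")
}

#' Create a circuit node
#'
#' @param id unique node identifier.
#' @param role \code{"internal"} (default), \code{"reference"} (pressure
#'   pinned at \code{pressure}, the hydraulic ground), or
#'   \code{"interface"} (attachment point for external forcing, standing in
#'   for an upstream/downstream 3D domain under a Dirichlet-to-Neumann
#'   coupling contract).
#' @param pressure prescribed pressure (Pa); reference nodes only.
#' @return an object of class \code{lpn_node}.
#' @export
lpn_node <- function(id, role = "internal", pressure = NA_real_) {
  role <- match.arg(role, NODE_ROLES)
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("node id must be a non-empty string")
  if (role == "reference") {
    if (is.na(pressure)) pressure <- 0
  } else if (!is.na(pressure)) {
    stop(sprintf("node '%s': only reference nodes carry a prescribed pressure", id))
  }
  structure(list(id = id, role = role, pressure = pressure),
            class = "lpn_node")
}

#' Assemble a netlist from components and nodes
#'
#' @param components list of \code{\link{lpn_component}} objects.
#' @param nodes list of \code{\link{lpn_node}} objects covering every node
#'   referenced by a component.
#' @param metadata named list of free-form annotations (name, units, ...).
#' @return an object of class \code{lpn_netlist}.
#' @export
lpn_netlist <- function(components, nodes, metadata = list()) {
  if (length(components) < 1L) stop("a netlist needs at least one component")
  cid <- vapply(components, `[[`, "", "id")
  nid <- vapply(nodes, `[[`, "", "id")
  if (anyDuplicated(cid)) stop(sprintf("duplicate component id '%s'",
                                       cid[duplicated(cid)][1L]))
  if (anyDuplicated(nid)) stop(sprintf("duplicate node id '%s'",
                                       nid[duplicated(nid)][1L]))
  if (anyDuplicated(c(cid, nid)))
    stop("component and node ids must not collide")
  for (comp in components) {
    for (term in c(comp$start, comp$end)) {
      if (!is.na(term) && !term %in% nid)
        stop(sprintf("component '%s' references undeclared node '%s'",
                     comp$id, term))
    }
  }
  structure(list(components = components, nodes = nodes,
                 metadata = metadata),
            class = "lpn_netlist")
}

#' @export
print.lpn_netlist <- function(x, ...) {
  cat(sprintf("LPN netlist: %d components, %d nodes\n",
              length(x$components), length(x$nodes)))
  kinds <- table(vapply(x$components, `[[`, "", "kind"))
  cat("  ", paste(sprintf("%s=%d", names(kinds), kinds), collapse = " "), "\n")
  roles <- vapply(x$nodes, `[[`, "", "role")
  cat(sprintf("  reference nodes: %s; interface nodes: %s\n",
              paste(vapply(x$nodes, `[[`, "", "id")[roles == "reference"],
                    collapse = ",") ,
              paste(vapply(x$nodes, `[[`, "", "id")[roles == "interface"],
                    collapse = ",")))
  invisible(x)
}

netlist_component_ids <- function(n) vapply(n$components, `[[`, "", "id")
netlist_node_ids <- function(n) vapply(n$nodes, `[[`, "", "id")

find_component <- function(n, id) {
  for (comp in n$components) if (comp$id == id) return(comp)
  NULL
}

# numeric formatting that round-trips doubles exactly
num_repr <- function(x) sprintf("%.17g", x)

parse_num <- function(s, lineno, what) {
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v) && !identical(tolower(s), "nan"))
    stop(sprintf("line %d: invalid number '%s' for %s", lineno, s, what))
  v
}

#' Parse a netlist from its text representation
#'
#' The format is line-oriented and diff-friendly. Blank lines and lines
#' starting with \code{#} are ignored. Three directives exist:
#' \preformatted{
#' meta <key> <value ...>
#' node <id> [reference[=<Pa>]] [interface]
#' component <kind> <id> <start> <end|-> <param> [key=value ...]
#' }
#' \code{-} marks an absent end node (single-node sources). Recognised
#' component keys: \code{tag}, \code{r_fwd}, \code{init_dp}, \code{init_q},
#' \code{init_v}, \code{v0}. All values SI.
#'
#' @param text netlist source, either a single string (possibly with
#'   embedded newlines) or a character vector of lines.
#' @return an \code{\link{lpn_netlist}}.
#' @seealso \code{\link{write_netlist}}, \code{\link{read_netlist}}
#' @export
parse_netlist <- function(text) {
  if (length(text) == 1L) text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  if (length(text) == 0L || all(!nzchar(trimws(text))))
    stop("empty netlist text")
  components <- list()
  nodes <- list()
  metadata <- list()
  for (i in seq_along(text)) {
    line <- trimws(sub("#.*$", "", text[i]))
    if (!nzchar(line)) next
    tok <- strsplit(line, "[[:space:]]+")[[1L]]
    directive <- tok[1L]
    if (directive == "meta") {
      if (length(tok) < 3L)
        stop(sprintf("line %d: meta needs a key and a value", i))
      metadata[[tok[2L]]] <- paste(tok[-(1:2)], collapse = " ")
    } else if (directive == "node") {
      if (length(tok) < 2L) stop(sprintf("line %d: node needs an id", i))
      role <- "internal"; pressure <- NA_real_
      for (opt in tok[-(1:2)]) {
        if (opt == "interface") {
          role <- "interface"
        } else if (opt == "reference") {
          role <- "reference"; pressure <- 0
        } else if (startsWith(opt, "reference=")) {
          role <- "reference"
          pressure <- parse_num(sub("^reference=", "", opt), i,
                                "reference pressure")
        } else {
          stop(sprintf("line %d: unknown node option '%s'", i, opt))
        }
      }
      nd <- tryCatch(lpn_node(tok[2L], role, pressure),
                     error = function(e) stop(sprintf("line %d: %s", i,
                                                      conditionMessage(e))))
      nodes[[length(nodes) + 1L]] <- nd
    } else if (directive == "component") {
      if (length(tok) < 6L)
        stop(sprintf(
          "line %d: component needs <kind> <id> <start> <end|-> <param>", i))
      kind <- tok[2L]
      if (!kind %in% COMPONENT_KINDS)
        stop(sprintf("line %d: unknown component kind '%s'", i, kind))
      endid <- if (tok[5L] == "-") NA_character_ else tok[5L]
      param <- parse_num(tok[6L], i, "parameter")
      if (!is.finite(param) || param < 0)
        stop(sprintf("line %d: negative or non-finite parameter for '%s'",
                     i, tok[3L]))
      extras <- list()
      for (opt in tok[-(1:6)]) {
        kv <- strsplit(opt, "=", fixed = TRUE)[[1L]]
        if (length(kv) != 2L)
          stop(sprintf("line %d: malformed key=value '%s'", i, opt))
        extras[[kv[1L]]] <- kv[2L]
      }
      bad <- setdiff(names(extras),
                     c("tag", "r_fwd", "init_dp", "init_q", "init_v", "v0"))
      if (length(bad))
        stop(sprintf("line %d: unknown component key '%s'", i, bad[1L]))
      getnum <- function(key, default) {
        if (is.null(extras[[key]])) default
        else parse_num(extras[[key]], i, key)
      }
      comp <- tryCatch(
        lpn_component(kind, tok[3L], tok[4L], endid, param,
                      tag = if (is.null(extras$tag)) NA_character_
                            else extras$tag,
                      r_fwd = getnum("r_fwd", 0),
                      init_dp = getnum("init_dp", NA_real_),
                      init_q = getnum("init_q", NA_real_),
                      init_v = getnum("init_v", NA_real_),
                      v0 = getnum("v0", 0)),
        error = function(e) stop(sprintf("line %d: %s", i,
                                         conditionMessage(e))))
      components[[length(components) + 1L]] <- comp
    } else {
      stop(sprintf("line %d: unknown directive '%s'", i, directive))
    }
  }
  lpn_netlist(components, nodes, metadata)
}

#' Serialise a netlist to its text representation
#'
#' Writes the same line-oriented format accepted by
#' \code{\link{parse_netlist}}; the round trip
#' \code{parse_netlist(write_netlist(n))} is structurally the identity.
#' Numbers are emitted with enough digits to round-trip doubles exactly.
#'
#' @param n an \code{\link{lpn_netlist}}.
#' @return a single string.
#' @export
write_netlist <- function(n) {
  stopifnot(inherits(n, "lpn_netlist"))
  out <- character()
  for (key in names(n$metadata)) {
    val <- n$metadata[[key]]
    if (!is.character(val) && !is.numeric(val))
      stop(sprintf("metadata entry '%s' is not serialisable", key))
    out <- c(out, sprintf("meta %s %s", key, as.character(val)))
  }
  for (nd in n$nodes) {
    line <- paste("node", nd$id)
    if (nd$role == "reference")
      line <- paste0(line, " reference=", num_repr(nd$pressure))
    if (nd$role == "interface") line <- paste(line, "interface")
    out <- c(out, line)
  }
  for (comp in n$components) {
    if (!comp$kind %in% COMPONENT_KINDS)
      stop(sprintf("component '%s' has unknown kind '%s'",
                   comp$id, comp$kind))
    line <- sprintf("component %s %s %s %s %s", comp$kind, comp$id,
                    comp$start,
                    if (is.na(comp$end)) "-" else comp$end,
                    num_repr(comp$param))
    if (!is.na(comp$tag)) line <- paste0(line, " tag=", comp$tag)
    if (comp$kind == "diode" && comp$r_fwd != 0)
      line <- paste0(line, " r_fwd=", num_repr(comp$r_fwd))
    if (!is.na(comp$init_dp))
      line <- paste0(line, " init_dp=", num_repr(comp$init_dp))
    if (!is.na(comp$init_q))
      line <- paste0(line, " init_q=", num_repr(comp$init_q))
    if (!is.na(comp$init_v))
      line <- paste0(line, " init_v=", num_repr(comp$init_v))
    if (comp$kind == "chamber" && comp$v0 != 0)
      line <- paste0(line, " v0=", num_repr(comp$v0))
    out <- c(out, line)
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Read or write a netlist file
#'
#' @param path file path.
#' @param n an \code{\link{lpn_netlist}} (for writing).
#' @return \code{read_netlist} returns an \code{lpn_netlist};
#'   \code{write_netlist_file} returns \code{path} invisibly.
#' @export
read_netlist <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  parse_netlist(readLines(path, warn = FALSE))
}

#' @rdname read_netlist
#' @export
write_netlist_file <- function(n, path) {
  writeLines(sub("\n$", "", write_netlist(n)), path)
  invisible(path)
}

#' Hash of a netlist's canonical text form
#'
#' Used for run provenance in result sidecars.
#' @param n an \code{\link{lpn_netlist}}.
#' @return md5 hex string.
#' @export
netlist_hash <- function(n) {
  tf <- tempfile(fileext = ".netlist")
  on.exit(unlink(tf))
  writeLines(write_netlist(n), tf)
  unname(tools::md5sum(tf))
}
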