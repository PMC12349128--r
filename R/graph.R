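#' Read an undirected simple graph from a plain-text edge list
#'
#' Parses the edge-list dialect used by public network repositories
#' (konect, networkrepository): one edge per line, two node identifiers
#' separated by whitespace or commas, with \code{#} or \code{\%} opening
#' comment lines. Extra columns (e.g. weights, timestamps) are ignored.
#' Duplicate edges -- including reversed duplicates -- collapse to one
#' undirected edge; self-loops are dropped and their count reported via
#' \code{message()}. Node identifiers are kept as opaque strings.
#'
#' @param source path to a file, or a character vector of lines (anything
#'   with length > 1, or length 1 containing a newline, is treated as lines).
#' @return an undirected simple \code{igraph} graph with named vertices.
#' @examples
#' g <- read_edgelist(c("a b", "b a", "a b"))
#' igraph::vcount(g) # 2
#' igraph::ecount(g) # 1
#' @export
read_edgelist <- function(source) {
  if (is.character(source) && length(source) == 1 &&
      !grepl("[\n\r]", source) && file.exists(source)) {
    lines <- readLines(source, warn = FALSE)
  } else if (is.character(source)) {
    lines <- unlist(strsplit(source, "\r?\n"))
  } else {
    stop("'source' must be a file path or a character vector of lines")
  }

  is_comment <- grepl("^[[:space:]]*[#%]", lines)
  is_blank   <- grepl("^[[:space:]]*$", lines)
  keep <- which(!is_comment & !is_blank)
  if (length(keep) == 0L) {
    stop("empty edge list: no data lines found")
  }

  from <- character(length(keep))
  to   <- character(length(keep))
  for (i in seq_along(keep)) {
    tokens <- strsplit(trimws(lines[keep[i]]), "[,[:space:]]+")[[1]]
    tokens <- tokens[nzchar(tokens)]
    if (length(tokens) < 2L) {
      stop(sprintf("malformed edge list: line %d has fewer than 2 tokens",
                   keep[i]))
    }
    from[i] <- tokens[1]
    to[i]   <- tokens[2]
  }

  loops <- from == to
  if (any(loops)) {
    message(sprintf("dropped %d self-loop(s)", sum(loops)))
    from <- from[!loops]
    to   <- to[!loops]
  }
  nodes <- unique(c(from, to))
  if (length(nodes) == 0L) {
    stop("empty edge list: all lines were self-loops")
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Write a graph as a plain-text edge list
#'
#' One edge per line, two node identifiers separated by a tab. Isolated
#' nodes are recorded in a trailing comment block so that a round-trip
#' through \code{\link{read_edgelist}} plus \code{add_isolates} recovers
#' the full vertex set; the edge set always round-trips exactly.
#'
#' @param g an igraph graph.
#' @param path output file path.
#' @param header optional character vector written as '#' comment lines.
#' @return \code{path}, invisibly.
#' @export
write_edgelist <- function(g, path, header = NULL) {
  stopifnot(igraph::is_igraph(g))
  el <- igraph::as_edgelist(g, names = TRUE)
  lines <- character(0)
  if (!is.null(header)) lines <- paste0("# ", header)
  lines <- c(lines, paste(el[, 1], el[, 2], sep = "\t"))
  iso <- igraph::V(g)$name[igraph::degree(g) == 0]
  if (length(iso) > 0) {
    lines <- c(lines, paste0("# isolated: ", paste(iso, collapse = " ")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Neighbor set of a node
#'
#' @param g an igraph graph.
#' @param v a node identifier (vertex name).
#' @return character vector of neighbor names; never contains \code{v}.
#' @export
node_neighbors <- function(g, v) {
  idx <- match(v, igraph::V(g)$name)
  if (is.na(idx)) stop(sprintf("unknown node: '%s'", v))
  igraph::V(g)$name[igraph::neighbors(g, idx)]
}

#' K-shell (k-core) decomposition
#'
#' Iterative peeling: for k = 1, 2, ... remove all nodes of degree <= k
#' until the graph is empty; a node's shell index Ks is the largest k
#' at which it is still present when round k starts. Isolated nodes get
#' Ks = 0. Equivalent to the coreness of each vertex.
#'
#' @param g an igraph graph.
#' @return named integer vector of shell indices, one per node.
#' @export
kshell <- function(g) {
  stopifnot(igraph::is_igraph(g))
  ks <- igraph::coreness(g)
  storage.mode(ks) <- "integer"
  names(ks) <- igraph::V(g)$name
  ks
}

#' Maximum node degree
#'
#' @param g a non-empty igraph graph.
#' @return integer, the maximum degree (0 if all nodes are isolated).
#' @export
max_degree <- function(g) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::vcount(g) == 0L) {
    stop("max_degree is undefined on an empty graph")
  }
  as.integer(max(igraph::degree(g)))
}

#' Per-node degree and k-shell profile
#'
#' @param g an igraph graph.
#' @return data.frame with columns \code{node}, \code{degree}, \code{kshell}.
#' @export
node_profiles <- function(g) {
  stopifnot(igraph::is_igraph(g))
  data.frame(
    node = igraph::V(g)$name,
    degree = as.integer(igraph::degree(g)),
    kshell = as.integer(kshell(g)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

# Order node names naturally: if every name is '<prefix><integer>' with a
# common prefix (v1, v2, ..., v10) sort by the integer, else lexicographic.
natural_order_key <- function(nms) {
  m <- regmatches(nms, regexec("^([^0-9]*)([0-9]+)$", nms))
  ok <- lengths(m) == 3L
  if (all(ok) && length(unique(vapply(m, `[`, "", 2L))) == 1L) {
    as.numeric(vapply(m, `[`, "", 3L))
  } else {
    nms
  }
}
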