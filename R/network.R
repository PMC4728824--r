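# File-backed interaction store and BFS interactor neighborhoods.

#' Load gene-gene interactions from TSV
#'
#' Three or four tab-delimited columns: gene A, gene B, evidence class
#' (\code{biochemical} or \code{computational}) and an optional free-text
#' method (e.g. Yeast Two-Hybrid, Pull-Down). Edges are undirected; the
#' same pair listed twice in either orientation collapses to one edge with
#' methods merged (\code{;}-joined, sorted, unique). A header row is
#' auto-detected. Unknown evidence values are an error.
#'
#' @param tsv_path File path.
#' @return An [InteractionStore-class].
#' @export
loadInteractions <- function(tsv_path) {
  if (!file.exists(tsv_path)) stop("interactions file not found: ", tsv_path)
  lines <- readLines(tsv_path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("empty interactions file: ", tsv_path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L))
    stop("interaction rows need >= 3 tab-delimited fields")
  a <- vapply(parts, `[`, "", 1L)
  b <- vapply(parts, `[`, "", 2L)
  ev <- vapply(parts, `[`, "", 3L)
  me <- vapply(parts, function(p) if (length(p) >= 4L) p[4L] else "", "")
  if (tolower(ev[1L]) %in% c("evidence", "class", "type")) {  # header
    a <- a[-1L]; b <- b[-1L]; ev <- ev[-1L]; me <- me[-1L]
  }
  ev <- tolower(ev)
  bad <- which(!ev %in% c("biochemical", "computational"))
  if (length(bad))
    stop("unknown evidence class '", ev[bad[1L]], "' (row ", bad[1L],
         "); expected biochemical or computational")
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, ev, sep = "\r")
  agg <- split(me, key)
  keys <- sort(names(agg))
  kp <- strsplit(keys, "\r", fixed = TRUE)
  edges <- data.frame(
    gene_a = vapply(kp, `[`, "", 1L),
    gene_b = vapply(kp, `[`, "", 2L),
    evidence = vapply(kp, `[`, "", 3L),
    method = vapply(keys, function(k) {
      m <- sort(unique(agg[[k]][nzchar(agg[[k]])]))
      paste(m, collapse = ";")
    }, "", USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  new("InteractionStore", edges = edges)
}

#' @describeIn loadInteractions Edge table accessor.
#' @param store An [InteractionStore-class].
#' @export
interactionEdges <- function(store) {
  stopifnot(is(store, "InteractionStore"))
  store@edges
}

#' Interactor neighborhood of a gene
#'
#' Deterministic breadth-first expansion around a root gene: at each layer
#' every not-yet-included edge incident to an already-reached node is
#' added, optionally restricted to one evidence class. Nodes within a layer
#' and edges are ordered lexicographically. A root absent from the store
#' yields an empty neighborhood.
#'
#' @param store An [InteractionStore-class].
#' @param root Root gene id.
#' @param depth Number of BFS layers (>= 1).
#' @param evidence Optional filter: \code{"biochemical"} or
#'   \code{"computational"}.
#' @return A [Neighborhood-class].
#' @export
interactionNeighborhood <- function(store, root, depth = 1L,
                                    evidence = NULL) {
  stopifnot(is(store, "InteractionStore"), depth >= 1L)
  e <- store@edges
  if (!is.null(evidence)) {
    evidence <- match.arg(evidence, c("biochemical", "computational"))
    e <- e[e$evidence == evidence, , drop = FALSE]
  }
  visited <- root
  picked <- logical(nrow(e))
  edge_depth <- integer(0)
  sel_rows <- integer(0)
  for (d in seq_len(depth)) {
    inc <- which(!picked & (e$gene_a %in% visited | e$gene_b %in% visited))
    if (length(inc) == 0L) break
    picked[inc] <- TRUE
    sel_rows <- c(sel_rows, inc)
    edge_depth <- c(edge_depth, rep(as.integer(d), length(inc)))
    visited <- unique(c(visited, e$gene_a[inc], e$gene_b[inc]))
  }
  edges <- e[sel_rows, , drop = FALSE]
  edges$depth <- edge_depth
  o <- order(edges$depth, edges$gene_a, edges$gene_b, edges$evidence)
  edges <- edges[o, , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- root
  for (d in unique(edges$depth)) {
    layer <- edges[edges$depth == d, , drop = FALSE]
    nodes <- c(nodes, sort(setdiff(unique(c(layer$gene_a, layer$gene_b)),
                                   nodes)))
  }
  new("Neighborhood", root = root, depth = as.integer(depth),
      edges = edges, nodes = nodes)
}

#' Export a neighborhood as SIF and/or GraphML
#'
#' SIF rows are \code{gene_a <evidence> gene_b}; GraphML is written via
#' igraph with \code{evidence}, \code{method} and \code{depth} edge
#' attributes and optional per-node annotation attributes.
#'
#' @param nbhd A [Neighborhood-class].
#' @param sif,graphml Output paths (either may be \code{NULL}).
#' @param annotations Optional \code{data.frame} with columns
#'   \code{gene_id}, \code{name}, \code{ec} used as node attributes.
#' @return Invisibly, the vector of files written.
#' @export
exportNetwork <- function(nbhd, sif = NULL, graphml = NULL,
                          annotations = NULL) {
  stopifnot(is(nbhd, "Neighborhood"))
  written <- character(0)
  e <- nbhd@edges
  if (!is.null(sif)) {
    lines <- if (nrow(e)) paste(e$gene_a, e$evidence, e$gene_b, sep = "\t")
             else character(0)
    writeLines(lines, sif)
    written <- c(written, sif)
  }
  if (!is.null(graphml)) {
    if (nrow(e) == 0L) {
      g <- igraph::make_empty_graph(n = length(nbhd@nodes), directed = FALSE)
      if (length(nbhd@nodes))
        igraph::V(g)$name <- nbhd@nodes
    } else {
      g <- igraph::graph_from_data_frame(
        e[, c("gene_a", "gene_b", "evidence", "method", "depth")],
        directed = FALSE, vertices = data.frame(name = nbhd@nodes))
    }
    if (!is.null(annotations) && length(igraph::V(g))) {
      i <- match(igraph::V(g)$name, annotations$gene_id)
      if ("name" %in% names(annotations))
        igraph::V(g)$label <- ifelse(is.na(i), "", annotations$name[i])
      if ("ec" %in% names(annotations))
        igraph::V(g)$ec <- ifelse(is.na(i), "", annotations$ec[i])
    }
    igraph::write_graph(g, graphml, format = "graphml")
    written <- c(written, graphml)
  }
  invisible(written)
}
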