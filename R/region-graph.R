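#' Region neighbourhood graphs
#'
#' A `region_graph` holds an ordered set of region identifiers together with
#' the symmetric neighbour relation between them. It is the combinatorial
#' backbone of the analysis: the intrinsic CAR (Besag) precision of the
#' spatial random field is `degree - adjacency` on exactly this graph, with
#' one link wherever two regions share a border.
#'
#' @param region_ids character vector of unique region identifiers; their
#'   order fixes the row/column order of every matrix built on the graph.
#' @param edges two-column matrix (or data.frame) of edges, each row an
#'   unordered pair of region indices (1-based) or region identifiers.
#' @param region_names optional vector of human-readable names.
#'
#' @return An object of class `region_graph`: a list with elements
#'   `region_ids`, `edges` (integer matrix, one row per undirected edge,
#'   `edges[, 1] < edges[, 2]`), and `region_names`.
#' @examples
#' g <- region_graph(c("A", "B", "C"), rbind(c(1, 2), c(2, 3)))
#' n_regions(g)
#' @export
region_graph <- function(region_ids, edges, region_names = NULL) {
  region_ids <- as.character(region_ids)
  if (anyDuplicated(region_ids)) stop("region_ids must be unique")
  n <- length(region_ids)
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop("edges must have two columns")
  if (is.character(edges)) {
    idx <- match(edges, region_ids)
    if (anyNA(idx)) stop("edge endpoint not in region_ids: ",
                         paste(unique(edges[is.na(idx)]), collapse = ", "))
    edges <- matrix(idx, ncol = 2L)
  }
  storage.mode(edges) <- "integer"
  if (nrow(edges) > 0) {
    if (any(edges < 1L) || any(edges > n)) stop("edge index out of range")
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
    edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    edges <- unique(edges)
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  structure(list(region_ids = region_ids, edges = edges,
                 region_names = region_names),
            class = "region_graph")
}

#' @rdname region_graph
#' @param graph a `region_graph`.
#' @export
n_regions <- function(graph) length(graph$region_ids)

#' @export
print.region_graph <- function(x, ...) {
  cat(sprintf("region_graph: %d regions, %d edges, %sconnected\n",
              n_regions(x), nrow(x$edges),
              if (is_connected_graph(x)) "" else "NOT "))
  invisible(x)
}

#' Adjacency matrix of a region graph
#'
#' @param graph a `region_graph`.
#' @return sparse symmetric 0/1 adjacency matrix.
#' @export
adjacency_matrix <- function(graph) {
  n <- n_regions(graph)
  e <- graph$edges
  Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                       x = 1, dims = c(n, n),
                       dimnames = list(graph$region_ids, graph$region_ids))
}

#' @rdname adjacency_matrix
#' @export
is_connected_graph <- function(graph) {
  n <- n_regions(graph)
  if (n == 1L) return(TRUE)
  if (nrow(graph$edges) == 0L) return(FALSE)
  ig <- igraph::make_empty_graph(n, directed = FALSE)
  ig <- igraph::add_edges(ig, t(graph$edges))
  igraph::is_connected(ig)
}

#' Lattice region graph with random diagonal augmentation
#'
#' Builds a connected `n_rows` x `n_cols` grid of regions joined by
#' rook-neighbour links, then adds one randomly oriented diagonal link inside
#' a random subset of grid cells. The diagonals break the perfect regularity
#' of the lattice so that simulated geographies have the irregular degree
#' sequences of real administrative maps.
#'
#' @param n_rows,n_cols lattice dimensions; `n_rows * n_cols >= 2`.
#' @param seed integer seed controlling the diagonal augmentation.
#' @param diag_prob probability that a unit cell receives a diagonal link.
#' @return a connected [region_graph()] with `n_rows * n_cols` regions.
#' @examples
#' make_region_graph(4, 4, seed = 7)
#' @export
make_region_graph <- function(n_rows, n_cols, seed, diag_prob = 0.25) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L || n_rows * n_cols < 2L)
    stop("need n_rows * n_cols >= 2 regions (a single region cannot carry a CAR structure)")
  idx <- function(r, c) (r - 1L) * n_cols + c
  edges <- NULL
  for (r in seq_len(n_rows)) for (cc in seq_len(n_cols)) {
    if (cc < n_cols) edges <- rbind(edges, c(idx(r, cc), idx(r, cc + 1L)))
    if (r < n_rows) edges <- rbind(edges, c(idx(r, cc), idx(r + 1L, cc)))
  }
  with_seed(seed, {
    for (r in seq_len(n_rows - 1L)) for (cc in seq_len(n_cols - 1L)) {
      if (stats::runif(1) < diag_prob) {
        if (stats::runif(1) < 0.5)
          edges <- rbind(edges, c(idx(r, cc), idx(r + 1L, cc + 1L)))
        else
          edges <- rbind(edges, c(idx(r, cc + 1L), idx(r + 1L, cc)))
      }
    }
  })
  ids <- sprintf("R%02d", seq_len(n_rows * n_cols))
  region_graph(ids, edges)
}

#' Neighbourhood graph of the merged German federal states
#'
#' The 13-unit region system used throughout the package's examples: the 16
#' German federal states with the city states merged into their surrounding
#' states (Hamburg into Schleswig-Holstein, Bremen into Lower Saxony, Berlin
#' into Brandenburg), joined by shared land borders.
#'
#' @return a connected [region_graph()] with 13 regions. Region ids are the
#'   usual two-letter state codes; the merged units keep the surrounding
#'   state's code.
#' @examples
#' german_region_graph()
#' @export
german_region_graph <- function() {
  ids <- c("SH", "NI", "MV", "BB", "ST", "SN", "TH", "HE", "NW", "RP",
           "SL", "BW", "BY")
  names <- c("Schleswig-Holstein + Hamburg", "Niedersachsen + Bremen",
             "Mecklenburg-Vorpommern", "Brandenburg + Berlin",
             "Sachsen-Anhalt", "Sachsen", "Thüringen", "Hessen",
             "Nordrhein-Westfalen", "Rheinland-Pfalz", "Saarland",
             "Baden-Württemberg", "Bayern")
  borders <- rbind(
    c("SH", "NI"), c("SH", "MV"), c("NI", "MV"), c("NI", "ST"),
    c("NI", "TH"), c("NI", "HE"), c("NI", "NW"), c("MV", "BB"),
    c("BB", "ST"), c("BB", "SN"), c("ST", "SN"), c("ST", "TH"),
    c("SN", "TH"), c("SN", "BY"), c("TH", "HE"), c("TH", "BY"),
    c("HE", "BW"), c("HE", "RP"), c("HE", "NW"), c("HE", "BY"),
    c("NW", "RP"), c("RP", "BW"), c("RP", "SL"), c("BW", "BY"))
  region_graph(ids, borders, region_names = names)
}

#' Read / write a region graph as an edge-list CSV
#'
#' The file has columns `region_a,region_b`, one row per undirected border.
#' Isolated regions cannot be represented; every region must appear in at
#' least one edge.
#'
#' @param graph a `region_graph`.
#' @param path file path.
#' @return `write_region_graph` returns `path` invisibly; `read_region_graph`
#'   returns a `region_graph` with regions ordered by first appearance unless
#'   `region_ids` is given.
#' @param region_ids optional explicit region ordering for reading.
#' @export
write_region_graph <- function(graph, path) {
  e <- graph$edges
  utils::write.csv(data.frame(region_a = graph$region_ids[e[, 1]],
                              region_b = graph$region_ids[e[, 2]]),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_region_graph
#' @export
read_region_graph <- function(path, region_ids = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("region_a", "region_b") %in% names(df)))
    stop("edge-list CSV needs columns region_a, region_b")
  ids <- region_ids %||% unique(c(rbind(df$region_a, df$region_b)))
  region_graph(ids, cbind(df$region_a, df$region_b))
}
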