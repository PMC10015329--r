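#' Network objects
#'
#' A `dw_network` is a minimal container for the undirected, unweighted
#' networks the double-well dynamics run on: a symmetric binary adjacency
#' matrix with zero diagonal. Nodes are indexed `1..N` internally; original
#' file labels, when a network is read from disk, are kept in the `labels`
#' attribute.
#'
#' @param adjacency square symmetric 0/1 matrix with zero diagonal, or an
#'   `igraph` object.
#' @param labels optional character vector of original node labels.
#' @return A `dw_network` with elements `adjacency` (integer matrix) and `N`.
#' @examples
#' net <- as_dw_network(rbind(c(0, 1), c(1, 0)))
#' net$N
#' @export
as_dw_network <- function(adjacency, labels = NULL) {
  if (inherits(adjacency, "igraph")) {
    g <- adjacency
    adjacency <- as.matrix(igraph::as_adjacency_matrix(g, type = "both"))
    if (is.null(labels) && !is.null(igraph::V(g)$name))
      labels <- igraph::V(g)$name
  }
  adjacency <- as.matrix(adjacency)
  storage.mode(adjacency) <- "integer"
  n <- nrow(adjacency)
  if (n < 2L) stop("a network needs at least 2 nodes", call. = FALSE)
  if (ncol(adjacency) != n) stop("adjacency must be square", call. = FALSE)
  if (!all(adjacency %in% c(0L, 1L)))
    stop("adjacency entries must be 0 or 1", call. = FALSE)
  if (!isTRUE(all(adjacency == t(adjacency))))
    stop("adjacency must be symmetric", call. = FALSE)
  if (any(diag(adjacency) != 0L))
    stop("adjacency must have a zero diagonal", call. = FALSE)
  dimnames(adjacency) <- NULL
  structure(
    list(adjacency = adjacency, N = n,
         labels = labels %||% as.character(seq_len(n) - 1L)),
    class = "dw_network"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dw_network <- function(x, ...) {
  cat("<dw_network> ", x$N, " nodes, ", sum(x$adjacency) / 2L, " edges\n",
      sep = "")
  invisible(x)
}

#' @rdname as_dw_network
#' @param net a `dw_network`.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "dw_network"))
  g <- igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected")
  igraph::V(g)$name <- net$labels
  g
}

# largest connected component, with node order preserved
largest_component_net <- function(g) {
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    keep <- which(comp$membership == which.max(comp$csize))
    g <- igraph::induced_subgraph(g, keep)
  }
  g
}

#' Generate a configuration-model network with a power-law degree sequence
#'
#' Draws node degrees from a discrete power law `P(k) ~ k^-exponent`
#' truncated to `[min_degree, N - 1]`, wires them with the configuration
#' model, removes self-loops and multi-edges, and keeps the largest
#' connected component (coupling across components is meaningless for the
#' dynamics, so disconnected remainders are dropped; the returned `N` may
#' therefore be smaller than requested).
#'
#' @param N requested node count (>= 2).
#' @param exponent power-law exponent (> 1); default 3.
#' @param min_degree smallest allowed degree (>= 1); default 2.
#' @param seed integer seed; the same seed reproduces the same network.
#' @return A [as_dw_network()] object.
#' @examples
#' net <- generate_powerlaw_config(100, seed = 1)
#' @export
generate_powerlaw_config <- function(N, exponent = 3, min_degree = 2, seed = 1) {
  if (N < 2) stop("N must be at least 2", call. = FALSE)
  if (exponent <= 1) stop("exponent must be > 1", call. = FALSE)
  if (min_degree < 1) stop("min_degree must be >= 1", call. = FALSE)
  set.seed(seed)
  if (N == 2L) return(as_dw_network(rbind(c(0, 1), c(1, 0))))
  ks <- min_degree:(N - 1L)
  pk <- ks^(-exponent)
  pk <- pk / sum(pk)
  repeat {
    deg <- sample(ks, N, replace = TRUE, prob = pk)
    if (sum(deg) %% 2L == 0L) break
  }
  g <- igraph::sample_degseq(deg, method = "configuration")
  g <- igraph::simplify(g)
  g <- largest_component_net(g)
  as_dw_network(g)
}

#' Generate an Erdos-Renyi network
#'
#' `G(N, p)` with `p = mean_degree / (N - 1)`; the largest connected
#' component is returned.
#'
#' @inheritParams generate_powerlaw_config
#' @param mean_degree target mean degree, in `(0, N - 1]`.
#' @return A [as_dw_network()] object.
#' @export
generate_er <- function(N, mean_degree, seed = 1) {
  if (N < 2) stop("N must be at least 2", call. = FALSE)
  p <- mean_degree / (N - 1)
  if (p <= 0 || p > 1)
    stop("mean_degree must give p = mean_degree/(N-1) in (0, 1]", call. = FALSE)
  set.seed(seed)
  g <- igraph::sample_gnp(N, p)
  g <- largest_component_net(g)
  as_dw_network(g)
}

#' Generate a planted-community (stochastic block model) network
#'
#' Equal-size blocks with within-block edge probability `p_in` and
#' between-block probability `p_out < p_in`; the largest connected
#' component is returned.
#'
#' @inheritParams generate_powerlaw_config
#' @param blocks number of equal-size communities (>= 2).
#' @param p_in,p_out within- and between-block edge probabilities.
#' @return A [as_dw_network()] object.
#' @export
generate_planted_communities <- function(N, blocks = 2, p_in = 0.2,
                                         p_out = 0.01, seed = 1) {
  if (N < 2) stop("N must be at least 2", call. = FALSE)
  if (blocks < 2) stop("blocks must be >= 2", call. = FALSE)
  if (!(p_out >= 0 && p_out <= p_in && p_in <= 1))
    stop("need 0 <= p_out <= p_in <= 1 for a planted community structure",
         call. = FALSE)
  set.seed(seed)
  sizes <- rep(N %/% blocks, blocks)
  extra <- N - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  pref <- matrix(p_out, blocks, blocks)
  diag(pref) <- p_in
  g <- igraph::sample_sbm(N, pref.matrix = pref, block.sizes = sizes)
  g <- largest_component_net(g)
  as_dw_network(g)
}

#' Read and write network files
#'
#' Supported formats are a whitespace-separated edge list (one edge per
#' line, `#` comments allowed, arbitrary node labels) and GraphML. Input is
#' coerced to the undirected, simple form the dynamics require: directed
#' edges are symmetrized and duplicate edges and self-loops are dropped with
#' a warning.
#'
#' @param path file path.
#' @param format `"edgelist"` or `"graphml"`; guessed from the file
#'   extension when missing.
#' @return `read_network()` returns a [as_dw_network()] object;
#'   `write_network()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".edgelist")
#' write_network(generate_er(10, 3, seed = 1), f)
#' net <- read_network(f)
#' @export
read_network <- function(path, format = c("auto", "edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE))
      "graphml" else "edgelist"
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L)
      stop("no edges found in ", path, call. = FALSE)
    parts <- strsplit(lines, "[[:space:]]+")
    if (any(lengths(parts) < 2L))
      stop("malformed edge list: each line needs two node labels",
           call. = FALSE)
    el <- t(vapply(parts, function(p) p[1:2], character(2)))
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
  }
  g <- igraph::as_undirected(g, mode = "collapse")
  # canonical node order: numeric labels sort numerically, others lexically
  labs <- igraph::V(g)$name
  if (!is.null(labs)) {
    ord <- if (all(grepl("^-?[0-9]+$", labs))) order(as.numeric(labs))
           else order(labs)
    perm <- integer(length(ord))
    perm[ord] <- seq_along(ord)
    g <- igraph::permute(g, perm)
  }
  n_loops <- sum(igraph::which_loop(g))
  n_multi <- sum(igraph::which_multiple(g))
  if (n_loops + n_multi > 0) {
    warning(sprintf("dropped %d self-loop(s) and %d duplicate edge(s)",
                    n_loops, n_multi), call. = FALSE)
    g <- igraph::simplify(g)
  }
  if (igraph::vcount(g) < 2L)
    stop("network must have at least 2 nodes", call. = FALSE)
  as_dw_network(g)
}

#' @rdname read_network
#' @param net a `dw_network`.
#' @export
write_network <- function(net, path,
                          format = c("auto", "edgelist", "graphml")) {
  stopifnot(inherits(net, "dw_network"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE))
      "graphml" else "edgelist"
  g <- as_igraph(net)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(g, names = TRUE)
    writeLines(paste(el[, 1], el[, 2]), path)
  }
  invisible(path)
}

#' Node degrees of a network
#'
#' @param net a `dw_network`.
#' @return Integer vector of degrees, one per node.
#' @export
network_degrees <- function(net) {
  stopifnot(inherits(net, "dw_network"))
  as.integer(rowSums(net$adjacency))
}
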