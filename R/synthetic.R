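# Synthetic benchmark inputs: random graphs from three classical models,
# rendered as N-Triples with a configurable fraction of nodes represented as
# blank nodes. This emulates the structure used to benchmark the splitter:
# nodes become IRIs <base_iri>node<i> or blank nodes _:bnode<i>, and each
# undirected edge becomes one triple with a distinct predicate
# <base_iri>property<j>.

#' Specification of a synthetic RDF benchmark graph
#'
#' Captures a random-graph model plus the node-labeling parameters used to
#' render it as N-Triples. Defaults follow the standard benchmark settings
#' for each model: Erdős–Rényi edge probability `p = 0.0005`,
#' Watts–Strogatz initial ring degree `d = 2` with rewiring probability
#' `p = 0.5`, Barabási–Albert `n0 = 2` initial nodes with `e = 30` edges per
#' added node, and a blank-node fraction of 0.5.
#'
#' @param model one of `"random"` (Erdős–Rényi G(n, p)),
#'   `"watts_strogatz"`, `"barabasi_albert"`.
#' @param n node count (for `barabasi_albert`: nodes *added* to the `n0`
#'   initial ones).
#' @param p edge probability (random) or rewiring probability
#'   (watts_strogatz); unused for barabasi_albert.
#' @param d initial ring degree for watts_strogatz (total degree; must be
#'   even).
#' @param n0 initial node count for barabasi_albert.
#' @param e edges attached per added node for barabasi_albert.
#' @param blank_ratio fraction of nodes rendered as blank nodes, in
#'   `[0, 1]`.
#' @param seed integer random seed; `NULL` leaves the RNG state alone.
#' @param base_iri namespace for the synthetic node/property IRIs.
#' @return an object of class `synthetic_graph_spec`.
#' @export
synthetic_graph_spec <- function(model = c("random", "watts_strogatz", "barabasi_albert"),
                                 n, p = NULL,
                                 d = 2L, n0 = 2L, e = 30L,
                                 blank_ratio = 0.5, seed = NULL,
                                 base_iri = "http://example.org/experiment/") {
  model <- match.arg(model)
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  if (is.null(p)) p <- if (model == "watts_strogatz") 0.5 else 0.0005
  if (p < 0 || p > 1) stop("p must be in [0, 1]", call. = FALSE)
  if (blank_ratio < 0 || blank_ratio > 1) stop("blank_ratio must be in [0, 1]", call. = FALSE)
  if (d < 1) stop("d must be >= 1", call. = FALSE)
  if (model == "watts_strogatz" && d %% 2 != 0) {
    stop("watts_strogatz requires an even ring degree d", call. = FALSE)
  }
  if (n0 < 1 || e < 1) stop("n0 and e must be >= 1", call. = FALSE)
  if (model == "barabasi_albert" && n < 1) stop("n (added nodes) must be >= 1", call. = FALSE)
  structure(list(model = model, n = as.integer(n), p = p, d = as.integer(d),
                 n0 = as.integer(n0), e = as.integer(e),
                 blank_ratio = blank_ratio, seed = seed, base_iri = base_iri),
            class = "synthetic_graph_spec")
}

#' @export
print.synthetic_graph_spec <- function(x, ...) {
  extra <- switch(x$model,
    random = sprintf("p = %g", x$p),
    watts_strogatz = sprintf("d = %d, p = %g", x$d, x$p),
    barabasi_albert = sprintf("n0 = %d, e = %d", x$n0, x$e))
  cat(sprintf("<synthetic_graph_spec: %s, n = %d, %s, blank_ratio = %g%s>\n",
              x$model, x$n, extra, x$blank_ratio,
              if (is.null(x$seed)) "" else sprintf(", seed = %d", x$seed)))
  invisible(x)
}

# model sampling without touching the seed (callers manage the RNG)
generate_graph_impl <- function(spec) {
  g <- switch(spec$model,
    random = igraph::sample_gnp(spec$n, spec$p),
    watts_strogatz = igraph::sample_smallworld(dim = 1, size = spec$n,
                                               nei = spec$d %/% 2L, p = spec$p,
                                               loops = TRUE, multiple = FALSE),
    barabasi_albert = igraph::sample_pa(
      spec$n0 + spec$n, m = spec$e, directed = FALSE,
      start.graph = igraph::make_empty_graph(spec$n0, directed = FALSE)))
  el <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(el) <- "integer"
  if (spec$model == "watts_strogatz" && nrow(el)) {
    el <- el[el[, 1L] != el[, 2L], , drop = FALSE]   # drop rewiring self-loops
  }
  # undirected edge -> one triple, lower-indexed node as subject
  cbind(u = pmin(el[, 1L], el[, 2L]), v = pmax(el[, 1L], el[, 2L]))
}

#' Generate a random graph
#'
#' Samples an edge list from the model described by `spec`:
#' Erdős–Rényi (each unordered pair present independently with probability
#' `p`), Watts–Strogatz (ring lattice of degree `d`, each edge rewired with
#' probability `p`; self-loops produced by rewiring are discarded), or
#' Barabási–Albert (start from `n0` isolated nodes, add `n` nodes each
#' attaching `e` edges by preferential attachment). Deterministic for a
#' fixed `spec$seed`.
#'
#' @param spec a [synthetic_graph_spec()].
#' @return a two-column integer matrix of node ids (`u <= v`), one row per
#'   edge.
#' @export
generate_graph <- function(spec) {
  stopifnot(inherits(spec, "synthetic_graph_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  generate_graph_impl(spec)
}

# label nodes and render edges as N-Triples rows (RNG left to the caller)
label_graph_impl <- function(edges, blank_ratio, base_iri) {
  nodes <- sort(unique(c(edges[, 1L], edges[, 2L])))   # isolated nodes emit nothing
  n_blank <- round(blank_ratio * length(nodes))
  blank_nodes <- if (n_blank) sample(nodes, n_blank) else integer()
  is_blank <- nodes %in% blank_nodes
  tok <- ifelse(is_blank,
                sprintf("_:bnode%d", nodes),
                sprintf("<%snode%d>", base_iri, nodes))
  lex <- ifelse(is_blank, sprintf("bnode%d", nodes),
                sprintf("%snode%d", base_iri, nodes))
  kind <- ifelse(is_blank, "blank", "iri")
  si <- match(edges[, 1L], nodes)
  oi <- match(edges[, 2L], nodes)
  prop <- sprintf("%sproperty%d", base_iri, seq_len(nrow(edges)))
  new_triple_set(
    subject = lex[si], predicate = prop, object = lex[oi],
    subj_kind = kind[si], obj_kind = kind[oi],
    raw_line = paste(tok[si], sprintf("<%s>", prop), tok[oi], "."))
}

#' Render a graph as N-Triples with blank-node labeling
#'
#' A uniformly random subset of `round(blank_ratio * n_nodes)` nodes is
#' rendered as blank nodes `_:bnode<i>`; the rest become IRIs
#' `<base_iri>node<i>`. Each edge `(u, v)` with `u <= v` becomes one triple
#' `term(u) <base_iri>property<j> term(v) .` with `j` the edge index.
#' Isolated nodes emit no triples.
#'
#' @param edges two-column integer edge matrix as from [generate_graph()].
#' @param blank_ratio fraction of nodes made blank, in `[0, 1]`.
#' @param seed optional seed for the blank-node draw; `NULL` continues the
#'   current RNG stream.
#' @param base_iri namespace for node/property IRIs.
#' @return a `triple_set`, one row per edge.
#' @export
label_graph <- function(edges, blank_ratio, seed = NULL,
                        base_iri = "http://example.org/experiment/") {
  stopifnot(is.matrix(edges), ncol(edges) == 2L)
  if (blank_ratio < 0 || blank_ratio > 1) stop("blank_ratio must be in [0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (!nrow(edges)) return(empty_triple_set())
  label_graph_impl(edges, blank_ratio, base_iri)
}

#' Generate and write a synthetic N-Triples benchmark dataset
#'
#' Samples the graph, labels it (one call to the RNG stream seeded once
#' from `spec$seed`, so the output file is reproducible bit-for-bit) and
#' writes it as N-Triples.
#'
#' @param spec a [synthetic_graph_spec()].
#' @param path destination file.
#' @return an object of class `dataset_summary`: triple count, node/blank
#'   counts and the b2/b1/plain class breakdown (b2 = both subject and
#'   object blank, b1 = exactly one blank, plain = none).
#' @examples
#' spec <- synthetic_graph_spec("random", n = 100, p = 0.1,
#'                              blank_ratio = 0.5, seed = 7)
#' f <- tempfile(fileext = ".nt")
#' make_dataset(spec, f)
#' @export
make_dataset <- function(spec, path) {
  stopifnot(inherits(spec, "synthetic_graph_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  edges <- generate_graph_impl(spec)
  ts <- if (nrow(edges)) label_graph_impl(edges, spec$blank_ratio, spec$base_iri)
        else empty_triple_set()
  write_ntriples(ts, path)
  cls <- classify_triples(ts)
  blanks <- unique(c(ts$subject[ts$subj_kind == "blank"],
                     ts$object[ts$obj_kind == "blank"]))
  structure(list(path = path,
                 triples = nrow(ts),
                 nodes = length(unique(c(edges[, 1L], edges[, 2L]))),
                 blank_nodes = length(blanks),
                 b2 = sum(cls == "b2"), b1 = sum(cls == "b1"),
                 plain = sum(cls == "plain"),
                 spec = spec),
            class = "dataset_summary")
}

#' @export
print.dataset_summary <- function(x, ...) {
  cat(sprintf("<dataset_summary: %s>\n", x$path))
  cat(sprintf("  %d triples over %d nodes (%d blank); classes: b2 = %d, b1 = %d, plain = %d\n",
              x$triples, x$nodes, x$blank_nodes, x$b2, x$b1, x$plain))
  invisible(x)
}
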