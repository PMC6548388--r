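# Grouping stage: partition the input triples into minimal groups such that
# identical blank nodes never cross group boundaries.
#
# Triples are classed b2 (subject and object both blank), b1 (exactly one of
# subject/object blank) or plain (no blank). Blank labels linked by b2
# triples are merged by union-find; b1 labels are folded into the same
# union-find (a label with no b2 edge forms its own component), which makes
# the resulting partition independent of triple order. Plain triples become
# singleton groups.

#' Classify triples by blank-node content
#'
#' @param x a `triple_set`.
#' @return character vector, one of `"b2"` (subject and object both blank
#'   nodes), `"b1"` (exactly one of subject/object blank), `"plain"`
#'   (neither blank). The predicate is always an IRI and is ignored.
#' @examples
#' f <- tempfile(fileext = ".nt")
#' writeLines(c("_:a <http://ex/p> _:b .",
#'              "_:a <http://ex/p> \"lit\" .",
#'              "<http://ex/s> <http://ex/p> \"lit\" ."), f)
#' classify_triples(read_ntriples(f))
#' @export
classify_triples <- function(x) {
  sb <- x$subj_kind == "blank"
  ob <- x$obj_kind == "blank"
  ifelse(sb & ob, "b2", ifelse(sb | ob, "b1", "plain"))
}

# blank label of each b1 triple (exactly one of subject/object is blank)
b1_label <- function(x) {
  ifelse(x$subj_kind == "blank", x$subject, x$object)
}

# union-find over a label universe; returns dense component ids 1..k in
# order of first appearance in `labels`
dense_components <- function(labels, edge_a, edge_b) {
  if (!length(labels)) return(integer())
  ia <- match(edge_a, labels)
  ib <- match(edge_b, labels)
  root <- uf_components(as.integer(ia), as.integer(ib), length(labels))
  match(root, unique(root))
}

#' Connected components of blank nodes linked by both-blank triples
#'
#' Builds the undirected graph whose vertices are the blank labels occurring
#' in `x` and whose edges are the (subject, object) pairs of each triple,
#' and computes its connected components with union-find (union by size,
#' path compression). Self-loops (subject = object) are allowed and form a
#' one-node component unless joined by other edges.
#'
#' @param x a `triple_set` in which every triple has a blank subject and a
#'   blank object (class `"b2"`); anything else is a contract violation.
#' @return an object of class `blank_components`: a list with
#'   `component_of` (named integer vector mapping blank label to a dense
#'   component id `1..k`) and `component_count`.
#' @export
blank_components <- function(x) {
  cls <- classify_triples(x)
  if (any(cls != "b2")) {
    stop("blank_components() requires triples with both subject and object blank; ",
         sum(cls != "b2"), " other triple(s) found", call. = FALSE)
  }
  labels <- unique(c(x$subject, x$object))
  comp <- dense_components(labels, x$subject, x$object)
  structure(list(component_of = setNames(comp, labels),
                 component_count = if (length(comp)) max(comp) else 0L),
            class = "blank_components")
}

#' @export
print.blank_components <- function(x, ...) {
  cat(sprintf("<blank_components: %d blank label%s in %d component%s>\n",
              length(x$component_of), if (length(x$component_of) == 1L) "" else "s",
              x$component_count, if (x$component_count == 1L) "" else "s"))
  invisible(x)
}

#' Partition triples into minimal blank-node-consistent groups
#'
#' Computes the finest partition of the input triples such that all triples
#' mentioning the same blank node fall in the same group: blank labels
#' joined by both-blank (`b2`) triples are merged into connected
#' components; each one-blank (`b1`) triple joins the component of its
#' blank label (creating a fresh component when the label is new); each
#' plain triple forms its own singleton group. The result does not depend
#' on triple order (up to group renumbering): groups are numbered by first
#' appearance of their blank labels, then by stream position for plain
#' singletons.
#'
#' @param x a `triple_set` (the full input stream).
#' @return an object of class `group_partition`: a list with
#'   \describe{
#'     \item{group}{integer vector, group id of each triple (by row).}
#'     \item{n_groups}{total number of groups.}
#'     \item{n_blank_groups}{number of groups containing blank nodes
#'       (ids `1..n_blank_groups`); the remaining ids are plain singletons.}
#'     \item{group_sizes}{integer vector of triple counts per group id.}
#'     \item{group_blanks}{list of character vectors: the blank labels of
#'       each blank-containing group (plain singleton groups have empty
#'       blank sets and are not listed).}
#'     \item{classes}{the per-triple class from [classify_triples()].}
#'   }
#' @examples
#' f <- tempfile(fileext = ".nt")
#' writeLines(c("_:a <http://ex/p> _:b .",
#'              "_:b <http://ex/p> _:c .",
#'              "_:d <http://ex/p> _:e .",
#'              "<http://ex/s1> <http://ex/p> _:a .",
#'              "<http://ex/s2> <http://ex/p> <http://ex/o2> ."), f)
#' build_partition(read_ntriples(f))
#' @export
build_partition <- function(x) {
  cls <- classify_triples(x)
  b2 <- cls == "b2"
  b1 <- cls == "b1"
  plain <- cls == "plain"
  b1lab <- b1_label(x[b1, , drop = FALSE])
  labels <- unique(c(x$subject[b2], x$object[b2], b1lab))
  comp <- dense_components(labels, x$subject[b2], x$object[b2])
  k <- if (length(comp)) max(comp) else 0L

  group <- integer(nrow(x))
  group[b2] <- comp[match(x$subject[b2], labels)]
  group[b1] <- comp[match(b1lab, labels)]
  group[plain] <- k + seq_len(sum(plain))
  n_groups <- k + sum(plain)

  structure(list(group = group,
                 n_groups = n_groups,
                 n_blank_groups = k,
                 group_sizes = tabulate(group, nbins = n_groups),
                 group_blanks = if (k) unname(split(labels, comp)) else list(),
                 classes = cls),
            class = "group_partition")
}

#' @export
print.group_partition <- function(x, ...) {
  cat(sprintf("<group_partition: %d triples in %d groups (%d with blank nodes, %d plain singletons)>\n",
              length(x$group), x$n_groups, x$n_blank_groups,
              x$n_groups - x$n_blank_groups))
  if (x$n_blank_groups) {
    sz <- sort(x$group_sizes[seq_len(x$n_blank_groups)], decreasing = TRUE)
    cat("  largest blank group:", sz[1L], "triples\n")
  }
  invisible(x)
}
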