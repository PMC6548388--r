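# Verification: certify that split outputs are consistent with the original
# file without loading anything into a triple store. The workhorse is the
# blank-node profile — the multiset of per-blank-node triple counts in
# subject and in object position (what SPARQL `count(*) ... FILTER
# (isBlank(?s))` grouped by node would return). Profiles are label-free, so
# they survive the label rewriting every loader performs. On small
# instances an exact blank-node bijection (RDF isomorphism restricted to
# blank relabeling) is available.

as_triple_set <- function(x) {
  if (inherits(x, "triple_set")) x
  else if (is.character(x) && length(x) == 1L) read_ntriples(x)
  else stop("expected a file path or a triple_set", call. = FALSE)
}

as_triple_set_list <- function(x) {
  if (inherits(x, "triple_set")) return(list(x))
  if (is.character(x)) return(lapply(x, read_ntriples))
  if (is.list(x)) return(lapply(x, as_triple_set))
  stop("expected file path(s) or triple_set(s)", call. = FALSE)
}

profile_one <- function(ts) {
  list(subject = as.integer(table(ts$subject[ts$subj_kind == "blank"])),
       object = as.integer(table(ts$object[ts$obj_kind == "blank"])))
}

#' Blank-node triple-count profile
#'
#' For every blank node, counts the triples in which it occurs as subject
#' and as object, and returns the two count multisets sorted in decreasing
#' order. When several files (or triple sets) are given, blank labels are
#' scoped per file — label `b1` in file A and `b1` in file B are distinct
#' nodes — mirroring the semantics of loading the files independently into
#' a store. Equal profiles are a necessary condition for the loaded graphs
#' to be isomorphic.
#'
#' @param x a file path, a vector of file paths, a `triple_set`, or a list
#'   of `triple_set`s.
#' @return an object of class `blank_profile`: a list with integer vectors
#'   `subject_counts` and `object_counts`, each sorted decreasingly.
#' @examples
#' f <- tempfile(fileext = ".nt")
#' writeLines(c("_:a <http://ex/p> <http://ex/o1> .",
#'              "_:a <http://ex/p> <http://ex/o2> .",
#'              "<http://ex/s> <http://ex/p> _:a ."), f)
#' blank_profile(f)  # subject_counts 2, object_counts 1
#' @export
blank_profile <- function(x) {
  parts <- lapply(as_triple_set_list(x), profile_one)
  structure(list(
    subject_counts = sort(unlist(lapply(parts, `[[`, "subject"), use.names = FALSE),
                          decreasing = TRUE),
    object_counts = sort(unlist(lapply(parts, `[[`, "object"), use.names = FALSE),
                         decreasing = TRUE)),
    class = "blank_profile")
}

#' @export
print.blank_profile <- function(x, ...) {
  fmt <- function(v) {
    if (!length(v)) return("(none)")
    paste0(paste(head(v, 10L), collapse = " "),
           if (length(v) > 10L) sprintf(" ... (%d nodes)", length(v)) else "")
  }
  cat("<blank_profile>\n")
  cat("  subject counts:", fmt(x$subject_counts), "\n")
  cat("  object counts: ", fmt(x$object_counts), "\n")
  invisible(x)
}

#' Compare two blank-node profiles
#'
#' @param a,b `blank_profile` objects.
#' @return `TRUE` iff both count multisets are identical.
#' @export
profiles_match <- function(a, b) {
  stopifnot(inherits(a, "blank_profile"), inherits(b, "blank_profile"))
  identical(a$subject_counts, b$subject_counts) &&
    identical(a$object_counts, b$object_counts)
}

# canonical token rendering from parsed fields (raw lines are unusable when
# comparing across files that may have rewritten whitespace or labels)
render_term <- function(lex, kind, blank_as = NULL) {
  out <- lex
  out[kind == "iri"] <- sprintf("<%s>", lex[kind == "iri"])
  if (is.null(blank_as)) {
    out[kind == "blank"] <- sprintf("_:%s", lex[kind == "blank"])
  } else {
    out[kind == "blank"] <- sprintf("_:%s", blank_as[lex[kind == "blank"]])
  }
  out
}

render_triples <- function(ts, blank_as = NULL) {
  paste(render_term(ts$subject, ts$subj_kind, blank_as),
        sprintf("<%s>", ts$predicate),
        render_term(ts$object, ts$obj_kind, blank_as))
}

# triples rendered with every blank label masked: invariant under relabeling
masked_lines <- function(ts) {
  sub_mask <- ifelse(ts$subj_kind == "blank", "_:*",
                     render_term(ts$subject, ts$subj_kind))
  obj_mask <- ifelse(ts$obj_kind == "blank", "_:*",
                     render_term(ts$object, ts$obj_kind))
  paste(sub_mask, sprintf("<%s>", ts$predicate), obj_mask)
}

#' Check that split files conserve the original file's content
#'
#' Passes iff (a) the split files together contain exactly as many triples
#' as the original, (b) the multiset of blank-free lines is identical, (c)
#' the multiset of blank-containing triples is identical once blank labels
#' are masked, and (d) the blank-node profiles (see [blank_profile()], with
#' per-file label scoping on the split side) agree. These are the
#' observable consequences of a correct blank-node-consistent split; any
#' lost, duplicated or blank-node-splitting output fails at least one.
#'
#' @param original path (or `triple_set`) of the original file.
#' @param splits paths (or list of `triple_set`s) of the split files.
#' @return an object of class `conservation_report`: a list with `pass`
#'   (logical) and `checks` (data frame enumerating each check and any
#'   discrepancy found).
#' @export
check_conservation <- function(original, splits) {
  orig <- as_triple_set(original)
  spl <- as_triple_set_list(splits)
  all_spl <- if (length(spl)) do.call(rbind, spl) else empty_triple_set()

  checks <- list()
  add <- function(name, pass, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = name, pass = pass, detail = detail, stringsAsFactors = FALSE)
  }

  add("triple count",
      nrow(orig) == nrow(all_spl),
      sprintf("original %d vs splits %d", nrow(orig), nrow(all_spl)))

  ocls <- classify_triples(orig)
  scls <- if (nrow(all_spl)) classify_triples(all_spl) else character()
  oplain <- sort(orig$raw_line[ocls == "plain"])
  splain <- sort(all_spl$raw_line[scls == "plain"])
  plain_ok <- identical(oplain, splain)
  detail <- ""
  if (!plain_ok) {
    miss <- setdiff(oplain, splain)
    extra <- setdiff(splain, oplain)
    detail <- paste0(
      if (length(miss)) paste0("missing: ", head(miss, 1L)) else "",
      if (length(miss) && length(extra)) "; " else "",
      if (length(extra)) paste0("unexpected: ", head(extra, 1L)) else "")
    if (detail == "") detail <- "multiplicities differ"
  }
  add("blank-free lines (multiset)", plain_ok, detail)

  omask <- sort(masked_lines(orig[ocls != "plain", , drop = FALSE]))
  smask <- sort(masked_lines(all_spl[scls != "plain", , drop = FALSE]))
  mask_ok <- identical(omask, smask)
  detail <- ""
  if (!mask_ok) {
    miss <- setdiff(omask, smask)
    detail <- if (length(miss)) paste0("missing pattern: ", head(miss, 1L))
              else "multiplicities differ"
  }
  add("blank-containing triples (label-masked multiset)", mask_ok, detail)

  po <- blank_profile(orig)
  ps <- blank_profile(spl)
  prof_ok <- profiles_match(po, ps)
  add("blank-node profiles", prof_ok,
      if (prof_ok) "" else sprintf(
        "original %d blank subject nodes / %d object nodes vs splits %d / %d",
        length(po$subject_counts), length(po$object_counts),
        length(ps$subject_counts), length(ps$object_counts)))

  checks <- do.call(rbind, checks)
  structure(list(pass = all(checks$pass), checks = checks,
                 original_profile = po, split_profile = ps),
            class = "conservation_report")
}

#' @export
print.conservation_report <- function(x, ...) {
  cat(sprintf("<conservation_report: %s>\n", if (x$pass) "PASS" else "FAIL"))
  for (i in seq_len(nrow(x$checks))) {
    cat(sprintf("  [%s] %s%s\n",
                if (x$checks$pass[i]) "ok" else "FAIL",
                x$checks$check[i],
                if (!x$checks$pass[i] && nzchar(x$checks$detail[i]))
                  paste0(" — ", x$checks$detail[i]) else ""))
  }
  invisible(x)
}

# per-blank-label signature: incident triples with this label rendered "@",
# any other blank rendered "?" — invariant under any blank relabeling
blank_signatures <- function(ts, scope = "") {
  sb <- ts$subj_kind == "blank"
  ob <- ts$obj_kind == "blank"
  labs <- unique(c(ts$subject[sb], ts$object[ob]))
  sigs <- lapply(labs, function(b) {
    hit <- (sb & ts$subject == b) | (ob & ts$object == b)
    tt <- ts[hit, , drop = FALSE]
    stok <- ifelse(tt$subj_kind == "blank", ifelse(tt$subject == b, "@", "?"),
                   render_term(tt$subject, tt$subj_kind))
    otok <- ifelse(tt$obj_kind == "blank", ifelse(tt$object == b, "@", "?"),
                   render_term(tt$object, tt$obj_kind))
    sort(paste(stok, sprintf("<%s>", tt$predicate), otok))
  })
  names(sigs) <- if (length(labs)) paste0(scope, labs) else character(0)
  sigs
}

#' Exact blank-node bijection (isomorphism) check for small instances
#'
#' Decides whether a bijection exists between the original file's blank
#' nodes and the (file, label)-scoped blank nodes of the split files that
#' makes the triple multisets equal — RDF isomorphism, given that IRIs and
#' literals carry their own identity. General graph isomorphism is
#' intractable, so the search (backtracking over signature-compatible
#' candidates) refuses instances with more than `max_blanks` distinct blank
#' labels; use [blank_profile()] comparison beyond that.
#'
#' @inheritParams check_conservation
#' @param max_blanks refuse instances with more original blank labels than
#'   this.
#' @return `TRUE` or `FALSE`; the witness bijection (a named character
#'   vector) is attached as attribute `"mapping"` on success.
#' @export
check_isomorphic <- function(original, splits, max_blanks = 20L) {
  orig <- as_triple_set(original)
  spl <- as_triple_set_list(splits)

  ocls <- classify_triples(orig)
  ob_labs <- unique(c(orig$subject[orig$subj_kind == "blank"],
                      orig$object[orig$obj_kind == "blank"]))
  if (length(ob_labs) > max_blanks) {
    stop(sprintf("instance too large for exact isomorphism (%d blank labels > %d); compare blank_profile()s instead",
                 length(ob_labs), max_blanks), call. = FALSE)
  }

  # scope split blank labels per file and pool the files
  scoped <- lapply(seq_along(spl), function(i) {
    ts <- spl[[i]]
    pre <- sprintf("f%d\r", i)               # \r cannot occur inside a label
    ts$subject[ts$subj_kind == "blank"] <- paste0(pre, ts$subject[ts$subj_kind == "blank"])
    ts$object[ts$obj_kind == "blank"] <- paste0(pre, ts$object[ts$obj_kind == "blank"])
    ts
  })
  all_spl <- if (length(scoped)) do.call(rbind, scoped) else empty_triple_set()
  scls <- if (nrow(all_spl)) classify_triples(all_spl) else character()

  # blank-free triples must agree outright
  if (!identical(sort(render_triples(orig[ocls == "plain", , drop = FALSE])),
                 sort(render_triples(all_spl[scls == "plain", , drop = FALSE])))) {
    return(FALSE)
  }

  osig <- blank_signatures(orig)
  ssig <- blank_signatures(all_spl)
  if (length(osig) != length(ssig)) return(FALSE)
  if (!length(osig)) return(structure(TRUE, mapping = character()))

  cand <- lapply(osig, function(sg) {
    names(ssig)[vapply(ssig, identical, logical(1), sg)]
  })
  if (any(lengths(cand) == 0L)) return(FALSE)

  ob <- orig[ocls != "plain", , drop = FALSE]
  target <- sort(render_triples(all_spl[scls != "plain", , drop = FALSE]))
  ord <- order(lengths(cand))                # most constrained labels first
  labs <- names(osig)[ord]
  cand <- cand[ord]

  assigned <- character(0)
  search <- function(i, map) {
    if (i > length(labs)) {
      got <- sort(render_triples(ob, blank_as = setNames(map, labs)))
      return(if (identical(got, target)) map else NULL)
    }
    for (c_ in setdiff(cand[[i]], map)) {
      res <- search(i + 1L, c(map, c_))
      if (!is.null(res)) return(res)
    }
    NULL
  }
  map <- search(1L, character(0))
  if (is.null(map)) return(FALSE)
  structure(TRUE, mapping = setNames(map, labs))
}
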