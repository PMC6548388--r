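# N-Triples reader/writer. Lines are carried verbatim (raw_line) and re-emitted
# unchanged: the splitter never re-serializes terms, so split files concatenate
# back to the exact input lines. Literal internals are validated only enough to
# delimit the term; their content is opaque to the splitter.

.re_iri <- "<[^<>\\s]*>"
.re_blank <- "_:\\S+?"
.re_literal <- "\"(?:[^\"\\\\]|\\\\.)*\"(?:\\^\\^<[^<>\\s]*>|@[A-Za-z][A-Za-z0-9-]*(?:-[A-Za-z0-9]+)*)?"
.re_triple <- sprintf("^\\s*(%s|%s)\\s+(%s)\\s+(%s|%s|%s)\\s*\\.\\s*$",
                      .re_iri, .re_blank, .re_iri,
                      .re_iri, .re_blank, .re_literal)
.re_skip <- "^\\s*(#|$)"

new_triple_set <- function(subject, predicate, object, subj_kind, obj_kind, raw_line) {
  structure(
    data.frame(subject = subject, predicate = predicate, object = object,
               subj_kind = subj_kind, obj_kind = obj_kind, raw_line = raw_line,
               stringsAsFactors = FALSE),
    class = c("triple_set", "data.frame"))
}

empty_triple_set <- function() {
  new_triple_set(character(), character(), character(),
                 character(), character(), character())
}

term_kind_of <- function(tok) {
  ifelse(startsWith(tok, "<"), "iri",
         ifelse(startsWith(tok, "_:"), "blank", "literal"))
}

term_lex_of <- function(tok, kind) {
  out <- tok
  iri <- kind == "iri"
  out[iri] <- substr(tok[iri], 2L, nchar(tok[iri]) - 1L)
  bl <- kind == "blank"
  out[bl] <- substr(tok[bl], 3L, nchar(tok[bl]))
  out                                       # literals keep the full token
}

# Vectorized core: parse a character vector of physical lines.
# Returns list(records = triple_set, n_skipped), or raises on malformed lines.
parse_ntriples_lines <- function(lines, line_offset = 0L) {
  lines <- sub("\r$", "", lines)            # accept CRLF, normalize to LF
  skip <- grepl(.re_skip, lines, perl = TRUE)
  body <- lines[!skip]
  if (!length(body)) {
    return(list(records = empty_triple_set(), n_skipped = sum(skip)))
  }
  ok <- grepl(.re_triple, body, perl = TRUE)
  if (!all(ok)) {
    bad <- which(!skip)[!ok]
    msg <- paste0("line ", line_offset + bad, ": ",
                  substr(lines[bad], 1L, 120L))
    stop("malformed N-Triples line(s):\n  ",
         paste(head(msg, 5L), collapse = "\n  "),
         if (length(msg) > 5L) sprintf("\n  ... and %d more", length(msg) - 5L),
         call. = FALSE)
  }
  s_tok <- sub(.re_triple, "\\1", body, perl = TRUE)
  p_tok <- sub(.re_triple, "\\2", body, perl = TRUE)
  o_tok <- sub(.re_triple, "\\3", body, perl = TRUE)
  s_kind <- term_kind_of(s_tok)
  o_kind <- term_kind_of(o_tok)
  list(records = new_triple_set(
         subject = term_lex_of(s_tok, s_kind),
         predicate = substr(p_tok, 2L, nchar(p_tok) - 1L),
         object = term_lex_of(o_tok, o_kind),
         subj_kind = s_kind, obj_kind = o_kind,
         raw_line = body),
       n_skipped = sum(skip))
}

#' Parse a single N-Triples line
#'
#' Parses one physical line of an N-Triples document into a one-row
#' [triple_set]. Blank lines and comment lines (first non-whitespace
#' character `#`) are skip lines and yield `NULL`. The original line (with
#' any trailing `\r` stripped) is retained in the `raw_line` column so it
#' can be re-emitted byte-exactly.
#'
#' @param line a single character string, one physical line.
#' @param line_number line number used in error messages.
#' @return a one-row `triple_set` data frame, or `NULL` for a skip line.
#'   Columns: `subject`, `predicate`, `object` (lexical forms: IRIs without
#'   angle brackets, blank labels without `_:`, literals as the full token
#'   including quotes and any datatype/language suffix), `subj_kind`,
#'   `obj_kind` (`"iri"`, `"blank"` or `"literal"`), `raw_line`.
#' @examples
#' parse_ntriple_line('<http://ex/s> <http://ex/p> "v"@en .')
#' parse_ntriple_line("# a comment")
#' @export
parse_ntriple_line <- function(line, line_number = 1L) {
  stopifnot(is.character(line), length(line) == 1L)
  res <- parse_ntriples_lines(line, line_offset = line_number - 1L)
  if (nrow(res$records) == 0L) NULL else res$records
}

#' Stream an N-Triples file in chunks
#'
#' Reads `path` in chunks of `chunk_size` lines, parses each chunk and calls
#' `fun(records, chunk_info)` with a [triple_set] of the chunk's triples.
#' Memory use is bounded by the chunk size, independent of file size; skip
#' lines (comments, blank lines) are counted but never passed to `fun`.
#'
#' @param path path to an N-Triples file.
#' @param fun function of one or two arguments: the chunk's `triple_set`
#'   and (optionally) a list with `first_line` and `n_skipped_so_far`.
#' @param chunk_size number of physical lines per chunk.
#' @return invisibly, a list with `n_triples` and `n_skipped` totals.
#' @seealso [read_ntriples()] to materialize a whole file.
#' @export
nt_chunk_apply <- function(path, fun, chunk_size = 200000L) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  con <- file(path, open = "rb")
  on.exit(close(con), add = TRUE)
  n_triples <- 0L
  n_skipped <- 0L
  first_line <- 1L
  use2 <- length(formals(fun)) >= 2L
  repeat {
    lines <- readLines(con, n = chunk_size, warn = FALSE)
    if (!length(lines)) break
    res <- parse_ntriples_lines(lines, line_offset = first_line - 1L)
    if (use2) {
      fun(res$records, list(first_line = first_line, n_skipped_so_far = n_skipped))
    } else {
      fun(res$records)
    }
    n_triples <- n_triples + nrow(res$records)
    n_skipped <- n_skipped + res$n_skipped
    first_line <- first_line + length(lines)
  }
  invisible(list(n_triples = n_triples, n_skipped = n_skipped))
}

#' Read an N-Triples file
#'
#' Parses a whole N-Triples file into a [triple_set] data frame, one row per
#' triple, in file order. Comment and blank lines are dropped (their count
#' is available as `attr(x, "n_skipped")`).
#'
#' @inheritParams nt_chunk_apply
#' @return a `triple_set` data frame (see [parse_ntriple_line()] for the
#'   columns).
#' @examples
#' f <- tempfile(fileext = ".nt")
#' writeLines(c("_:b1 <http://ex/p> _:b2 .",
#'              "<http://ex/s> <http://ex/p> \"v\" ."), f)
#' read_ntriples(f)
#' @export
read_ntriples <- function(path, chunk_size = 200000L) {
  chunks <- list()
  i <- 0L
  tot <- nt_chunk_apply(path, function(recs) {
    i <<- i + 1L
    chunks[[i]] <<- recs
  }, chunk_size = chunk_size)
  out <- if (i == 0L) empty_triple_set()
         else if (i == 1L) chunks[[1L]]
         else structure(do.call(rbind, chunks), class = c("triple_set", "data.frame"))
  rownames(out) <- NULL
  attr(out, "n_skipped") <- tot$n_skipped
  out
}

#' Write triples to an N-Triples file
#'
#' Emits each record's original source line (`raw_line`) followed by a
#' single `\n`; terms are never re-serialized, so writing the result of
#' [read_ntriples()] reproduces the input file byte-for-byte (modulo
#' dropped comment lines and terminator normalization).
#'
#' @param x a `triple_set` (or any data frame with a `raw_line` column).
#' @param path destination path.
#' @return invisibly, the number of lines written.
#' @export
write_ntriples <- function(x, path) {
  stopifnot(!is.null(x$raw_line))
  con <- NULL
  tryCatch({
    con <- file(path, open = "wb")
    if (nrow(x)) writeLines(x$raw_line, con, useBytes = TRUE)
    close(con)
    con <- NULL
  }, error = function(e) {
    if (!is.null(con)) try(close(con), silent = TRUE)
    try(unlink(path), silent = TRUE)        # do not leave a partial file
    stop("failed writing ", path, ": ", conditionMessage(e), call. = FALSE)
  })
  invisible(nrow(x))
}

#' @export
print.triple_set <- function(x, ...) {
  cat(sprintf("<triple_set: %d triple%s>\n", nrow(x), if (nrow(x) == 1L) "" else "s"))
  if (nrow(x)) {
    show <- utils::head(x$raw_line, 6L)
    cat(paste0("  ", show), sep = "\n")
    if (nrow(x) > 6L) cat(sprintf("  ... and %d more\n", nrow(x) - 6L))
  }
  invisible(x)
}
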