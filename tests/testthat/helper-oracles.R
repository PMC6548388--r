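# Independent oracles. These deliberately use different algorithms and data
# paths than the package (character-walk parsing, boolean-matrix transitive
# closure, plain enumeration) so that agreement is evidence, not tautology.

# --- reference N-Triples line parser: single-character walk ----------------
# Returns list(kinds, lexs) for a triple line, the string "skip" for
# blank/comment lines, or the string "error".
ref_parse_line <- function(line) {
  line <- sub("\r$", "", line)
  chars <- strsplit(line, "", fixed = TRUE)[[1]]
  n <- length(chars)
  i <- 1L
  ws <- function() while (i <= n && chars[i] %in% c(" ", "\t")) i <<- i + 1L
  ws()
  if (i > n || chars[i] == "#") return("skip")
  read_iri <- function() {
    start <- i; i <<- i + 1L
    while (i <= n && !chars[i] %in% c(">", "<", " ", "\t")) i <<- i + 1L
    if (i > n || chars[i] != ">") return(NULL)
    i <<- i + 1L
    paste(chars[(start + 1L):(i - 2L)], collapse = "")
  }
  read_blank <- function() {
    i <<- i + 2L
    start <- i
    while (i <= n && !chars[i] %in% c(" ", "\t")) i <<- i + 1L
    lab <- if (i > start) paste(chars[start:(i - 1L)], collapse = "") else NULL
    lab
  }
  read_literal <- function() {
    start <- i; i <<- i + 1L
    repeat {
      if (i > n) return(NULL)
      if (chars[i] == "\\") { i <<- i + 2L; next }
      if (chars[i] == "\"") { i <<- i + 1L; break }
      i <<- i + 1L
    }
    if (i <= n && chars[i] == "@") {
      i <<- i + 1L
      while (i <= n && grepl("[A-Za-z0-9-]", chars[i])) i <<- i + 1L
    } else if (i + 1L <= n && chars[i] == "^" && chars[i + 1L] == "^") {
      i <<- i + 2L
      if (i > n || chars[i] != "<") return(NULL)
      if (is.null(read_iri())) return(NULL)
    }
    paste(chars[start:(i - 1L)], collapse = "")
  }
  read_term <- function(allowed) {
    if (i > n) return(NULL)
    if (chars[i] == "<" && "iri" %in% allowed) {
      v <- read_iri(); if (is.null(v)) return(NULL)
      list(kind = "iri", lex = v)
    } else if (i + 1L <= n && chars[i] == "_" && chars[i + 1L] == ":" &&
               "blank" %in% allowed) {
      v <- read_blank(); if (is.null(v)) return(NULL)
      # a trailing "." before end-of-statement belongs to the terminator
      list(kind = "blank", lex = v)
    } else if (chars[i] == "\"" && "literal" %in% allowed) {
      v <- read_literal(); if (is.null(v)) return(NULL)
      list(kind = "literal", lex = v)
    } else NULL
  }
  s <- read_term(c("iri", "blank")); if (is.null(s)) return("error")
  ws()
  p <- read_term("iri"); if (is.null(p)) return("error")
  ws()
  o <- read_term(c("iri", "blank", "literal")); if (is.null(o)) return("error")
  # object blank labels may have swallowed the terminator characters
  if (o$kind == "blank") {
    stripped <- sub("\\.$", "", o$lex)
    if (stripped != o$lex && i > n) { o$lex <- stripped; i <- n }  # "_:b." form
  }
  ws()
  if (o$kind == "blank" && i > n) return("error")
  if (i > n || chars[i] != ".") return("error")
  i <- i + 1L
  ws()
  if (i <= n) return("error")
  list(kinds = c(s$kind, p$kind, o$kind), lexs = c(s$lex, p$lex, o$lex))
}

# --- transitive-closure connectivity oracle --------------------------------
# components of an undirected graph given as label pairs, via boolean matrix
# closure over the label universe
closure_components <- function(labels, a, b) {
  k <- length(labels)
  if (!k) return(integer())
  M <- diag(1, k)
  ia <- match(a, labels); ib <- match(b, labels)
  for (e in seq_along(ia)) { M[ia[e], ib[e]] <- 1; M[ib[e], ia[e]] <- 1 }
  repeat {
    M2 <- ((M %*% M) > 0) * 1
    if (identical(M2, M)) break
    M <- M2
  }
  match(apply(M, 1, paste, collapse = ""), unique(apply(M, 1, paste, collapse = "")))
}

# groups of a triple set as equivalence classes of the reflexive-transitive
# closure of "shares a blank label", plain triples as singletons
oracle_grouping <- function(ts) {
  n <- nrow(ts)
  labs <- lapply(seq_len(n), function(i) {
    c(if (ts$subj_kind[i] == "blank") ts$subject[i],
      if (ts$obj_kind[i] == "blank") ts$object[i])
  })
  M <- diag(1, n)
  for (i in seq_len(n)) {
    if (i < n) for (j in (i + 1L):n) {
      if (length(intersect(labs[[i]], labs[[j]]))) { M[i, j] <- 1; M[j, i] <- 1 }
    }
  }
  repeat {
    M2 <- ((M %*% M) > 0) * 1
    if (identical(M2, M)) break
    M <- M2
  }
  key <- apply(M, 1, paste, collapse = "")
  match(key, unique(key))
}

# canonical form of a partition (vector of group ids) for comparison:
# list of member-index sets, sorted by smallest member
canon_partition <- function(ids) {
  parts <- unname(split(seq_along(ids), ids))
  parts <- lapply(parts, sort)
  parts[order(vapply(parts, `[`, integer(1), 1L))]
}

# --- scheduling oracles -----------------------------------------------------
# exact minimum makespan by plain enumeration of all m^n assignments
enum_makespan <- function(sizes, m) {
  n <- length(sizes)
  grid <- do.call(expand.grid, rep(list(seq_len(m)), n))
  best <- sum(sizes)
  for (r in seq_len(nrow(grid))) {
    asg <- as.integer(grid[r, ])
    loads <- vapply(seq_len(m), function(j) sum(sizes[asg == j]), numeric(1))
    best <- min(best, max(loads))
  }
  best
}

# sequential unit-job distribution: add `count` size-1 jobs one at a time to
# the currently smallest bin (ties to the lowest index)
unit_fill_loop <- function(bin_sizes, count) {
  for (i in seq_len(count)) {
    j <- which.min(bin_sizes)
    bin_sizes[j] <- bin_sizes[j] + 1
  }
  bin_sizes
}

# all multisets of `len` values drawn from `values` (non-decreasing tuples)
size_multisets <- function(len, values) {
  if (len == 1L) return(as.list(values))
  out <- list()
  rec <- function(prefix, lo) {
    if (length(prefix) == len) { out[[length(out) + 1L]] <<- prefix; return() }
    for (v in values[values >= lo]) rec(c(prefix, v), v)
  }
  rec(numeric(0), min(values))
  out
}

# --- random fixture builders ------------------------------------------------
# random triple set over a small blank-label pool, covering b2/b1/plain mixes
random_triple_set <- function(n_triples, n_labels = 8L,
                              p_class = c(b2 = 0.3, b1 = 0.4, plain = 0.3)) {
  pool <- sprintf("b%d", seq_len(n_labels))
  cls <- sample(names(p_class), n_triples, replace = TRUE, prob = p_class)
  term <- function(kind) {
    switch(kind,
           blank = paste0("_:", sample(pool, 1L)),
           iri = sprintf("<http://ex/n%d>", sample(500L, 1L)),
           literal = sprintf("\"v%d\"", sample(500L, 1L)))
  }
  lines <- vapply(cls, function(cl) {
    s <- switch(cl, b2 = term("blank"), b1 = if (runif(1) < 0.5) term("blank") else term("iri"),
                plain = if (runif(1) < 0.5) term("iri") else term("iri"))
    o <- switch(cl,
                b2 = term("blank"),
                b1 = if (startsWith(s, "_:")) {
                  if (runif(1) < 0.5) term("iri") else term("literal")
                } else term("blank"),
                plain = if (runif(1) < 0.5) term("iri") else term("literal"))
    paste(s, sprintf("<http://ex/p%d>", sample(50L, 1L)), o, ".")
  }, character(1))
  bnsplit:::parse_ntriples_lines(lines)$records
}

# write a triple_set to a temp .nt file, returning the path
write_temp_nt <- function(ts) {
  f <- tempfile(fileext = ".nt")
  write_ntriples(ts, f)
  f
}
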