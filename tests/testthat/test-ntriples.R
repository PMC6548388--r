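test_that("well-formed lines parse into the right term kinds and lexical forms", {
  r <- parse_ntriple_line("<http://ex/s> <http://ex/p> <http://ex/o> .")
  expect_equal(r$subj_kind, "iri")
  expect_equal(r$subject, "http://ex/s")
  expect_equal(r$predicate, "http://ex/p")
  expect_equal(r$obj_kind, "iri")

  r <- parse_ntriple_line("_:b1 <http://ex/p> _:b2 .")
  expect_equal(r$subj_kind, "blank")
  expect_equal(r$subject, "b1")
  expect_equal(r$object, "b2")

  line <- '<http://ex/s> <http://ex/p> "a \\"quoted\\" value"@en .'
  r <- parse_ntriple_line(line)
  expect_equal(r$obj_kind, "literal")
  # the literal lexical form is the full token, cross-checked against the
  # character-walk reference parser
  ref <- ref_parse_line(line)
  expect_equal(r$object, ref$lexs[3])
  expect_equal(c(r$subj_kind, "iri", r$obj_kind), ref$kinds)

  r <- parse_ntriple_line('<http://ex/s> <http://ex/p> "3.1"^^<http://www.w3.org/2001/XMLSchema#decimal> .')
  expect_equal(r$obj_kind, "literal")
  expect_match(r$object, "XMLSchema#decimal")
})

test_that("comment and blank lines are skip markers, malformed lines are errors", {
  expect_null(parse_ntriple_line("# a comment"))
  expect_null(parse_ntriple_line("   "))
  expect_null(parse_ntriple_line(""))

  # missing terminator, literal subject, blank predicate, bad term syntax
  expect_error(parse_ntriple_line("<http://ex/s> <http://ex/p> <http://ex/o>", 7),
               "line 7")
  expect_error(parse_ntriple_line('"lit" <http://ex/p> <http://ex/o> .'), "malformed")
  expect_error(parse_ntriple_line("<http://ex/s> _:b <http://ex/o> ."), "malformed")
  expect_error(parse_ntriple_line("<http://ex s> <http://ex/p> <http://ex/o> ."),
               "malformed")
})

test_that("write after read reproduces a clean file byte-for-byte", {
  set.seed(11)
  ts <- random_triple_set(100)
  f1 <- write_temp_nt(ts)
  x <- read_ntriples(f1)
  f2 <- tempfile(fileext = ".nt")
  expect_equal(write_ntriples(x, f2), 100L)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  # permuted order: same multiset of lines
  f3 <- tempfile(fileext = ".nt")
  write_ntriples(x[sample(nrow(x)), ], f3)
  expect_identical(sort(readLines(f1)), sort(readLines(f3)))
})

test_that("empty files, comments and CRLF terminators are handled", {
  f <- tempfile(fileext = ".nt")
  file.create(f)
  x <- read_ntriples(f)
  expect_equal(nrow(x), 0L)

  writeLines(c("# header", "<http://ex/s> <http://ex/p> <http://ex/o> .",
               "", "_:a <http://ex/p> \"v\" ."), f)
  x <- read_ntriples(f)
  expect_equal(nrow(x), 2L)
  expect_equal(attr(x, "n_skipped"), 2L)

  # CRLF input parses and is re-emitted with bare LF
  con <- file(f, open = "wb")
  writeBin(charToRaw("_:a <http://ex/p> _:b .\r\n<http://ex/s> <http://ex/p> <http://ex/o> .\r\n"), con)
  close(con)
  x <- read_ntriples(f)
  expect_equal(nrow(x), 2L)
  expect_false(any(grepl("\r", x$raw_line)))
  f2 <- tempfile(fileext = ".nt")
  write_ntriples(x, f2)
  expect_false(any(grepl("\r", readLines(f2))))
})

test_that("chunked streaming yields every record in order with bounded chunks", {
  set.seed(12)
  ts <- random_triple_set(500)
  f <- write_temp_nt(ts)
  seen <- character()
  chunks <- 0L
  tot <- nt_chunk_apply(f, function(recs) {
    chunks <<- chunks + 1L
    expect_lte(nrow(recs), 64L)
    seen <<- c(seen, recs$raw_line)
  }, chunk_size = 64L)
  expect_identical(seen, ts$raw_line)
  expect_equal(tot$n_triples, 500L)
  expect_gte(chunks, 8L)

  # record count equals the non-comment, non-blank line count on a larger file
  set.seed(13)
  big <- random_triple_set(20000)
  fb <- tempfile(fileext = ".nt")
  lines <- big$raw_line
  lines[sample(20000, 500)] <- "# noise"
  writeLines(lines, fb)
  n_body <- sum(!grepl("^\\s*(#|$)", lines))   # independent text scan
  expect_equal(nt_chunk_apply(fb, function(recs) NULL)$n_triples, n_body)
})

test_that("the vectorized parser agrees with the reference parser on a generated corpus", {
  set.seed(14)
  ts <- random_triple_set(1000, n_labels = 40L)
  for (i in sample(1000, 250)) {
    ref <- ref_parse_line(ts$raw_line[i])
    expect_identical(c(ts$subj_kind[i], "iri", ts$obj_kind[i]), ref$kinds)
    expect_identical(c(ts$subject[i], ts$predicate[i], ts$object[i]), ref$lexs)
  }
})

test_that("synthetic generator output is parse-total", {
  spec <- synthetic_graph_spec("watts_strogatz", n = 400, d = 2, p = 0.5,
                               blank_ratio = 0.5, seed = 21)
  f <- tempfile(fileext = ".nt")
  make_dataset(spec, f)
  expect_silent(x <- read_ntriples(f))
  expect_gt(nrow(x), 0L)
  for (i in sample(nrow(x), 50)) {
    expect_false(identical(ref_parse_line(x$raw_line[i]), "error"))
  }
})
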