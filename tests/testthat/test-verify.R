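mk_ts <- function(lines) bnsplit:::parse_ntriples_lines(lines)$records

test_that("profiles count per-blank-node triples by position", {
  ts <- mk_ts(c("_:a <http://ex/p> <http://ex/o1> .",
                "_:a <http://ex/p> <http://ex/o2> .",
                "<http://ex/s> <http://ex/p> _:a ."))
  p <- blank_profile(ts)
  expect_equal(p$subject_counts, 2L)
  expect_equal(p$object_counts, 1L)

  # per-file scoping: the same label in two files is two nodes
  p2 <- blank_profile(list(mk_ts("_:a <http://ex/p> <http://ex/o> ."),
                           mk_ts("_:a <http://ex/p> <http://ex/o> .")))
  expect_equal(p2$subject_counts, c(1L, 1L))
})

test_that("a correct split preserves the profile; a blank-splitting one does not", {
  set.seed(61)
  ts <- random_triple_set(120, n_labels = 9L)
  part <- build_partition(ts)
  k <- part$n_blank_groups
  asg <- distribute_plain_fast(
    suppressWarnings(lpt_assign(part$group_sizes[seq_len(k)], 3)),
    sum(part$classes == "plain"))
  bins <- bins_for(part, asg)
  spl <- lapply(1:3, function(j) ts[bins == j, , drop = FALSE])
  expect_true(profiles_match(blank_profile(ts), blank_profile(spl)))

  # deliberately divide one multi-triple group across two files
  g <- which(part$group_sizes >= 2)[1]
  idx <- which(part$group == g)
  bad <- list(ts[idx[1], , drop = FALSE], ts[idx[-1], , drop = FALSE],
              ts[-idx, , drop = FALSE])
  expect_false(profiles_match(blank_profile(ts), blank_profile(bad)))
})

test_that("conservation passes on an identity split and names discrepancies", {
  set.seed(62)
  ts <- random_triple_set(60)
  f <- write_temp_nt(ts)
  rep <- check_conservation(f, f)            # m = 1 copy
  expect_true(rep$pass)

  # one line deleted -> fail, with the discrepancy reported
  rep2 <- check_conservation(ts, list(ts[-1, , drop = FALSE]))
  expect_false(rep2$pass)
  expect_true(any(!rep2$checks$pass))
  expect_match(paste(rep2$checks$detail, collapse = " "), "59|missing",
               ignore.case = TRUE)
})

test_that("exact bijection accepts relabelings and rejects merged blanks", {
  ts <- mk_ts(c("_:a <http://ex/p> _:b .",
                "_:b <http://ex/p> <http://ex/o> .",
                "_:c <http://ex/p> \"v\" .",
                "<http://ex/s> <http://ex/p> <http://ex/o> ."))
  # correct split: group {a,b} in one file, {c} + plain in another
  part <- build_partition(ts)
  s1 <- ts[part$group == part$group[1], , drop = FALSE]
  s2 <- ts[part$group != part$group[1], , drop = FALSE]
  expect_true(check_isomorphic(ts, list(s1, s2)))

  # swapping two blank labels inside one file is still isomorphic
  s1sw <- s1
  swap <- c(a = "b", b = "a")
  bl <- s1sw$subj_kind == "blank"
  s1sw$subject[bl] <- unname(swap[s1sw$subject[bl]])
  bl <- s1sw$obj_kind == "blank"
  s1sw$object[bl] <- unname(swap[s1sw$object[bl]])
  s1sw$raw_line <- paste(ifelse(s1sw$subj_kind == "blank", paste0("_:", s1sw$subject),
                                paste0("<", s1sw$subject, ">")),
                         paste0("<", s1sw$predicate, ">"),
                         ifelse(s1sw$obj_kind == "blank", paste0("_:", s1sw$object),
                                ifelse(s1sw$obj_kind == "iri",
                                       paste0("<", s1sw$object, ">"), s1sw$object)),
                         ".")
  expect_true(check_isomorphic(ts, list(s1sw, s2)))

  # merging two distinct blanks into one label is not isomorphic
  merged <- mk_ts(c("_:x <http://ex/p> _:x .",
                    "_:x <http://ex/p> <http://ex/o> .",
                    "_:x <http://ex/p> \"v\" .",
                    "<http://ex/s> <http://ex/p> <http://ex/o> ."))
  expect_false(check_isomorphic(ts, list(merged)))

  # refusal above the blank budget
  big <- mk_ts(sprintf("_:b%d <http://ex/p> \"v\" .", 1:25))
  expect_error(check_isomorphic(big, list(big)), "too large")
})

test_that("split-then-verify passes end to end on a generated dataset", {
  spec <- synthetic_graph_spec("barabasi_albert", n = 400, n0 = 2, e = 10,
                               blank_ratio = 0.5, seed = 63)
  f <- tempfile(fileext = ".nt")
  make_dataset(spec, f)
  man <- run_split(f, 10, output_dir = tempdir())
  expect_equal(length(man$outputs), 10L)
  rep <- run_verify(f, man$outputs)
  expect_true(rep$pass)

  # tampering with one part is detected
  lines <- readLines(man$outputs[1])
  writeLines(lines[-1], man$outputs[1])
  expect_false(run_verify(f, man$outputs)$pass)
})
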