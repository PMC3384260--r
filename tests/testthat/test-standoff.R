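# Standoff I/O: .txt/.a1 reading, dependency dialects, .a2 round trips,
# the file pipeline and its ablation flags.

test_that("txt/a1 reading validates spans against the text", {
  d <- withr::local_tempdir()
  writeLines("The gp41 protein acts.", file.path(d, "doc.txt"))
  writeLines("T1\tProtein 4 8\tgp41", file.path(d, "doc.a1"))
  doc <- read_txt_a1(file.path(d, "doc.txt"), file.path(d, "doc.a1"))
  expect_equal(doc$entities$text, "gp41")
  expect_equal(doc$entities$start, 4L)
  # empty .a1 -> zero entities
  writeLines(character(0), file.path(d, "empty.a1"))
  doc2 <- read_txt_a1(file.path(d, "doc.txt"), file.path(d, "empty.a1"))
  expect_equal(nrow(doc2$entities), 0)
  # offset/text mismatch is a parse error naming the line
  writeLines("T1\tProtein 4 8\tgp99", file.path(d, "bad.a1"))
  expect_error(read_txt_a1(file.path(d, "doc.txt"), file.path(d, "bad.a1")),
               "T1")
})

test_that("both dependency dialects parse and agree on structure", {
  d <- withr::local_tempdir()
  paren <- file.path(d, "p.sd")
  writeLines(c("amod(involvement-3, possible-2)",
               "prep_of(involvement-3, HCMV-5)",
               "",
               "nsubj(binds-2, It-1)"), paren)
  sents <- read_dependencies(paren)
  expect_length(sents, 2)
  expect_equal(sents[[1]]$deps,
               data.frame(label = c("amod", "prep_of"), gov = c(3L, 3L),
                          dep = c(2L, 5L), stringsAsFactors = FALSE))
  expect_equal(sents[[1]]$tokens$form[sents[[1]]$tokens$idx == 5], "HCMV")
  conll <- file.path(d, "c.dep")
  writeLines(c(paste("1\tIt\tit\tPRP\t2\tnsubj",
                     "2\tbinds\tbind\tVBZ\t0\troot", sep = "\n")), conll)
  sents2 <- read_dependencies(conll)
  expect_equal(sents2[[1]]$deps$label, "nsubj")
  expect_equal(sents2[[1]]$tokens$lemma, c("it", "bind"))
  # blank-line separated blocks -> sentence count equals block count
  expect_length(sents, 2)
  # malformed line errors with its position
  writeLines("garbage without parens", file.path(d, "bad.sd"))
  writeLines("1\tonly\ttwo", file.path(d, "bad2.dep"))
  expect_error(read_dependencies(file.path(d, "bad2.dep")), "sentence 1")
})

test_that("equivalent parses in the two dialects build identical graphs", {
  d <- withr::local_tempdir()
  conll <- file.path(d, "x.dep")
  writeLines(c("1\tpossible\tpossible\t\t2\tamod",
               "2\tinvolvement\tinvolvement\t\t0\troot",
               "3\tof\tof\t\t0\troot",
               "4\tHCMV\thcmv\t\t2\tprep_of"), conll)
  paren <- file.path(d, "x.sd")
  writeLines(c("amod(involvement-2, possible-1)",
               "prep_of(involvement-2, HCMV-4)"), paren)
  text <- "possible involvement of HCMV"
  a <- read_dependencies(conll, text)
  b <- read_dependencies(paren, text)
  ga <- build_sentence_graph(a[[1]]$tokens, a[[1]]$deps,
                             lexicon = default_lexicon())
  gb <- build_sentence_graph(b[[1]]$tokens, b[[1]]$deps,
                             lexicon = default_lexicon())
  expect_equal(ga$arcs, gb$arcs)
})

test_that("a2 serialization round-trips and refuses dangling references", {
  res <- fixture_result("ex14")
  ents <- builtin_cases()$ex14$entities
  lines <- res$a2
  parsed <- read_a2(lines)
  expect_equal(nrow(parsed$triggers), 2)
  # write -> read -> write fixpoint: rebuild an event set and re-serialize
  expect_equal(parsed$events[[1]]$type, "Positive_regulation")
  expect_equal(parsed$events[[1]]$roles[[1]]$role, "Theme")
  # zero events -> empty output
  empty <- structure(list(events = list(), modifications = list(),
                          track = "GENIA"), class = "event_set")
  expect_length(write_a2(empty, ents), 0)
  # dangling participant reference refuses to write
  bad <- structure(list(events = list(list(
    pred_id = "p1", type = "GENE_EXPRESSION", trigger_start = 0L,
    trigger_end = 4L, trigger_text = "x",
    roles = list(list(role = "Theme", kind = "entity", ref = "T99")))),
    modifications = list(), track = "GENIA"), class = "event_set")
  expect_error(write_a2(bad, ents), "dangling")
})

test_that("trigger T numbering continues after the a1 maximum", {
  res <- fixture_result("ex14")
  parsed <- read_a2(res$a2)
  expect_equal(parsed$triggers$id, c("T4", "T5"))   # a1 holds T1..T3
})

test_that("expected standoff output for the demonstrative-causal sentence", {
  res <- fixture_result("ex14")
  e_lines <- grep("^E", res$a2, value = TRUE)
  expect_equal(sub("\t", " ", e_lines),
               c("E1 Positive_regulation:T4 Theme:E2 Cause:T1",
                 "E2 Gene_expression:T5 Theme:T2"))
})

test_that("the file pipeline reproduces the in-memory results", {
  d <- withr::local_tempdir()
  indir <- file.path(d, "in"); outdir <- file.path(d, "out")
  cases <- builtin_cases()
  for (nm in c("ex14", "fig2", "ex16"))
    write_case_files(cases[[nm]], indir)
  stats <- run_pipeline(indir, outdir)
  expect_setequal(stats$doc_id, c("ex14", "fig2", "ex16"))
  for (nm in c("ex14", "fig2", "ex16")) {
    got <- readLines(file.path(outdir, paste0(nm, ".a2")))
    expect_equal(got, fixture_result(nm)$a2)
  }
  # byte-identical across runs
  run_pipeline(indir, file.path(d, "out2"))
  for (nm in c("ex14", "fig2", "ex16"))
    expect_identical(readLines(file.path(outdir, paste0(nm, ".a2"))),
                     readLines(file.path(d, "out2", paste0(nm, ".a2"))))
})

test_that("coreference ablation flags change output only when phenomena exist", {
  base <- compose_config()
  off <- compose_config(coref_classes = "none")
  # no anaphora: identical output
  expect_equal(run_fixture(builtin_cases()$ex13, off)$a2,
               run_fixture(builtin_cases()$ex13, base)$a2)
  # pronominal anaphora: PRON toggle changes output, RELAT toggle does not
  ex16 <- builtin_cases()$ex16
  with_pron <- run_fixture(ex16, compose_config(coref_classes = "pron"))$a2
  no_pron <- run_fixture(ex16, compose_config(
    coref_classes = c("relat", "appos", "dnp")))$a2
  expect_false(identical(with_pron, no_pron))
  expect_equal(run_fixture(ex16, base)$a2, with_pron)
  # sortal anaphora responds to the DNP toggle
  ex24 <- builtin_cases()$ex24
  expect_false(identical(
    run_fixture(ex24, compose_config(coref_classes = "dnp"))$a2,
    run_fixture(ex24, off)$a2))
})

test_that("propagation depth ablation changes only propagation fixtures", {
  deep <- compose_config()
  shallow <- compose_config(propagation_depth = 1)
  expect_false(identical(run_fixture(builtin_cases()$ex13, deep)$a2,
                         run_fixture(builtin_cases()$ex13, shallow)$a2))
  expect_identical(run_fixture(builtin_cases()$ex12, deep)$a2,
                   run_fixture(builtin_cases()$ex12, shallow)$a2)
})
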