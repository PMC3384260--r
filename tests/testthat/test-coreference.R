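# Coreference: RELAT/APPOS rules, candidate windows, compatibility,
# blocking, closest-candidate selection.

test_that("relative pronouns corefer with the modified NP head", {
  r <- fixture_result("fig2")
  ca <- coref_arcs(r$graph)
  expect_true(any(ca$anaphor == "which" & ca$antecedent == "phosphorylation"))
})

test_that("a rel dependency without a matching rcmod yields no arc", {
  tk <- data.frame(idx = 1:3, form = c("protein", "which", "binds"),
                   lemma = c("protein", "which", "bind"),
                   pos = c("NN", "WDT", "VBZ"),
                   start = c(0L, 10L, 20L), end = c(7L, 15L, 25L))
  deps <- data.frame(label = "rel", gov = 3L, dep = 2L)
  sg <- build_sentence_graph(tk, deps, lexicon = default_lexicon())
  g <- link_sentences(list(sg))
  expect_equal(nrow(resolve_relat(g)), 0)
  # and with no rel dependency at all
  expect_equal(nrow(resolve_relat(fixture_result("ex11")$graph)), 0)
})

test_that("appositive-family arcs corefer in either direction, anaphor last", {
  r <- fixture_result("ex14")
  ca <- coref_arcs(r$graph)
  expect_true(any(ca$anaphor == "IL-10" & ca$antecedent == "interleukin-10"))
  expect_true(any(ca$anaphor == "domain" & ca$antecedent == "gp41"))
  # no appositive arcs -> no APPOS coreference
  expect_equal(nrow(resolve_appos(fixture_result("ex12")$graph)), 0)
})

test_that("candidate sets equal the brute-force prior/bound filter", {
  for (nm in c("ex23", "ex27")) {
    case <- builtin_cases()[[nm]]
    fx <- fixture_graph(case)
    g <- fx$graph
    lex <- fx$config$compat_lexicons
    anas <- find_anaphors(g)
    for (i in seq_len(nrow(anas))) {
      ana <- as.list(anas[i, ])
      got <- candidate_antecedents(ana, g, lex)
      nd <- g$nodes
      astart <- nd$start[nd$id == ana$node]
      brute <- nd$id[nd$start < astart &
                       (nd$binding != "free" | nd$lemma %in% lex$hypernyms |
                          nd$conj)]
      # candidates are the reachable members of the brute-force set
      expect_true(all(got %in% brute))
      d <- bioscope:::coref_distances(g, ana$node)
      expect_setequal(got, brute[is.finite(d[brute])])
      # ordered by increasing graph distance
      expect_true(!is.unsorted(d[got]))
    }
  }
})

test_that("sortal compatibility constraints fire as specified", {
  lex <- compat_lexicons()
  # singular hypernymy: entity antecedent for "this protein"-style anaphor
  r24 <- fixture_result("ex24")
  ca <- coref_arcs(r24$graph)
  expect_true(any(ca$anaphor == "factor" & ca$antecedent == "APOBEC3G"))
  # plural hypernymy (set-instance): conjunction antecedent
  g23 <- fixture_result("ex23")$graph
  anas <- find_anaphors(g23)
  their <- as.list(anas[anas$head_lemma == "their", ])
  conj <- g23$nodes$id[g23$nodes$conj]
  expect_true(antecedent_compatible(their, conj[1], g23, lex))
  # number agreement failure: singular pronoun vs plural conjunction
  its <- their; its$number <- "singular"
  expect_false(antecedent_compatible(its, conj[1], g23, lex))
})

test_that("head word and meronymy constraints license sortal anaphora", {
  # "the gene" vs "CD4 gene": head-word constraint via the free head noun
  tk1 <- data.frame(idx = 1:3, form = c("CD4", "gene", "works"),
                    lemma = c("cd4", "gene", "work"),
                    pos = c("NN", "NN", "VBZ"),
                    start = c(0L, 4L, 9L), end = c(3L, 8L, 14L))
  d1 <- data.frame(label = c("nn", "nsubj"), gov = c(2L, 3L), dep = c(1L, 2L))
  tk2 <- data.frame(idx = 1:3, form = c("the", "gene", "acts"),
                    lemma = c("the", "gene", "act"),
                    pos = c("DT", "NN", "VBZ"),
                    start = c(15L, 19L, 24L), end = c(18L, 23L, 28L))
  d2 <- data.frame(label = c("det", "nsubj"), gov = c(2L, 3L), dep = c(1L, 2L))
  ents <- data.frame(id = "T1", type = "Protein", start = 0L, end = 3L,
                     text = "CD4", stringsAsFactors = FALSE)
  g <- link_sentences(list(
    build_sentence_graph(tk1, d1, ents, default_lexicon(), sentence = 1L),
    build_sentence_graph(tk2, d2, ents, default_lexicon(), sentence = 2L)))
  g2 <- resolve_coreference(g)
  ca <- coref_arcs(g2)
  expect_true(any(ca$anaphor == "gene" & ca$antecedent == "gene"))
  # meronymy: "the dimer" accepts an entity with a '/' compound surface form
  lex <- compat_lexicons()
  gx <- g2
  gx$nodes$binding[1] <- "entity"
  gx$nodes$text[1] <- "IBR/F"
  ana <- list(node = gx$nodes$id[gx$nodes$lemma == "gene" &
                                   gx$nodes$sentence == 2][1],
              klass = "DNP", number = "singular", reflexive = FALSE,
              head_lemma = "dimer")
  expect_true(antecedent_compatible(ana, gx$nodes$id[1], gx, lex))
})

test_that("event constraint pairs lexicalizations of the same event type", {
  tk1 <- data.frame(idx = 1:2, form = c("STAT1", "phosphorylated"),
                    lemma = c("stat1", "phosphorylate"),
                    pos = c("NN", "VBN"), start = c(0L, 6L),
                    end = c(5L, 20L))
  d1 <- data.frame(label = "nsubjpass", gov = 2L, dep = 1L)
  tk2 <- data.frame(idx = 1:3, form = c("the", "phosphorylation", "matters"),
                    lemma = c("the", "phosphorylation", "matter"),
                    pos = c("DT", "NN", "VBZ"),
                    start = c(21L, 25L, 41L), end = c(24L, 40L, 48L))
  d2 <- data.frame(label = c("det", "nsubj"), gov = c(2L, 3L),
                   dep = c(1L, 2L))
  ents <- data.frame(id = "T1", type = "Protein", start = 0L, end = 5L,
                     text = "STAT1", stringsAsFactors = FALSE)
  g <- link_sentences(list(
    build_sentence_graph(tk1, d1, ents, default_lexicon(), sentence = 1L),
    build_sentence_graph(tk2, d2, ents, default_lexicon(), sentence = 2L)))
  g <- resolve_coreference(g)
  ca <- coref_arcs(g)
  expect_true(any(ca$anaphor == "phosphorylation" &
                    ca$antecedent == "phosphorylated"))
})

test_that("structural blockers fire: direct embedding and subject-object", {
  r <- fixture_result("ex23")
  g <- r$graph
  nd <- g$nodes
  their <- nd$id[nd$lemma == "their"]
  expr <- nd$id[nd$lemma == "expression"]
  ana <- list(node = their, klass = "PRON", number = "plural",
              reflexive = FALSE, head_lemma = "their")
  # direct parent (POSS arc) blocks
  expect_true(antecedent_blocked(ana, expr, g))
  # unrelated distant node does not block
  gata3 <- nd$id[nd$text == "GATA3"]
  expect_false(antecedent_blocked(ana, gata3, g))
})

test_that("subject-object blocking spares reflexive anaphors", {
  tk <- data.frame(idx = 1:3, form = c("Raf", "binds", "itself"),
                   lemma = c("raf", "bind", "itself"),
                   pos = c("NN", "VBZ", "PRP"),
                   start = c(0L, 4L, 10L), end = c(3L, 9L, 16L))
  deps <- data.frame(label = c("nsubj", "dobj"), gov = c(2L, 2L),
                     dep = c(1L, 3L))
  ents <- data.frame(id = "T1", type = "Protein", start = 0L, end = 3L,
                     text = "Raf", stringsAsFactors = FALSE)
  sg <- build_sentence_graph(tk, deps, ents, default_lexicon())
  g <- link_sentences(list(sg), entities = ents)
  nd <- g$nodes
  raf <- nd$id[nd$text == "Raf"]
  itself <- nd$id[nd$lemma == "itself"]
  refl <- list(node = itself, klass = "PRON", number = "singular",
               reflexive = TRUE, head_lemma = "itself")
  nonrefl <- refl; nonrefl$reflexive <- FALSE; nonrefl$head_lemma <- "it"
  expect_false(antecedent_blocked(refl, raf, g))
  expect_true(antecedent_blocked(nonrefl, raf, g))
  # reflexive resolution goes through end to end
  g2 <- resolve_coreference(g)
  ca <- coref_arcs(g2)
  expect_true(any(ca$anaphor == "itself" & ca$antecedent == "Raf"))
})

test_that("closest unblocked compatible candidate wins; plural fans out", {
  r16 <- fixture_result("ex16")
  expect_equal(coref_arcs(r16$graph),
               data.frame(anaphor = "Its", antecedent = "Eotaxin",
                          stringsAsFactors = FALSE))
  r23 <- fixture_result("ex23")
  ca <- coref_arcs(r23$graph)
  expect_setequal(ca$antecedent[ca$anaphor == "their"], c("GATA3", "FOXP3"))
  r27 <- fixture_result("ex27")
  ca27 <- coref_arcs(r27$graph)
  expect_setequal(ca27$antecedent[ca27$anaphor == "they"],
                  c("PKD1", "PKD2", "PKD3"))
  # semantically free NP ("PKD enzymes") is never selected
  expect_false("enzymes" %in% ca27$antecedent)
})

test_that("COREF arcs always point backwards and never at blocked pairs", {
  for (nm in c("fig2", "ex14", "ex16", "ex23", "ex24", "ex25", "ex26",
               "ex27")) {
    g <- fixture_result(nm)$graph
    a <- graph_arcs(g, "coref")
    nd <- g$nodes
    expect_true(all(nd$start[match(a$target, nd$id)] <=
                      nd$start[match(a$source, nd$id)]))
    # adding COREF arcs leaves the non-COREF subgraph acyclic
    expect_true(assert_acyclic(g))
  }
})

test_that("resolution is deterministic", {
  a <- run_fixture(builtin_cases()$ex27)
  b <- run_fixture(builtin_cases()$ex27)
  expect_identical(a$graph$arcs, b$graph$arcs)
  expect_identical(a$a2, b$a2)
})
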