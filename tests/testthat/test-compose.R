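# Composition: argument identification and propagation, polarity and
# modality operators, coordination distribution, negative raising.

test_that("polarity composition matches the published table row by row", {
  expect_equal(compose_polarity("neutral", "positive"), "positive")
  expect_equal(compose_polarity("neutral", "negative"), "negative")
  expect_equal(compose_polarity("negative", "positive"), "negative")
  expect_equal(compose_polarity("negative", "negative"), "negative")
  expect_equal(compose_polarity("negative", NULL), "negative")
  expect_equal(compose_polarity("positive", "negative"), "negative")
  expect_equal(compose_polarity("positive", "positive"), "positive")
  expect_equal(compose_polarity("positive", NULL), "positive")
  expect_equal(compose_polarity("neutral", NULL), "neutral")
  # totality over the polarity square
  for (tp in c("positive", "negative", "neutral"))
    for (ep in c("positive", "negative", "neutral"))
      expect_true(compose_polarity(tp, ep) %in%
                    c("positive", "negative", "neutral"))
})

test_that("the negator inverts the modality value and is an involution", {
  expect_equal(apply_negator(1), 0)
  expect_equal(apply_negator(0.5), 0.5)
  for (mv in seq(0, 1, by = 0.1))
    expect_equal(apply_negator(apply_negator(mv)), mv)
})

test_that("the modal shift lowers high values and raises low values", {
  expect_equal(apply_modal(0.7, 0), 0.3)    # "may not involve"
  expect_equal(apply_modal(0.7, 1), 0.7)    # "presumed"
  # strength 1 is the identity on both branches
  for (mv in seq(0, 1, by = 0.25)) expect_equal(apply_modal(1, mv), mv)
  # branch monotonicity: output <= input when input >= 0.5, >= otherwise
  for (s in c(0.3, 0.6, 0.9)) {
    for (mv in seq(0, 1, by = 0.1)) {
      out <- apply_modal(s, mv)
      if (mv >= 0.5) expect_lte(out, mv) else expect_gte(out, mv)
      expect_gte(out, 0); expect_lte(out, 1)
    }
  }
})

test_that("diminishers lower like modals; intensifiers raise symmetrically", {
  s <- 0.3
  expect_equal(apply_shifter("DIMINISHER", s, 1), s)
  expect_equal(apply_shifter("INTENSIFIER", s, 1), 1)  # clamped at maximum
  expect_equal(apply_shifter("INTENSIFIER", s, 0.6), 0.6 + (1 - s) * 0.4)
  for (mv in seq(0, 1, by = 0.25)) {
    expect_equal(apply_shifter("DIMINISHER", 1, mv), mv)
    expect_equal(apply_shifter("INTENSIFIER", 1, mv), mv)
  }
})

test_that("modality values stay within [0,1] under random operator chains", {
  set.seed(7)
  for (rep in 1:200) {
    mv <- 1.0
    for (k in seq_len(sample(1:8, 1))) {
      op <- sample(c("neg", "modal", "dim", "int"), 1)
      s <- runif(1)
      mv <- switch(op,
                   neg = apply_negator(mv),
                   modal = apply_modal(s, mv),
                   dim = apply_shifter("DIMINISHER", s, mv),
                   int = apply_shifter("INTENSIFIER", s, mv))
      expect_gte(mv, 0); expect_lte(mv, 1)
    }
  }
})

test_that("argument identification rules reproduce the published rule rows", {
  rules <- default_argument_rules()
  mk_graph <- function(lemma, pos, sem, rel) {
    nodes <- data.frame(
      id = c("a", "b"), sentence = 1L, first_idx = 1:2, last_idx = 1:2,
      start = c(0L, 10L), end = c(5L, 15L), text = c(lemma, "arg"),
      lemma = c(lemma, "arg"), pos = c(pos, "NN"),
      binding = c("predicate", "free"),
      ref = NA_character_, sem_type = c(sem, NA), polarity = NA_character_,
      strength = c(1, NA), negative_raising = FALSE, conj = FALSE,
      stringsAsFactors = FALSE)
    arcs <- data.frame(type = rel, source = "a", target = "b",
                       stringsAsFactors = FALSE)
    list(nodes = nodes, arcs = arcs)
  }
  row <- function(lemma, pos, sem, rel) {
    identify_arguments("a", mk_graph(lemma, pos, sem, rel), rules)$arg_type
  }
  expect_equal(row("influence", "NN", NA, "PREP_ON"), "Object")
  expect_equal(row("binding", "NN", "BINDING", "PREP_ON"), NA_character_)
  expect_equal(row("stimulate", "VB", "CAUSAL", "AGENT"), "Subject")
  expect_equal(row("bind", "VBD", "BINDING", "NSUBJPASS"), "Object")
  expect_equal(row("examine", "VB", "INTERROGATIVE", "WHETHER_COMP"),
               "Object")
  expect_equal(row("wonder", "VB", "CAUSAL", "WHETHER_COMP"), NA_character_)
  expect_equal(row("production", "NN", "GENE_EXPRESSION", "PREP_IN"),
               "Adjunct")
  expect_equal(row("role", "NN", "SALIENCY", "PREP_IN"), NA_character_)
})

test_that("inclusion/exclusion constraint semantics follow the amended rule", {
  rules <- load_argument_rules(data.frame(
    relation = "PREP_X", pos = "NN", inclusions = "alpha,CAUSAL",
    exclusions = "-", arg_type = "Object"))
  # brute-force oracle over (lemma, sem) combinations
  for (lemma in c("alpha", "beta")) {
    for (sem in c("CAUSAL", "BINDING")) {
      expected <- lemma == "alpha" || sem == "CAUSAL"
      got <- bioscope:::rule_applies(rules[1, ], "PREP_X", lemma, "NN", sem)
      expect_identical(got, expected)
    }
  }
  expect_error(load_argument_rules(data.frame(
    relation = "X", pos = "NN", inclusions = "a", exclusions = "a",
    arg_type = "Object")), "overlap")
})

test_that("argument propagation licenses bound descendants of free chains", {
  r <- fixture_result("ex13")
  ps <- r$predications
  bind <- pred_by_lemma(ps, "bind")
  expect_equal(bind$object$kind, "entity")
  expect_equal(bind$object$ref, "T1")   # IL-10 through site -> promoter
  # gp41 is not an argument: PREP_AFTER licenses no rule
  refs <- vapply(pred_args(bind), `[[`, character(1), "ref")
  expect_false("T2" %in% refs)
  # the search itself, with depths
  g <- r$graph
  site <- g$nodes$id[g$nodes$lemma == "site"]
  hits <- propagate_arguments(g, site)
  expect_equal(g$nodes$text[match(hits$node[1], g$nodes$id)], "IL-10")
  expect_equal(hits$depth[1], 2L)
  # a depth limit of 1 cannot cross the two-node free chain
  expect_equal(nrow(propagate_arguments(g, site, depth = 1)), 0)
})

test_that("propagation depth 1 changes the composed argument on ex13", {
  case <- builtin_cases()$ex13
  shallow <- run_fixture(case, compose_config(propagation_depth = 1))
  bind <- pred_by_lemma(shallow$predications, "bind")
  expect_equal(bind$object$kind, "free")   # stops at the free "site"
})

test_that("the may-not-involve chain composes to the published values", {
  ps <- fixture_result("ex12")$predications
  involve <- pred_by_lemma(ps, "involve")
  expect_equal(involve$mv, 0.3)
  expect_equal(involve$polarity, "negative")
  expect_true(involve$negated)
  may <- pred_by_lemma(ps, "may")
  expect_equal(may$mv, 0.7)
  expect_equal(embedding_class(may$sem_type), "modal")
})

test_that("a positive causal over a negative causal composes negative", {
  ps <- fixture_result("ex11")$predications
  lead <- pred_by_lemma(ps, "lead")
  expect_equal(lead$sem_type, "CAUSAL")
  expect_equal(lead$polarity, "negative")
  expect_equal(lead$mv, 1)
  prevention <- pred_by_lemma(ps, "prevention")
  expect_equal(prevention$polarity, "negative")
})

test_that("coordination distributes one predication per conjunct", {
  ps23 <- fixture_result("ex23")$predications
  expect_length(pred_ids_by_lemma(ps23, "expression"), 2)
  ps27 <- fixture_result("ex27")$predications
  acts <- lapply(pred_ids_by_lemma(ps27, "activate"),
                 function(i) ps27$predications[[i]])
  expect_length(acts, 3)
  expect_setequal(vapply(acts, function(p) p$object$ref, character(1)),
                  c("T1", "T2", "T3"))
  # distributed predications differ only in the distributed slot
  others <- unique(vapply(acts, function(p)
    paste(p$sem_type, p$polarity, p$mv, length(p$adjuncts)), character(1)))
  expect_length(others, 1)
})

test_that("negative raising transfers negation to the complement", {
  ps <- fixture_result("negraise")$predications
  think <- pred_by_lemma(ps, "think")
  stim <- pred_by_lemma(ps, "stimulate")
  expect_false(think$negated)
  expect_equal(think$polarity, "positive")
  expect_true(stim$negated)
  expect_equal(stim$polarity, "negative")
  # negation inverts to 0, then the epistemic strength 0.8 raises to 0.2
  expect_equal(stim$mv, 0.2)
})

test_that("worked demonstrative sentence composes as printed", {
  ps <- fixture_result("ex14")$predications
  show <- pred_by_lemma(ps, "show")
  stim <- pred_by_lemma(ps, "stimulate")
  prod <- pred_by_lemma(ps, "production")
  expect_equal(show$sem_type, "DEMONSTRATIVE")
  expect_equal(show$mv, 1); expect_equal(show$polarity, "positive")
  expect_equal(show$object$ref, stim$id)
  expect_equal(show$subject$kind, "free")
  expect_equal(stim$object$ref, prod$id)
  expect_equal(stim$subject$ref, "T1")
  # appositive abbreviation substitutes the full form entity
  expect_equal(prod$object$ref, "T2")
  expect_equal(prod$adjuncts[[1]]$kind, "free")
})

test_that("a graph without predicate mentions composes to the empty set", {
  tk <- data.frame(idx = 1:2, form = c("the", "cat"),
                   lemma = c("the", "cat"), pos = c("DT", "NN"),
                   start = c(0L, 4L), end = c(3L, 7L))
  deps <- data.frame(label = "det", gov = 2L, dep = 1L)
  g <- link_sentences(list(build_sentence_graph(tk, deps,
                                                lexicon = default_lexicon())))
  ps <- compose_document(g)
  expect_length(ps$predications, 0)
})
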