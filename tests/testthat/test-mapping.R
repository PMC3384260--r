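# Mapping: type mapping, role mapping, pruning, modifications.

mk_pred <- function(sem, klass, pol = "neutral", mv = 1, object = NULL,
                    id = "p1", lemma = "w") {
  new_predication(id, paste0("n_", id), lemma, sem, klass, mv = mv,
                  polarity = pol, object = object)
}

test_that("type mapping reproduces the published constraint rows", {
  rules <- default_type_mapping()
  map1 <- function(pr, track = "GENIA") {
    ps <- predication_set(list(pr))
    map_types(ps, rules, track)$out_type
  }
  expect_equal(map1(mk_pred("CAUSAL", "relational", "neutral")),
               "REGULATION")
  expect_equal(map1(mk_pred("SUCCESS", "modal", "negative")), "NEGATION")
  expect_equal(map1(mk_pred("CAUSAL", "relational", "positive",
                            ), track = "EPI"), "CATALYSIS")
  expect_equal(map1(mk_pred("SPECULATIVE", "modal", "positive", mv = 0.7)),
               "SPECULATION")
  expect_true(is.na(map1(mk_pred("SPECULATIVE", "modal", "positive",
                                 mv = 0))))   # mv constraint > 0.0
  expect_equal(map1(mk_pred("DEMONSTRATIVE", "modal", "negative")),
               "SPECULATION")
  # positive demonstrative is pruned (no rule row applies)
  expect_true(is.na(map1(mk_pred("DEMONSTRATIVE", "modal", "positive"))))
  # unmappable types: DEONTIC and TEMPORAL predications
  expect_true(is.na(map1(mk_pred("OBLIGATIVE", "modal", "positive"))))
  expect_true(is.na(map1(mk_pred("TEMPORAL", "relational", "neutral"))))
  # atomic predications keep their event type
  expect_equal(map1(mk_pred("GENE_EXPRESSION", "atomic")),
               "GENE_EXPRESSION")
})

test_that("role mapping converts logical arguments per the published rows", {
  rules <- default_role_mapping()
  pr <- new_predication("p1", "n1", "stimulate", "CAUSAL", "relational",
                        object = pred_arg("predication", "p0"),
                        subject = pred_arg("entity", "T1"))
  roles <- map_roles(pr, "POSITIVE_REGULATION", rules)
  expect_equal(vapply(roles, `[[`, character(1), "role"),
               c("Theme", "Cause"))
  # BINDING: Subject maps to Theme, not Cause
  roles_b <- map_roles(pr, "BINDING", rules)
  expect_equal(vapply(roles_b, `[[`, character(1), "role"),
               c("Theme", "Theme"))
  # PROCESS: Object maps to Participant (Subject still maps to Cause and is
  # later pruned by the event definition)
  roles_p <- map_roles(pr, "PROCESS", rules)
  expect_equal(vapply(roles_p, `[[`, character(1), "role"),
               c("Participant", "Cause"))
  # SPECULATION/NEGATION: Object maps to Scope
  roles_s <- map_roles(pr, "SPECULATION", rules)
  expect_equal(roles_s[[1]]$role, "Scope")
  # no mappable arguments -> empty participant set
  bare <- new_predication("p2", "n2", "x", "CAUSAL", "relational")
  expect_length(map_roles(bare, "REGULATION", rules), 0)
})

mk_event <- function(pred_id, type, roles = list(), start = 0L) {
  list(pred_id = pred_id, type = type, trigger_start = start,
       trigger_end = start + 4L, trigger_text = "trig", roles = roles)
}

test_that("pruning drops non-conforming and free participants", {
  ev <- mk_event("p1", "GENE_EXPRESSION", list(
    list(role = "Theme", kind = "entity", ref = "T1"),
    list(role = "Cause", kind = "entity", ref = "T2"),
    list(role = "Theme", kind = "free", ref = "n9")))
  out <- prune_events(list(ev), track = "GENIA")
  expect_length(out, 1)
  expect_equal(vapply(out[[1]]$roles, `[[`, character(1), "role"), "Theme")
  expect_equal(out[[1]]$roles[[1]]$ref, "T1")
})

test_that("events missing a mandatory participant are dropped, PROCESS kept", {
  no_theme <- mk_event("p1", "PHOSPHORYLATION", list(
    list(role = "Theme", kind = "free", ref = "n3")))
  expect_length(prune_events(list(no_theme), track = "GENIA"), 0)
  proc <- mk_event("p2", "PROCESS")
  expect_length(prune_events(list(proc), track = "ID"), 1)
  # PROCESS is undefined outside the infectious-diseases track
  expect_length(prune_events(list(proc), track = "GENIA"), 0)
})

test_that("pruning cascades through dropped sub-events and is monotone", {
  e_sub <- mk_event("p1", "PHOSPHORYLATION", list(
    list(role = "Theme", kind = "free", ref = "n3")))      # will drop
  e_top <- mk_event("p2", "POSITIVE_REGULATION", list(
    list(role = "Theme", kind = "predication", ref = "p1"),
    list(role = "Cause", kind = "entity", ref = "T1")), start = 10L)
  out <- prune_events(list(e_sub, e_top), track = "GENIA")
  expect_length(out, 0)   # top loses Theme, then fails the mandatory test
  # monotone: output is a subset of input at every step
  e_ok <- mk_event("p3", "GENE_EXPRESSION", list(
    list(role = "Theme", kind = "entity", ref = "T2")), start = 20L)
  out2 <- prune_events(list(e_sub, e_top, e_ok), track = "GENIA")
  expect_true(all(vapply(out2, `[[`, character(1), "pred_id") %in%
                    c("p1", "p2", "p3")))
  expect_length(out2, 1)
})

test_that("attributive arguments transfer to the embedded predication", {
  res <- fixture_result("ex8")
  sigs <- event_signatures(res)
  expect_equal(sigs, "PROTEIN_CATABOLISM(Theme:T1)")
  # the attributive predication itself yields no event
  expect_false(any(grepl("PATIENT", sigs)))
})

test_that("worked examples map to the expected annotation sets", {
  expect_setequal(event_signatures(fixture_result("ex14")),
                  c("POSITIVE_REGULATION(Cause:T1,Theme:production)",
                    "GENE_EXPRESSION(Theme:T2)"))
  fig2 <- fixture_result("fig2")
  expect_setequal(event_signatures(fig2),
                  c("PHOSPHORYLATION(Theme:T1)",
                    "POSITIVE_REGULATION(Theme:phosphorylation)"))
  # TEMPORAL and empty-argument predications yield no events
  ps <- fig2$predications
  mapped_preds <- vapply(fig2$events$events, `[[`, character(1), "pred_id")
  for (lemma in c("subsequent", "stimulation", "degradation", "important"))
    expect_false(any(pred_ids_by_lemma(ps, lemma) %in% mapped_preds))
})

test_that("negated success predications emit Negation on the scoped event", {
  res <- fixture_result("ex7")
  mods <- res$events$modifications
  expect_length(mods, 1)
  expect_equal(mods[[1]]$type, "NEGATION")
  target <- res$predications$predications[[mods[[1]]$target]]
  expect_equal(target$lemma, "stimulate")
})

test_that("speculation modifications attach to the nearest mapped events", {
  res <- fixture_result("ex12")
  mods <- res$events$modifications
  expect_length(mods, 2)
  expect_true(all(vapply(mods, `[[`, character(1), "type") == "SPECULATION"))
  targets <- vapply(mods, function(m)
    res$predications$predications[[m$target]]$lemma, character(1))
  expect_setequal(targets, c("upregulation", "activation"))
})

test_that("mapping never invents participants and output is closed", {
  for (nm in c("fig2", "ex14", "ex23", "ex26", "ex27")) {
    res <- fixture_result(nm)
    ents <- builtin_cases()[[nm]]$entities
    preds <- vapply(res$events$events, `[[`, character(1), "pred_id")
    for (ev in res$events$events) {
      for (r in ev$roles) {
        if (r$kind == "entity") expect_true(r$ref %in% ents$id)
        else expect_true(r$ref %in% preds)
      }
    }
    for (m in res$events$modifications)
      expect_true(m$target %in% preds)
  }
})
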