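# shared test helpers: predication lookup, event signatures, and a tiny
# hand-rolled reachability oracle for scope checks

pred_ids_by_lemma <- function(ps, lemma) {
  names(Filter(function(p) p$lemma == lemma, ps$predications))
}

pred_by_lemma <- function(ps, lemma) {
  ids <- pred_ids_by_lemma(ps, lemma)
  stopifnot(length(ids) >= 1)
  ps$predications[[ids[1]]]
}

# render events as "Type(Role:ref, ...)" with predication refs replaced by
# the referenced trigger lemma, for order-insensitive comparison
event_signatures <- function(res) {
  ps <- res$predications
  vapply(res$events$events, function(ev) {
    rr <- vapply(ev$roles, function(r) {
      ref <- if (r$kind == "predication")
        ps$predications[[r$ref]]$lemma else r$ref
      paste0(r$role, ":", ref)
    }, character(1))
    paste0(ev$type, "(", paste(sort(rr), collapse = ","), ")")
  }, character(1))
}

coref_arcs <- function(graph) {
  a <- graph$arcs[graph$arcs$type == "COREF", , drop = FALSE]
  nodes <- graph$nodes
  data.frame(anaphor = nodes$text[match(a$source, nodes$id)],
             antecedent = nodes$text[match(a$target, nodes$id)],
             stringsAsFactors = FALSE)
}

# brute-force reachability over predication arguments by exhaustive path
# enumeration (independent of scope_of)
brute_scope <- function(ps, id) {
  kids <- function(i) {
    args <- pred_args(ps$predications[[i]])
    unlist(lapply(args, function(a)
      if (a$kind == "predication") a$ref else character(0)))
  }
  paths <- list(id)
  reached <- character(0)
  while (length(paths)) {
    p <- paths[[1]]; paths <- paths[-1]
    for (k in kids(p[length(p)])) {
      if (k %in% p) stop("cycle")
      reached <- c(reached, k)
      paths[[length(paths) + 1]] <- c(p, k)
    }
  }
  unique(reached)
}

# build a random predication forest directly (no graph), for scope tests
random_pred_forest <- function(seed, n = 6) {
  set.seed(seed)
  preds <- list()
  for (i in seq_len(n)) {
    kids <- if (i > 1) sample(seq_len(i - 1), sample(0:min(2, i - 1), 1))
            else integer(0)
    args <- lapply(kids, function(k) pred_arg("predication", sprintf("q%d", k)))
    ent <- if (runif(1) < 0.5) list(pred_arg("entity", sprintf("T%d", i)))
           else list()
    aa <- c(args, ent)
    preds[[i]] <- new_predication(
      id = sprintf("q%d", i), node = sprintf("n%d", i),
      lemma = sprintf("w%d", i), sem_type = "CAUSAL",
      klass = if (length(args)) "relational" else "atomic",
      object = if (length(aa)) aa[[1]] else NULL,
      subject = if (length(aa) > 1) aa[[2]] else NULL,
      adjuncts = if (length(aa) > 2) aa[-(1:2)] else list())
  }
  predication_set(preds)
}

fixture_result <- local({
  cache <- new.env(parent = emptyenv())
  function(name) {
    if (is.null(cache[[name]])) {
      cache[[name]] <- run_fixture(builtin_cases()[[name]])
    }
    cache[[name]]
  }
})
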