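# Built-in worked-example fixtures and the random-graph generator used for
# oracle testing. Dependency parses are transcribed from the worked
# examples where printed and minimally authored elsewhere (marked
# "authored"); fixture text is detokenized with single spaces so character
# offsets are reproducible.

parse_dep_spec <- function(spec) {
  if (!nzchar(trimws(spec)))
    return(data.frame(label = character(0), gov = integer(0),
                      dep = integer(0), stringsAsFactors = FALSE))
  items <- trimws(strsplit(spec, ";", fixed = TRUE)[[1]])
  items <- items[nzchar(items)]
  m <- regmatches(items, regexec("^([A-Za-z_]+)\\((\\d+),(\\d+)\\)$", items))
  bad <- which(lengths(m) != 4)
  if (length(bad)) stop("bad dependency spec: ", items[bad[1]])
  data.frame(label = vapply(m, `[`, character(1), 2),
             gov = as.integer(vapply(m, `[`, character(1), 3)),
             dep = as.integer(vapply(m, `[`, character(1), 4)),
             stringsAsFactors = FALSE)
}

mk_sentence <- function(forms, pos, deps, lemma = NULL) {
  forms <- strsplit(forms, " ", fixed = TRUE)[[1]]
  pos <- strsplit(pos, " ", fixed = TRUE)[[1]]
  stopifnot(length(forms) == length(pos))
  lemmas <- tolower(forms)
  if (!is.null(lemma)) {
    for (nm in names(lemma)) lemmas[as.integer(nm)] <- lemma[[nm]]
  }
  list(tokens = data.frame(idx = seq_along(forms), form = forms,
                           lemma = lemmas, pos = pos,
                           start = NA_integer_, end = NA_integer_,
                           stringsAsFactors = FALSE),
       deps = parse_dep_spec(deps))
}

# assemble a fixture case: join sentences into a document (single spaces),
# compute token offsets, and resolve entity token spans to offsets
mk_case <- function(name, modules, sentences, entities = list(),
                    hypernyms_extra = character(0), note = "authored") {
  cursor <- 0L
  texts <- character(length(sentences))
  for (i in seq_along(sentences)) {
    tk <- sentences[[i]]$tokens
    starts <- integer(nrow(tk))
    for (j in seq_len(nrow(tk))) {
      starts[j] <- cursor
      cursor <- cursor + nchar(tk$form[j]) + 1L
    }
    sentences[[i]]$tokens$start <- starts
    sentences[[i]]$tokens$end <- starts + nchar(tk$form)
    texts[i] <- paste(tk$form, collapse = " ")
  }
  text <- paste(texts, collapse = " ")
  ents <- empty_entities()
  for (k in seq_along(entities)) {
    e <- entities[[k]]
    tk <- sentences[[e$sent]]$tokens
    start <- tk$start[e$from]
    end <- tk$end[e$to]
    ents <- rbind(ents, data.frame(
      id = sprintf("T%d", k), type = e$type, start = start, end = end,
      text = substring(text, start + 1, end), stringsAsFactors = FALSE))
  }
  structure(list(name = name, modules = modules, text = text,
                 sentences = sentences, entities = ents,
                 hypernyms_extra = hypernyms_extra, note = note),
            class = "fixture_case")
}

#' @export
print.fixture_case <- function(x, ...) {
  cat(sprintf("<fixture_case %s (%s): %d sentence(s), %d entities>\n",
              x$name, paste(x$modules, collapse = ","),
              length(x$sentences), nrow(x$entities)))
  invisible(x)
}

#' Built-in worked-example fixtures
#'
#' Encodes the worked examples the package's rule set is validated against:
#' the NP-internal, coordination, inversion and corrective transformations;
#' the causal/assumptive/saliency/temporal sentence; modality chains
#' (`may not involve`); argument propagation (`bound ... to the site of the
#' IL-10 promoter`); the demonstrative-over-causal sentence with its
#' expected two-event standoff output; and the coreference examples
#' (pronominal, set-instance, sortal, appositive). Each case carries the
#' module tags it exercises; dependencies are transcribed where the source
#' example prints them and authored minimally otherwise.
#'
#' @return named list of `fixture_case` objects.
#' @export
builtin_cases <- function() {
  cases <- list(
    mk_case("t3r1", c("graph_construction"),
            list(mk_sentence("CD40 ligand interactions play a key role .",
                             "NN NN NNS VBP DT JJ NN .",
                             "nn(3,2); nn(3,1); nsubj(4,3); dobj(4,7); det(7,5); amod(7,6)",
                             lemma = c("3" = "interaction", "4" = "play"))),
            list(list(type = "Protein", sent = 1, from = 1, to = 2))),
    mk_case("t3r2", c("graph_construction"),
            list(mk_sentence("It specifically binds and phosphorylates IkBa .",
                             "PRP RB VBZ CC VBZ NN .",
                             "nsubj(3,1); advmod(3,2); conj_and(3,5); dobj(3,6); dobj(5,6)",
                             lemma = c("3" = "bind", "5" = "phosphorylate"))),
            list(list(type = "Protein", sent = 1, from = 6, to = 6))),
    mk_case("t3r3", c("graph_construction"),
            list(mk_sentence("possible involvement of HCMV .",
                             "JJ NN IN NN .",
                             "amod(2,1); prep_of(2,4)")),
            list(list(type = "Organism", sent = 1, from = 4, to = 4))),
    mk_case("t3r4", c("graph_construction"),
            list(mk_sentence("Tat and Sp1 proteins bind DNA .",
                             "NN CC NN NNS VBP NN .",
                             "nn(4,3); conj_and(1,4); nsubj(5,4); dobj(5,6)",
                             lemma = c("4" = "protein", "5" = "bind"))),
            list(list(type = "Protein", sent = 1, from = 1, to = 1),
                 list(type = "Protein", sent = 1, from = 3, to = 3))),
    mk_case("fig2", c("graph_construction", "composition", "task_mapping"),
            list(mk_sentence(
              "Stimulation of cells leads to a rapid phosphorylation of IkBa , which is presumed to be important for the subsequent degradation .",
              "NN IN NNS VBZ TO DT JJ NN IN NN , WDT VBZ VBN TO VB JJ IN DT JJ NN .",
              paste("nsubj(4,1); prep_of(1,3); prep_to(4,8); amod(8,7);",
                    "prep_of(8,10); rcmod(8,14); rel(14,12); auxpass(14,13);",
                    "xcomp(14,17); xsubj(17,12); prep_for(17,21); det(21,19);",
                    "amod(21,20)"),
              lemma = c("3" = "cell", "4" = "lead", "13" = "be",
                        "14" = "presume", "16" = "be"))),
            list(list(type = "Protein", sent = 1, from = 10, to = 10))),
    mk_case("ex8", c("composition", "task_mapping"),
            list(mk_sentence("p105 undergoes degradation .",
                             "NN VBZ NN .", "nsubj(2,1); dobj(2,3)",
                             lemma = c("2" = "undergo"))),
            list(list(type = "Protein", sent = 1, from = 1, to = 1))),
    mk_case("ex11", c("composition"),
            list(mk_sentence("Overexpression leads to the prevention of expression .",
                             "NN VBZ TO DT NN IN NN .",
                             "nsubj(2,1); prep_to(2,5); det(5,4); prep_of(5,7)",
                             lemma = c("2" = "lead"))),
            list()),
    mk_case("ex12", c("graph_construction", "composition"),
            list(mk_sentence(
              "Thus , IL-10 upregulation in monocytes may not involve NF-kB activation .",
              "RB , NN NN IN NNS MD RB VB NN NN .",
              paste("advmod(9,1); aux(9,7); neg(9,8); nsubj(9,4); nn(4,3);",
                    "prep_in(4,6); dobj(9,11); nn(11,10)"),
              lemma = c("6" = "monocyte"))),
            list(list(type = "Protein", sent = 1, from = 3, to = 3),
                 list(type = "Protein", sent = 1, from = 10, to = 10))),
    mk_case("ex13", c("composition"),
            list(mk_sentence(
              "no NF-kB bound to the main site of the IL-10 promoter after addition of gp41 .",
              "DT NN VBD TO DT JJ NN IN DT NN NN IN NN IN NN .",
              "prep_to(3,7); prep_of(7,11); nn(11,10); prep_after(3,13); prep_of(13,15)",
              lemma = c("3" = "bind"))),
            list(list(type = "Protein", sent = 1, from = 10, to = 10),
                 list(type = "Protein", sent = 1, from = 15, to = 15))),
    mk_case("ex14", c("composition", "task_mapping", "standoff_io"),
            list(mk_sentence(
              "Our previous results show that recombinant gp41 , the extracellular domain of HIV-1 transmembrane glycoprotein , stimulates interleukin-10 ( IL-10 ) production in human monocytes .",
              "PRP$ JJ NNS VBP IN JJ NN , DT JJ NN IN NN JJ NN , VBZ NN -LRB- NN -RRB- NN IN JJ NNS .",
              paste("poss(3,1); nsubj(4,3); ccomp(4,17); nsubj(17,7);",
                    "amod(7,6); appos(7,11); det(11,9); amod(11,10);",
                    "prep_of(11,15); nn(15,13); amod(15,14); dobj(17,22);",
                    "nn(22,18); abbrev(18,20); prep_in(22,25); amod(25,24)"),
              lemma = c("3" = "result", "17" = "stimulate",
                        "25" = "monocyte"))),
            list(list(type = "Protein", sent = 1, from = 7, to = 7),
                 list(type = "Protein", sent = 1, from = 18, to = 18),
                 list(type = "Protein", sent = 1, from = 20, to = 20))),
    mk_case("ex16", c("coreference", "composition"),
            list(mk_sentence("Eotaxin is a beta-chemokine .",
                             "NN VBZ DT NN .",
                             "nsubj(4,1); cop(4,2); det(4,3)",
                             lemma = c("2" = "be")),
                 mk_sentence("Its expression is stimulus-specific .",
                             "PRP$ NN VBZ JJ .",
                             "poss(2,1); nsubj(4,2); cop(4,3)",
                             lemma = c("3" = "be"))),
            list(list(type = "Protein", sent = 1, from = 1, to = 1))),
    mk_case("ex23", c("coreference", "composition"),
            list(mk_sentence(
              "Although GATA3 and FOXP3 showed similar kinetics , their expression polarizes at the end .",
              "IN NN CC NN VBD JJ NNS , PRP$ NN VBZ IN DT NN .",
              paste("mark(5,1); nsubj(5,2); conj_and(2,4); dobj(5,7);",
                    "amod(7,6); poss(10,9); nsubj(11,10); advcl(11,5);",
                    "prep_at(11,14); det(14,13)"),
              lemma = c("5" = "show", "7" = "kinetic", "11" = "polarize"))),
            list(list(type = "Protein", sent = 1, from = 2, to = 2),
                 list(type = "Protein", sent = 1, from = 4, to = 4))),
    mk_case("ex24", c("coreference", "composition"),
            list(mk_sentence("APOBEC3G is expressed in lymphocytes .",
                             "NN VBZ VBN IN NNS .",
                             "nsubjpass(3,1); auxpass(3,2); prep_in(3,5)",
                             lemma = c("2" = "be", "3" = "express",
                                       "5" = "lymphocyte")),
                 mk_sentence(
                   "We studied the transcriptional regulation of this restriction factor .",
                   "PRP VBD DT JJ NN IN DT NN NN .",
                   paste("nsubj(2,1); dobj(2,5); det(5,3); amod(5,4);",
                         "prep_of(5,9); det(9,7); nn(9,8)"),
                   lemma = c("2" = "study"))),
            list(list(type = "Protein", sent = 1, from = 1, to = 1))),
    mk_case("ex25", c("coreference", "composition"),
            list(mk_sentence(
              "CD3 , CD2 , and CD28 are receptors on T lymphocytes .",
              "NN , NN , CC NN VBP NNS IN NN NNS .",
              paste("conj_and(1,3); conj_and(1,6); nsubj(8,1); cop(8,7);",
                    "prep_on(8,11); nn(11,10)"),
              lemma = c("7" = "be", "8" = "receptor", "11" = "lymphocyte")),
                 mk_sentence(
                   "Engagement of any of these receptors induces phosphorylation of proteins .",
                   "NN IN DT IN DT NNS VBZ NN IN NNS .",
                   paste("prep_of(1,3); prep_of(3,6); det(6,5); nsubj(7,1);",
                         "dobj(7,8); prep_of(8,10)"),
                   lemma = c("6" = "receptor", "7" = "induce",
                             "10" = "protein"))),
            list(list(type = "Protein", sent = 1, from = 1, to = 1),
                 list(type = "Protein", sent = 1, from = 3, to = 3),
                 list(type = "Protein", sent = 1, from = 6, to = 6)),
            hypernyms_extra = "receptor"),
    mk_case("ex26", c("coreference", "composition"),
            list(mk_sentence(
              "Runx1 activates IL-2 and IFN-gamma expression by binding to their promoters .",
              "NN VBZ NN CC NN NN IN VBG TO PRP$ NNS .",
              paste("nsubj(2,1); dobj(2,6); nn(6,3); conj_and(3,5); nn(6,5);",
                    "prepc_by(2,8); xsubj(8,1); prep_to(8,11); poss(11,10)"),
              lemma = c("2" = "activate", "8" = "bind", "11" = "promoter"))),
            list(list(type = "Protein", sent = 1, from = 1, to = 1),
                 list(type = "Protein", sent = 1, from = 3, to = 3),
                 list(type = "Protein", sent = 1, from = 5, to = 5))),
    mk_case("ex27", c("coreference", "composition"),
            list(mk_sentence(
              "The PKD family has three members : PKD1 , PKD2 , and PKD3 .",
              "DT NN NN VBZ CD NNS : NN , NN , CC NN .",
              paste("det(3,1); nn(3,2); nsubj(4,3); dobj(4,6); num(6,5);",
                    "appos(6,8); conj_and(8,10); conj_and(8,13)"),
              lemma = c("4" = "have", "6" = "member")),
                 mk_sentence(
                   "PKD enzymes are expressed in cells , where they are activated .",
                   "NN NNS VBP VBN IN NNS , WRB PRP VBP VBN .",
                   paste("nn(2,1); nsubjpass(4,2); auxpass(4,3); prep_in(4,6);",
                         "rcmod(6,11); advmod(11,8); nsubjpass(11,9);",
                         "auxpass(11,10)"),
                   lemma = c("2" = "enzyme", "3" = "be", "4" = "express",
                             "6" = "cell", "10" = "be", "11" = "activate"))),
            list(list(type = "Protein", sent = 1, from = 8, to = 8),
                 list(type = "Protein", sent = 1, from = 10, to = 10),
                 list(type = "Protein", sent = 1, from = 13, to = 13))),
    mk_case("ex7", c("composition", "task_mapping"),
            list(mk_sentence("gp41 failed to stimulate production of IL-10 .",
                             "NN VBD TO VB NN IN NN .",
                             paste("nsubj(2,1); xcomp(2,4); aux(4,3);",
                                   "xsubj(4,1); dobj(4,5); prep_of(5,7)"),
                             lemma = c("2" = "fail"))),
            list(list(type = "Protein", sent = 1, from = 1, to = 1),
                 list(type = "Protein", sent = 1, from = 7, to = 7))),
    mk_case("apposarg", c("coreference", "composition"),
            list(mk_sentence("interleukin-10 ( IL-10 ) production increased .",
                             "NN -LRB- NN -RRB- NN VBD .",
                             "abbrev(1,3); nn(5,3); nsubj(6,5)",
                             lemma = c("6" = "increase"))),
            list(list(type = "Protein", sent = 1, from = 1, to = 1))),
    mk_case("negraise", c("composition"),
            list(mk_sentence("We do not think that gp41 stimulates production .",
                             "PRP VBP RB VB IN NN VBZ NN .",
                             paste("nsubj(4,1); aux(4,2); neg(4,3);",
                                   "ccomp(4,7); nsubj(7,6); dobj(7,8)"),
                             lemma = c("7" = "stimulate"))),
            list(list(type = "Protein", sent = 1, from = 6, to = 6)))
  )
  stats::setNames(cases, vapply(cases, `[[`, character(1), "name"))
}

#' Build the embedding graph and configuration for a fixture case
#'
#' @param case a `fixture_case`.
#' @param config base configuration; the case's hypernym extensions are
#'   applied on top.
#' @return list with `graph` (coreference already resolved), `config`,
#'   `doc`.
#' @export
fixture_graph <- function(case, config = compose_config()) {
  if (length(case$hypernyms_extra)) {
    config$compat_lexicons$hypernyms <-
      unique(c(config$compat_lexicons$hypernyms, case$hypernyms_extra))
  }
  subgraphs <- lapply(seq_along(case$sentences), function(i) {
    s <- case$sentences[[i]]
    build_sentence_graph(s$tokens, s$deps, case$entities, config$lexicon,
                         sentence = i, opts = config$graph_opts)
  })
  graph <- link_sentences(subgraphs, case$text, case$entities, case$name)
  graph <- resolve_coreference(graph, config$coref_classes,
                               config$compat_lexicons)
  list(graph = graph, config = config,
       doc = structure(list(doc_id = case$name, text = case$text,
                            entities = case$entities),
                       class = "standoff_document"))
}

#' Run the full pipeline on a fixture case
#'
#' @param case a `fixture_case`.
#' @param config base configuration (case hypernym extensions applied).
#' @return the [extract_events()] result list.
#' @export
run_fixture <- function(case, config = compose_config()) {
  fx <- fixture_graph(case, config)
  ps <- compose_document(fx$graph, fx$config)
  es <- map_events(ps, fx$config)
  a2 <- write_a2(es, case$entities)
  list(doc = fx$doc, graph = fx$graph, predications = ps, events = es,
       a2 = a2)
}

#' Write a fixture case as standoff files
#'
#' Emits `<name>.txt`, `<name>.a1` and `<name>.dep` (CoNLL dialect; rows
#' with a repeated token index carry additional dependencies) so fixture
#' cases can exercise the file-based pipeline.
#'
#' @param case a `fixture_case`.
#' @param dir output directory.
#' @return the `.txt` path, invisibly.
#' @export
write_case_files <- function(case, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  txt <- file.path(dir, paste0(case$name, ".txt"))
  writeLines(case$text, txt)
  a1 <- vapply(seq_len(nrow(case$entities)), function(k) {
    e <- case$entities[k, ]
    sprintf("%s\t%s %d %d\t%s", e$id, e$type, e$start, e$end, e$text)
  }, character(1))
  writeLines(a1, file.path(dir, paste0(case$name, ".a1")))
  blocks <- vapply(case$sentences, function(s) {
    tk <- s$tokens; dp <- s$deps
    gov <- stats::setNames(rep(0L, nrow(tk)), tk$idx)
    lab <- stats::setNames(rep("root", nrow(tk)), tk$idx)
    extra <- character(0)
    seen <- logical(nrow(tk))
    for (r in seq_len(nrow(dp))) {
      d <- dp$dep[r]
      if (!seen[d]) {
        gov[as.character(d)] <- dp$gov[r]
        lab[as.character(d)] <- dp$label[r]
        seen[d] <- TRUE
      } else {
        extra <- c(extra, sprintf("%d\t%s\t%s\t%s\t%d\t%s", d, tk$form[d],
                                  tk$lemma[d], tk$pos[d], dp$gov[r],
                                  dp$label[r]))
      }
    }
    rows <- sprintf("%d\t%s\t%s\t%s\t%d\t%s", tk$idx, tk$form, tk$lemma,
                    tk$pos, gov[as.character(tk$idx)],
                    lab[as.character(tk$idx)])
    paste(c(rows, extra), collapse = "\n")
  }, character(1))
  writeLines(paste(blocks, collapse = "\n\n"),
             file.path(dir, paste0(case$name, ".dep")))
  invisible(txt)
}

# ---------------------------------------------------------------------------
# Random embedding graphs with a known generator state (oracle testing)
# ---------------------------------------------------------------------------

#' Generate a small random embedding graph
#'
#' Produces a random tree-shaped embedding graph over at most `size` nodes
#' with randomly bound nodes (entities, free elements, atomic and embedding
#' triggers, negators, diminishers) and rule-licensing arc labels. Used to
#' cross-check the composer against the independent recursive evaluator
#' ([compose_oracle()]); reproducible from the seed.
#'
#' @param seed integer seed.
#' @param size number of nodes (at most 12).
#' @return an `embedding_graph`.
#' @export
random_graph <- function(seed, size = 8) {
  stopifnot(size >= 1, size <= 12)
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(old())
  roles <- c("entity", "free", "atomic", "embedding", "negator", "shifter")
  probs <- c(0.28, 0.22, 0.20, 0.18, 0.07, 0.05)
  atomic_types <- c("GENE_EXPRESSION", "PHOSPHORYLATION", "BINDING")
  embed_types <- c("CAUSAL", "SPECULATIVE", "SUCCESS", "SALIENCY")
  labels <- c("DOBJ", "NSUBJ", "XCOMP", "PREP_TO", "PREP_AFTER", "CCOMP")
  n <- size
  nodes <- empty_nodes()
  ent_count <- 0L
  for (i in seq_len(n)) {
    role <- sample(roles, 1, prob = probs)
    binding <- switch(role, entity = "entity", free = "free", "predicate")
    sem <- switch(role,
                  entity = NA_character_, free = NA_character_,
                  atomic = sample(atomic_types, 1),
                  embedding = sample(embed_types, 1),
                  negator = "NEGATOR",
                  shifter = sample(c("DIMINISHER", "INTENSIFIER"), 1))
    if (role == "entity") ent_count <- ent_count + 1L
    nodes <- rbind(nodes, data.frame(
      id = sprintf("n%d", i), sentence = 1L, first_idx = i, last_idx = i,
      start = (i - 1L) * 10L, end = (i - 1L) * 10L + 5L,
      text = sprintf("w%d", i), lemma = sprintf("w%d", i),
      pos = if (binding == "predicate") "VB" else "NN",
      binding = binding,
      ref = if (role == "entity") sprintf("T%d", ent_count) else NA_character_,
      sem_type = sem,
      polarity = if (binding == "predicate" && role != "negator")
        sample(POLARITIES, 1) else if (role == "negator") "negative"
        else NA_character_,
      strength = if (binding != "predicate") NA_real_
        else if (role == "atomic") 1.0
        else sample(c(0.3, 0.5, 0.7, 1.0), 1),
      negative_raising = FALSE, conj = FALSE, stringsAsFactors = FALSE))
  }
  arcs <- empty_arcs()
  if (n > 1) {
    for (i in 2:n) {
      parent <- sample(seq_len(i - 1), 1)
      arcs <- rbind(arcs, data.frame(
        type = sample(labels, 1), source = sprintf("n%d", parent),
        target = sprintf("n%d", i), stringsAsFactors = FALSE))
    }
  }
  entities <- nodes[nodes$binding == "entity",
                    c("id", "ref", "start", "end", "text")]
  ents <- if (nrow(entities)) {
    data.frame(id = entities$ref, type = "Protein", start = entities$start,
               end = entities$end, text = entities$text,
               stringsAsFactors = FALSE)
  } else empty_entities()
  structure(list(nodes = nodes, arcs = arcs,
                 sentences = data.frame(sentence = 1L,
                                        root = "n1", paragraph = 1L),
                 entities = ents, text = "", doc_id = sprintf("rg%d", seed)),
            class = "embedding_graph")
}

# save/restore RNG state so fixture generation does not disturb callers
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    function() assign(".Random.seed", old, envir = globalenv())
  } else {
    function() suppressWarnings(
      rm(".Random.seed", envir = globalenv()))
  }
}
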