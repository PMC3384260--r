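# Deterministic coreference resolution over the embedding graph:
# RELAT (relative pronouns), APPOS (appositive family), PRON (third-person
# personal/possessive pronouns), DNP (definite/demonstrative NPs).

PRON_LEMMAS <- c(it = "singular", its = "singular", itself = "singular",
                 they = "plural", their = "plural", themselves = "plural")
REFLEXIVES <- c("itself", "themselves")
DNP_DETS <- c(the = "any", this = "singular", that = "singular",
              these = "plural", those = "plural")
APPOS_TYPES <- c("APPOS", "ABBREV", "PREP_INCLUDING", "PREP_SUCH_AS")
SUBJECT_ARCS <- c("NSUBJ", "XSUBJ", "AGENT")
OBJECT_ARCS <- c("DOBJ", "NSUBJPASS", "IOBJ")

#' Compatibility lexicons for sortal anaphora
#'
#' Hypernym head nouns license `this protein`-style anaphora over entity
#' antecedents; meronym head nouns license `the dimer`-style anaphora over
#' conjunctions of entities. Defaults ship with the package; larger lists
#' induced from a corpus can be supplied as files (one lowercase lemma per
#' line, `#` comments).
#'
#' @param hypernyms character vector or file path.
#' @param meronyms character vector or file path.
#' @return list with `hypernyms` and `meronyms` character vectors.
#' @export
compat_lexicons <- function(hypernyms = NULL, meronyms = NULL) {
  read_list <- function(x, default_file) {
    if (is.null(x))
      x <- system.file("extdata", default_file, package = "bioscope")
    if (length(x) == 1 && file.exists(x)) {
      x <- readLines(x, warn = FALSE)
      x <- trimws(sub("#.*$", "", x))
      x <- x[nzchar(x)]
    }
    tolower(x)
  }
  h <- read_list(hypernyms, "hypernyms.txt")
  m <- read_list(meronyms, "meronyms.txt")
  stopifnot(length(h) > 0, length(m) > 0)
  list(hypernyms = h, meronyms = m)
}

#' Resolve relative-pronoun coreference (RELAT)
#'
#' The antecedent of a relative pronominal anaphor is the noun-phrase head
#' its clause modifies: `REL(X, RP)` together with `RCMOD(ANT, X)` yields
#' `COREF(RP, ANT)`.
#'
#' @param graph an `embedding_graph`.
#' @return data.frame of COREF arcs (may be empty).
#' @export
resolve_relat <- function(graph) {
  a <- graph$arcs
  rel <- a[a$type == "REL", , drop = FALSE]
  out <- empty_arcs()
  for (r in seq_len(nrow(rel))) {
    x <- rel$source[r]; rp <- rel$target[r]
    ant <- a$source[a$type == "RCMOD" & a$target == x]
    for (an in ant) {
      out <- rbind(out, data.frame(type = "COREF", source = rp, target = an,
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

#' Resolve appositive-family coreference (APPOS)
#'
#' Appositions, abbreviations and `including`/`such as` constructions
#' corefer regardless of argument order; the arc is normalized so the
#' textually later element is the anaphor.
#'
#' @param graph an `embedding_graph`.
#' @return data.frame of COREF arcs.
#' @export
resolve_appos <- function(graph) {
  a <- graph$arcs
  ap <- a[a$type %in% APPOS_TYPES, , drop = FALSE]
  out <- empty_arcs()
  for (r in seq_len(nrow(ap))) {
    u <- ap$source[r]; v <- ap$target[r]
    su <- graph_node(graph, u)$start
    sv <- graph_node(graph, v)$start
    ana <- if (sv >= su) v else u
    ant <- if (sv >= su) u else v
    out <- rbind(out, data.frame(type = "COREF", source = ana, target = ant,
                                 stringsAsFactors = FALSE))
  }
  unique(out)
}

node_number <- function(graph, id) {
  nd <- graph_node(graph, id)
  if (isTRUE(nd$conj)) return("plural")
  if (!is.na(nd$lemma) && nd$lemma %in% names(PRON_LEMMAS))
    return(unname(PRON_LEMMAS[[nd$lemma]]))
  if (!is.na(nd$pos) && nd$pos %in% c("NNS", "NNPS")) return("plural")
  "singular"
}

#' Identify PRON and DNP anaphoric mentions
#'
#' PRON: third-person personal and possessive pronouns only. DNP (sortal
#' anaphora): noun phrases introduced by a definite or demonstrative
#' determiner that are not associated with entities.
#'
#' @param graph an `embedding_graph`.
#' @return data.frame with `node`, `klass`, `number`, `reflexive`,
#'   `head_lemma`.
#' @export
find_anaphors <- function(graph) {
  nodes <- graph$nodes
  arcs <- graph$arcs
  out <- data.frame(node = character(0), klass = character(0),
                    number = character(0), reflexive = logical(0),
                    head_lemma = character(0), stringsAsFactors = FALSE)
  pron <- nodes$lemma %in% names(PRON_LEMMAS) & nodes$binding == "free"
  for (i in which(pron)) {
    out <- rbind(out, data.frame(
      node = nodes$id[i], klass = "PRON",
      number = PRON_LEMMAS[[nodes$lemma[i]]],
      reflexive = nodes$lemma[i] %in% REFLEXIVES,
      head_lemma = nodes$lemma[i], stringsAsFactors = FALSE))
  }
  # DNP: DET arc from a definite/demonstrative determiner to a non-entity NP
  det <- arcs[arcs$type == "DET", , drop = FALSE]
  for (r in seq_len(nrow(det))) {
    d <- graph_node(graph, det$source[r])
    h <- graph_node(graph, det$target[r])
    if (is.na(d$lemma) || !(d$lemma %in% names(DNP_DETS))) next
    if (is.na(h$pos) || !startsWith(h$pos, "NN")) next
    if (h$binding == "entity") next
    num <- DNP_DETS[[d$lemma]]
    if (num == "any") num <- node_number(graph, h$id)
    out <- rbind(out, data.frame(
      node = h$id, klass = "DNP", number = num, reflexive = FALSE,
      head_lemma = h$lemma, stringsAsFactors = FALSE))
  }
  out
}

coref_distances <- function(graph, from) {
  a <- graph_arcs(graph, "linked")
  if (!nrow(a)) return(stats::setNames(rep(Inf, nrow(graph$nodes)),
                                       graph$nodes$id))
  g <- igraph::graph_from_data_frame(a[, c("source", "target")],
                                     directed = FALSE,
                                     vertices = data.frame(name = graph$nodes$id))
  d <- igraph::distances(g, v = from, to = igraph::V(g))
  stats::setNames(as.numeric(d[1, ]), colnames(d))
}

conjunct_nodes <- function(graph, id) {
  graph$arcs$target[graph$arcs$type == "CC" & graph$arcs$source == id]
}

conj_of_entities <- function(graph, id) {
  cj <- conjunct_nodes(graph, id)
  length(cj) > 0 &&
    all(graph$nodes$binding[match(cj, graph$nodes$id)] == "entity")
}

#' Candidate antecedents for a PRON/DNP anaphor
#'
#' Candidates are embedding-graph nodes appearing before the anaphor in the
#' discourse (the anaphor's sentence and the sentences preceding it in the
#' same paragraph) that are semantically bound, hypernym heads, or
#' conjunction nodes. Candidates are ordered by increasing undirected graph
#' distance (intra-sentential + PREV arcs), with token distance and then
#' earlier offset as tie-breaks.
#'
#' @param anaphor one row of [find_anaphors()] output (list or data.frame
#'   row).
#' @param graph an `embedding_graph`.
#' @param lexicons [compat_lexicons()].
#' @return character vector of node ids, nearest first.
#' @export
candidate_antecedents <- function(anaphor, graph,
                                  lexicons = compat_lexicons()) {
  nodes <- graph$nodes
  an <- graph_node(graph, anaphor$node)
  para <- graph$sentences$paragraph[match(an$sentence,
                                          graph$sentences$sentence)]
  sent_ok <- graph$sentences$sentence[graph$sentences$paragraph == para |
                                        is.na(graph$sentences$paragraph)]
  prior <- nodes$start < an$start & nodes$sentence %in% sent_ok &
    nodes$id != an$id
  eligible <- prior & (nodes$binding != "free" |
                         nodes$lemma %in% lexicons$hypernyms |
                         nodes$conj)
  cand <- nodes$id[eligible]
  if (!length(cand)) return(character(0))
  d <- coref_distances(graph, an$id)
  gd <- d[cand]
  gd[is.na(gd)] <- Inf
  td <- abs(an$start - nodes$start[match(cand, nodes$id)])
  keep <- is.finite(gd)
  cand <- cand[keep]; gd <- gd[keep]; td <- td[keep]
  cand[order(gd, td, nodes$start[match(cand, nodes$id)])]
}

same_event_stem <- function(a, b) {
  strip <- function(x) sub("(ations?|ation|tions?|ions?|ing|ed|es|s|d)$", "", x)
  strip(a) == strip(b) || startsWith(a, strip(b)) || startsWith(b, strip(a))
}

#' Syntactic/semantic compatibility of an anaphor-candidate pair
#'
#' PRON requires person and number agreement (candidates are third person by
#' construction). DNP requires number agreement plus at least one of: head
#' word identity, singular hypernymy (entity antecedent), plural hypernymy
#' (conjunction-of-entities antecedent, i.e. set-instance anaphora),
#' meronymy, or the event constraint (anaphor and antecedent lexicalize the
#' same event type).
#'
#' @param anaphor anaphor record (row of [find_anaphors()]).
#' @param candidate candidate node id.
#' @param graph an `embedding_graph`.
#' @param lexicons [compat_lexicons()].
#' @return logical.
#' @export
antecedent_compatible <- function(anaphor, candidate, graph,
                                  lexicons = compat_lexicons()) {
  cn <- graph_node(graph, candidate)
  num_ok <- node_number(graph, candidate) == anaphor$number
  if (anaphor$klass == "PRON") return(num_ok)
  if (!num_ok) return(FALSE)
  head <- anaphor$head_lemma
  # head word constraint
  if (!is.na(cn$lemma) &&
      (cn$lemma == head || endsWith(cn$lemma, paste0(" ", head))))
    return(TRUE)
  hyper <- head %in% lexicons$hypernyms
  if (hyper && anaphor$number == "singular" && cn$binding == "entity")
    return(TRUE)
  if (hyper && anaphor$number == "plural" && conj_of_entities(graph, candidate))
    return(TRUE)
  if (head %in% lexicons$meronyms &&
      (conj_of_entities(graph, candidate) ||
         (cn$binding == "entity" && grepl("/", cn$text, fixed = TRUE))))
    return(TRUE)
  # event constraint: both heads are triggers lexicalizing the same event
  anode <- graph_node(graph, anaphor$node)
  if (anode$binding == "predicate" && cn$binding == "predicate" &&
      identical(anode$sem_type, cn$sem_type) &&
      same_event_stem(anode$lemma, cn$lemma))
    return(TRUE)
  FALSE
}

#' Structural blocking of an anaphor-candidate pair
#'
#' A candidate is blocked if (1) it directly embeds or is directly embedded
#' by the anaphor, (2) it is the subject and the anaphor the object of the
#' same predicate and the anaphor is not reflexive, or (3) the anaphor is in
#' an adjunct position and the candidate in subject position of the same
#' predicate.
#'
#' @param anaphor anaphor record.
#' @param candidate candidate node id.
#' @param graph an `embedding_graph`.
#' @return logical.
#' @export
antecedent_blocked <- function(anaphor, candidate, graph) {
  a <- graph_arcs(graph, "linked")
  an <- anaphor$node
  direct <- any((a$source == an & a$target == candidate) |
                  (a$source == candidate & a$target == an))
  if (direct) return(TRUE)
  parents_c <- a[a$target == candidate, , drop = FALSE]
  parents_a <- a[a$target == an, , drop = FALSE]
  shared <- intersect(parents_c$source, parents_a$source)
  for (p in shared) {
    c_lab <- parents_c$type[parents_c$source == p]
    a_lab <- parents_a$type[parents_a$source == p]
    if (any(c_lab %in% SUBJECT_ARCS) && any(a_lab %in% OBJECT_ARCS) &&
        !isTRUE(anaphor$reflexive)) return(TRUE)
    if (any(c_lab %in% SUBJECT_ARCS) && any(startsWith(a_lab, "PREP")))
      return(TRUE)
  }
  FALSE
}

#' Resolve pronominal and sortal anaphora (PRON/DNP)
#'
#' For each anaphor the closest compatible unblocked candidate in the
#' embedding graph is selected. A plural anaphor resolved to a conjunction
#' node yields one COREF arc per bound conjunct.
#'
#' @param graph an `embedding_graph`.
#' @param lexicons [compat_lexicons()].
#' @param classes subset of `c("pron", "dnp")` to resolve.
#' @return data.frame of COREF arcs.
#' @export
resolve_pron_dnp <- function(graph, lexicons = compat_lexicons(),
                             classes = c("pron", "dnp")) {
  anaphors <- find_anaphors(graph)
  if (nrow(anaphors)) {
    anaphors <- anaphors[tolower(anaphors$klass) %in% classes, , drop = FALSE]
  }
  out <- empty_arcs()
  for (i in seq_len(nrow(anaphors))) {
    ana <- as.list(anaphors[i, ])
    cands <- candidate_antecedents(ana, graph, lexicons)
    sel <- NULL
    for (cd in cands) {
      if (!antecedent_compatible(ana, cd, graph, lexicons)) next
      if (antecedent_blocked(ana, cd, graph)) next
      sel <- cd
      break
    }
    if (is.null(sel)) next
    targets <- sel
    if (isTRUE(graph_node(graph, sel)$conj) && ana$number == "plural") {
      cj <- conjunct_nodes(graph, sel)
      bound <- cj[graph$nodes$binding[match(cj, graph$nodes$id)] != "free"]
      if (length(bound)) targets <- bound
    }
    for (tg in targets) {
      out <- rbind(out, data.frame(type = "COREF", source = ana$node,
                                   target = tg, stringsAsFactors = FALSE))
    }
  }
  out
}

#' Add COREF arcs to an embedding graph
#'
#' Runs the enabled coreference classes and appends the resulting arcs.
#' COREF arcs always point from the anaphor back to an earlier (or
#' same-sentence) node and are excluded from scope computation, so the
#' non-COREF subgraph stays acyclic.
#'
#' @param graph an `embedding_graph`.
#' @param classes subset of `c("relat", "appos", "pron", "dnp")`; `"all"`
#'   and `"none"` shortcuts accepted.
#' @param lexicons [compat_lexicons()].
#' @return the graph with COREF arcs added.
#' @export
resolve_coreference <- function(graph,
                                classes = c("relat", "appos", "pron", "dnp"),
                                lexicons = compat_lexicons()) {
  if (identical(classes, "all"))
    classes <- c("relat", "appos", "pron", "dnp")
  if (identical(classes, "none") || !length(classes)) return(graph)
  arcs <- empty_arcs()
  if ("relat" %in% classes) arcs <- rbind(arcs, resolve_relat(graph))
  if ("appos" %in% classes) arcs <- rbind(arcs, resolve_appos(graph))
  pd <- intersect(classes, c("pron", "dnp"))
  if (length(pd)) arcs <- rbind(arcs, resolve_pron_dnp(graph, lexicons, pd))
  if (nrow(arcs)) graph$arcs <- rbind(graph$arcs, unique(arcs))
  graph
}
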