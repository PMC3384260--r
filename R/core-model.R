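#' bioscope: rule-based composition of biological events
#'
#' Two-phase, rule-based biological event extraction. Phase one composes a
#' document-level semantic embedding graph from syntactic dependencies, gold
#' entities and a trigger lexicon, and builds predications bottom-up with
#' scalar modality values, polarity composition, argument propagation and
#' deterministic coreference resolution. Phase two maps the predications to
#' shared-task event and Speculation/Negation annotations in BioNLP standoff
#' format.
#'
#' The main entry points are [extract_events()] for a single document and
#' [run_pipeline()] for a directory of standoff documents. The intermediate
#' stages are exposed individually: [build_sentence_graph()],
#' [link_sentences()], [resolve_coreference()], [compose_document()],
#' [map_events()] and [write_a2()].
#'
#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# Polarity / modality primitives
# ---------------------------------------------------------------------------

POLARITIES <- c("positive", "negative", "neutral")

#' Clamp a scalar modality value to the unit interval
#' @param mv numeric modality value.
#' @return numeric in \[0, 1\].
#' @keywords internal
clamp_mv <- function(mv) min(1, max(0, mv))

#' Default scalar modality value for a freshly composed atomic predication
#' @return 1.0
#' @export
default_mv <- function() 1.0

# ---------------------------------------------------------------------------
# Predications
# ---------------------------------------------------------------------------

#' Create a predication
#'
#' A predication is a predicate (a trigger-bound surface element) together
#' with a scalar modality value in \[0, 1\], a polarity, and ordered logical
#' arguments. Arguments occupy three slots: one Object, one Subject and any
#' number of Adjuncts; when listed positionally the Object comes first, the
#' Subject second and Adjuncts after. Each argument is either an entity
#' mention, a semantically free surface element (treated as an entity of
#' unknown type), or another predication.
#'
#' @param id predication identifier (assigned deterministically in
#'   composition order).
#' @param node id of the trigger-bound surface element (graph node).
#' @param lemma trigger lemma.
#' @param sem_type atomic event type or embedding category (uppercase).
#' @param klass one of `"atomic"`, `"modal"`, `"relational"`,
#'   `"attributive"` (valence shifters never form predications).
#' @param mv scalar modality value in \[0, 1\].
#' @param polarity `"positive"`, `"negative"` or `"neutral"`.
#' @param object,subject a predication argument (see [pred_arg()]) or `NULL`.
#' @param adjuncts list of predication arguments.
#' @param negated logical; `TRUE` once a NEGATOR has applied to this
#'   predication (used when mapping to Negation modifications).
#' @param trigger list of trigger features (polarity, strength,
#'   negative_raising) from the lexicon entry.
#' @return an object of class `predication`.
#' @export
new_predication <- function(id, node, lemma, sem_type, klass,
                            mv = default_mv(), polarity = "neutral",
                            object = NULL, subject = NULL,
                            adjuncts = list(), negated = FALSE,
                            trigger = list()) {
  stopifnot(mv >= 0, mv <= 1, polarity %in% POLARITIES)
  structure(list(id = id, node = node, lemma = lemma, sem_type = sem_type,
                 klass = klass, mv = mv, polarity = polarity,
                 object = object, subject = subject, adjuncts = adjuncts,
                 negated = negated, trigger = trigger),
            class = "predication")
}

#' Build a predication argument reference
#'
#' @param kind `"entity"` (a typed entity mention), `"free"` (a semantically
#'   free surface element, i.e. an entity of unknown type), or
#'   `"predication"`.
#' @param ref entity id, node id, or predication id depending on `kind`.
#' @param text surface text of the argument (for display).
#' @return a list of class `pred_arg`.
#' @export
pred_arg <- function(kind = c("entity", "free", "predication"), ref, text = "") {
  kind <- match.arg(kind)
  structure(list(kind = kind, ref = ref, text = text), class = "pred_arg")
}

#' Ordered argument list of a predication
#'
#' Position 1 is the Object, position 2 the Subject, remaining positions are
#' Adjuncts. Empty slots are skipped (an Object-only predication has a single
#' positional argument).
#'
#' @param pr a `predication`.
#' @return list of `pred_arg` objects.
#' @export
pred_args <- function(pr) {
  out <- list()
  if (!is.null(pr$object)) out <- c(out, list(pr$object))
  if (!is.null(pr$subject)) out <- c(out, list(pr$subject))
  c(out, pr$adjuncts)
}

#' @export
format.predication <- function(x, ...) {
  fmt_arg <- function(a) {
    if (a$kind == "predication") a$ref
    else sprintf("%s:%s", if (nzchar(a$text)) a$text else a$ref,
                 if (a$kind == "entity") "E" else "?")
  }
  args <- vapply(pred_args(x), fmt_arg, character(1))
  sprintf("%s %s:%s(mv=%.3g, %s%s%s)", x$id, x$lemma, x$sem_type, x$mv,
          x$polarity, if (length(args)) ", " else "",
          paste(args, collapse = ", "))
}

#' @export
print.predication <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Predication sets
# ---------------------------------------------------------------------------

#' Bundle composed predications
#'
#' @param predications named list of `predication` objects (names = ids).
#' @param graph the embedding graph they were composed from (may be `NULL`
#'   for hand-built sets, e.g. in tests).
#' @return object of class `predication_set`.
#' @export
predication_set <- function(predications = list(), graph = NULL) {
  names(predications) <- vapply(predications, `[[`, character(1), "id")
  structure(list(predications = predications, graph = graph),
            class = "predication_set")
}

#' @export
print.predication_set <- function(x, ...) {
  cat(sprintf("<predication_set: %d predications>\n", length(x$predications)))
  for (p in x$predications) cat(" ", format(p), "\n")
  invisible(x)
}

#' Look up a predication by id
#' @param ps a `predication_set`.
#' @param id predication id.
#' @return the `predication`; errors if unknown.
#' @export
get_predication <- function(ps, id) {
  pr <- ps$predications[[id]]
  if (is.null(pr)) stop("unknown predication id: ", id)
  pr
}

#' Does one predication directly embed another?
#'
#' `pr1` embeds `pr2` iff `pr2` appears among the arguments of `pr1`.
#'
#' @param ps a `predication_set`.
#' @param id1,id2 predication ids.
#' @return logical.
#' @export
embeds <- function(ps, id1, id2) {
  pr1 <- get_predication(ps, id1)
  get_predication(ps, id2)  # lookup error for unknown ids
  args <- pred_args(pr1)
  any(vapply(args, function(a) a$kind == "predication" && a$ref == id2,
             logical(1)))
}

#' Scope of a predication
#'
#' The transitive closure of direct embedding: every predication reachable
#' from `id` through argument chains. The scope relation is a strict partial
#' order (transitive, irreflexive); a cycle among predications indicates a
#' composition bug and raises an error.
#'
#' @param ps a `predication_set`.
#' @param id predication id.
#' @return character vector of predication ids within the scope of `id`.
#' @export
scope_of <- function(ps, id) {
  get_predication(ps, id)
  seen <- character(0)
  frontier <- id
  while (length(frontier)) {
    nxt <- character(0)
    for (f in frontier) {
      args <- pred_args(get_predication(ps, f))
      kids <- vapply(args, function(a)
        if (a$kind == "predication") a$ref else NA_character_, character(1))
      nxt <- c(nxt, kids[!is.na(kids)])
    }
    nxt <- setdiff(unique(nxt), seen)
    if (id %in% nxt)
      stop("cycle detected in predication graph at ", id)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

#' Embedded-predication arguments of a predication
#' @param pr a `predication`.
#' @return character vector of embedded predication ids.
#' @keywords internal
embedded_pred_ids <- function(pr) {
  args <- pred_args(pr)
  ids <- vapply(args, function(a)
    if (a$kind == "predication") a$ref else NA_character_, character(1))
  ids[!is.na(ids)]
}

# ---------------------------------------------------------------------------
# Semantic-type taxonomy
# ---------------------------------------------------------------------------

MODAL_TYPES <- c("EPISTEMIC", "ASSUMPTIVE", "SPECULATIVE",
                 "EVIDENTIAL", "DEDUCTIVE", "DEMONSTRATIVE", "REPORTING",
                 "DYNAMIC", "POTENTIAL", "VOLITIVE",
                 "DEONTIC", "OBLIGATIVE", "PERMISSIVE",
                 "INTENTIONAL", "INTERROGATIVE", "SUCCESS")
RELATIONAL_TYPES <- c("CAUSAL", "TEMPORAL", "CORRELATIVE", "COMPARATIVE",
                      "SALIENCY")
ATTRIBUTIVE_TYPES <- c("PATIENT", "EXPERIENCER", "AGENTIVE")
SHIFTER_TYPES <- c("NEGATOR", "INTENSIFIER", "DIMINISHER")

#' Classify a semantic type
#'
#' Maps a trigger semantic type to its embedding class: `"modal"`,
#' `"relational"`, `"attributive"`, `"valence_shifter"`, or `"atomic"` for
#' shared-task event types (anything not in the embedding taxonomy).
#'
#' @param sem_type uppercase semantic type label.
#' @return character scalar.
#' @export
embedding_class <- function(sem_type) {
  vapply(sem_type, function(s) {
    if (s %in% MODAL_TYPES) "modal"
    else if (s %in% RELATIONAL_TYPES) "relational"
    else if (s %in% ATTRIBUTIVE_TYPES) "attributive"
    else if (s %in% SHIFTER_TYPES) "valence_shifter"
    else "atomic"
  }, character(1), USE.NAMES = FALSE)
}
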