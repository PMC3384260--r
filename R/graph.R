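# Graph construction: syntactic dependencies + entity/predicate mentions ->
# sentence-level embedding subgraphs -> document-level embedding graph.

#' Options controlling the dependency-to-embedding-graph transformation
#'
#' The transformation engine applies five rule classes in a fixed order:
#' corrective (modifier coordination repair), collapse (multi-token mention
#' units), split (coordination), inversion (semantic direction switch with
#' operator chaining), and identity (pass-through with uppercased label).
#' The engine is data-driven: additional dependency labels can be added to
#' the inversion set, and extra user rules can be supplied as functions
#' taking and returning the working dependency table.
#'
#' @param invert_labels syntactic dependency labels whose direction is
#'   switched (the dependent semantically embeds the governor).
#' @param conj_prefix label prefix identifying coordination dependencies.
#' @param nn_labels labels treated as NP-internal modification for the
#'   corrective rule.
#' @param punct_pos POS tags excluded from the node set when isolated.
#' @return list of options.
#' @export
graph_options <- function(invert_labels = c("amod", "advmod", "aux",
                                            "auxpass", "neg", "det", "mark",
                                            "complm", "quantmod", "predet"),
                          conj_prefix = "conj",
                          nn_labels = "nn",
                          punct_pos = c(".", ",", ":", "``", "''",
                                        "-LRB-", "-RRB-", "HYPH")) {
  list(invert_labels = invert_labels, conj_prefix = conj_prefix,
       nn_labels = nn_labels, punct_pos = punct_pos)
}

is_conj_label <- function(label, prefix = "conj") {
  label == prefix | startsWith(label, paste0(prefix, "_"))
}

conj_word <- function(label, prefix = "conj") {
  ifelse(is_conj_label(label, prefix) & label != prefix,
         substring(label, nchar(prefix) + 2), "and")
}

empty_nodes <- function() {
  data.frame(id = character(0), sentence = integer(0),
             first_idx = integer(0), last_idx = integer(0),
             start = integer(0), end = integer(0), text = character(0),
             lemma = character(0), pos = character(0),
             binding = character(0), ref = character(0),
             sem_type = character(0), polarity = character(0),
             strength = numeric(0), negative_raising = logical(0),
             conj = logical(0), stringsAsFactors = FALSE)
}

empty_arcs <- function() {
  data.frame(type = character(0), source = character(0),
             target = character(0), stringsAsFactors = FALSE)
}

#' Build the embedding subgraph of one sentence
#'
#' Applies the intra-sentential transformation rules to the sentence's
#' syntactic dependencies, producing surface-element nodes and typed
#' embedding relations. Rule order: corrective, collapse, split, inversion
#' (with chaining of stacked modifiers), identity. Any dependency matched by
#' no rule passes through as an embedding relation with its label
#' uppercased. The result is checked for acyclicity; a cycle is broken by
#' dropping the arc whose dependent has the latest character offset (with a
#' warning).
#'
#' @param tokens data.frame with columns `idx`, `form`, `lemma`, `pos`,
#'   `start`, `end` (0-based, half-open document offsets).
#' @param deps data.frame with columns `label`, `gov`, `dep` (1-based token
#'   indices; `gov = 0` marks the root and is ignored).
#' @param entities data.frame of entity mentions (`id`, `type`, `start`,
#'   `end`, `text`); may be empty.
#' @param lexicon a `trigger_lexicon` used to identify predicate mentions,
#'   or a precomputed mention data.frame from [match_triggers()].
#' @param sentence integer sentence index (used in node ids).
#' @param opts options from [graph_options()].
#' @return a list with `nodes`, `arcs`, `sentence` of class
#'   `sentence_graph`.
#' @export
build_sentence_graph <- function(tokens, deps, entities = NULL,
                                 lexicon = default_lexicon(),
                                 sentence = 1L, opts = graph_options()) {
  if (is.null(entities)) entities <- empty_entities()
  n <- nrow(tokens)
  if (!is.null(deps) && nrow(deps)) deps <- deps[deps$gov > 0, , drop = FALSE]
  if (is.null(deps)) deps <- data.frame(label = character(0),
                                        gov = integer(0), dep = integer(0))
  # token indices may be sparse (dialects that only list tokens taking part
  # in a dependency): renumber to consecutive positions
  if (n && any(tokens$idx != seq_len(n))) {
    if (nrow(deps)) {
      deps$gov <- match(deps$gov, tokens$idx)
      deps$dep <- match(deps$dep, tokens$idx)
      deps <- deps[!is.na(deps$gov) & !is.na(deps$dep), , drop = FALSE]
    }
    tokens$idx <- seq_len(n)
  }

  # --- unit bookkeeping ----------------------------------------------------
  st <- new.env(parent = emptyenv())
  st$rep <- seq_len(n)                 # token idx -> representative token
  st$info <- vector("list", n)
  for (i in seq_len(n)) {
    st$info[[i]] <- list(tokens = tokens$idx[i], virtual = FALSE,
                         binding = "free", ref = NA_character_,
                         text = tokens$form[i], lemma = tolower(tokens$lemma[i]),
                         pos = tokens$pos[i], start = tokens$start[i],
                         end = tokens$end[i], sem_type = NA_character_,
                         polarity = NA_character_, strength = NA_real_,
                         negative_raising = NA, conj = FALSE)
  }
  st$nvirt <- 0L
  find_unit <- function(i) {
    while (st$rep[i] != i) i <- st$rep[i]
    i
  }
  unit_of <- function(tok) if (tok > n) tok else find_unit(tok)
  new_virtual <- function(lemma, start, end) {
    st$nvirt <- st$nvirt + 1L
    uid <- n + st$nvirt
    st$info[[uid]] <- list(tokens = integer(0), virtual = TRUE,
                           binding = "free", ref = NA_character_,
                           text = lemma, lemma = lemma, pos = "CC",
                           start = start, end = end,
                           sem_type = NA_character_,
                           polarity = NA_character_, strength = NA_real_,
                           negative_raising = NA, conj = FALSE)
    uid
  }

  final <- list()   # emitted embedding relations (unit-level)
  emit <- function(type, src, tgt) {
    final[[length(final) + 1]] <<- list(type = type, src = src, tgt = tgt)
  }
  consumed <- rep(FALSE, nrow(deps))

  ent_tok <- rep(NA_character_, n)   # entity id per token
  for (k in seq_len(nrow(entities))) {
    hit <- tokens$start < entities$end[k] & tokens$end > entities$start[k]
    ent_tok[hit] <- entities$id[k]
  }
  predicates <- if (is.data.frame(lexicon) &&
                    !inherits(lexicon, "trigger_lexicon")) lexicon
                else match_triggers(tokens, lexicon)
  bound_tok <- !is.na(ent_tok)
  if (nrow(predicates)) {
    for (k in seq_len(nrow(predicates))) {
      span <- predicates$first_idx[k]:predicates$last_idx[k]
      if (!any(bound_tok[span])) bound_tok[span] <- TRUE
    }
  }

  # --- corrective: modifier coordination repair ----------------------------
  if (nrow(deps)) {
    for (r in which(is_conj_label(deps$label, opts$conj_prefix))) {
      if (consumed[r]) next
      a <- deps$gov[r]; h <- deps$dep[r]
      nnr <- which(deps$label %in% opts$nn_labels & deps$gov == h & !consumed)
      if (!length(nnr)) next
      mods <- deps$dep[nnr]
      if (!bound_tok[a] || !all(bound_tok[mods]) || !is.na(ent_tok[h])) next
      conjuncts <- sort(c(a, mods))
      cw <- conj_word(deps$label[r], opts$conj_prefix)
      cand <- which(tolower(tokens$lemma) == cw &
                    tokens$idx > min(conjuncts) & tokens$idx < max(conjuncts))
      cu <- if (length(cand)) cand[1]
            else new_virtual(cw, tokens$start[min(conjuncts)],
                             tokens$end[max(conjuncts)])
      st$info[[cu]]$conj <- TRUE
      emit("NN", h, cu)
      for (cj in conjuncts) emit("CC", cu, cj)
      consumed[c(r, nnr)] <- TRUE
    }
  }

  # --- collapse: multi-token mentions --------------------------------------
  merge_span <- function(span, binding, ref, feats = NULL, text = NULL) {
    span <- sort(unique(vapply(span, find_unit, integer(1))))
    head_u <- span[1]
    toks <- sort(unique(unlist(lapply(span, function(u) st$info[[u]]$tokens))))
    inf <- st$info[[head_u]]
    inf$tokens <- toks
    inf$start <- min(tokens$start[toks])
    inf$end <- max(tokens$end[toks])
    inf$text <- if (!is.null(text)) text else
      substr_span(tokens, min(toks), max(toks))
    inf$lemma <- paste(tolower(tokens$lemma[toks]), collapse = " ")
    inf$pos <- tokens$pos[max(toks)]
    inf$binding <- binding
    inf$ref <- ref
    if (!is.null(feats)) {
      inf$lemma <- feats$lemma
      inf$pos <- feats$pos
      inf$sem_type <- feats$sem_type
      inf$polarity <- feats$polarity
      inf$strength <- feats$strength
      inf$negative_raising <- feats$negative_raising
    }
    st$info[[head_u]] <- inf
    for (u in span[-1]) st$rep[u] <- head_u
    head_u
  }
  for (k in seq_len(nrow(entities))) {
    span <- which(tokens$start < entities$end[k] &
                  tokens$end > entities$start[k])
    if (!length(span)) next
    merge_span(span, "entity", entities$id[k], text = entities$text[k])
  }
  if (nrow(predicates)) for (k in seq_len(nrow(predicates))) {
    span <- predicates$first_idx[k]:predicates$last_idx[k]
    if (any(!is.na(ent_tok[span]))) next   # entities take precedence
    merge_span(span, "predicate", predicates$lemma[k],
               feats = as.list(predicates[k, c("lemma", "pos", "sem_type",
                                               "polarity", "strength",
                                               "negative_raising")]))
  }

  # dependency endpoints at unit level; drop intra-unit links
  if (nrow(deps)) {
    deps$gu <- vapply(deps$gov, unit_of, integer(1))
    deps$du <- vapply(deps$dep, unit_of, integer(1))
    consumed[deps$gu == deps$du] <- TRUE
    dup <- duplicated(data.frame(deps$label, deps$gu, deps$du))
    consumed[dup] <- TRUE
  }

  # --- split: coordination -------------------------------------------------
  redirect <- list()   # conjunct unit -> conj unit
  if (nrow(deps)) {
    crows <- which(is_conj_label(deps$label, opts$conj_prefix) & !consumed)
    if (length(crows)) {
      govs <- unique(deps$gu[crows])
      for (g in govs) {
        rows <- crows[deps$gu[crows] == g]
        conjuncts <- unique(c(g, deps$du[rows]))
        cw <- conj_word(deps$label[rows[1]], opts$conj_prefix)
        lo <- min(vapply(conjuncts, function(u) st$info[[u]]$start, numeric(1)))
        hi <- max(vapply(conjuncts, function(u) st$info[[u]]$end, numeric(1)))
        cand <- which(tolower(tokens$lemma) == cw & tokens$start >= lo &
                      tokens$end <= hi)
        cand <- cand[vapply(cand, function(i) find_unit(i) == i &&
                              !st$info[[i]]$conj &&
                              st$info[[i]]$binding == "free", logical(1))]
        cu <- if (length(cand)) cand[1] else new_virtual(cw, lo, hi)
        st$info[[cu]]$conj <- TRUE
        for (cj in conjuncts) emit("CC", cu, cj)
        for (cj in conjuncts) redirect[[as.character(cj)]] <- cu
        consumed[rows] <- TRUE
      }
    }
  }
  redirect_unit <- function(u, src) {
    r <- redirect[[as.character(u)]]
    if (is.null(r)) return(u)
    rs <- redirect[[as.character(src)]]
    if (!is.null(rs) && rs == r) return(u)  # source in same coordination
    r
  }

  # --- inversion with operator chaining ------------------------------------
  if (nrow(deps)) {
    irows <- which(deps$label %in% opts$invert_labels & !consumed)
    if (length(irows)) {
      for (g in unique(deps$gu[irows])) {
        rows <- irows[deps$gu[irows] == g]
        ord <- order(vapply(deps$du[rows], function(u) st$info[[u]]$start,
                            numeric(1)))
        rows <- rows[ord]
        chain <- c(deps$du[rows], g)
        for (k in seq_along(rows)) {
          emit(toupper(deps$label[rows[k]]), chain[k], chain[k + 1])
        }
        consumed[rows] <- TRUE
      }
    }
  }

  # --- identity: pass-through ----------------------------------------------
  if (nrow(deps)) {
    for (r in which(!consumed)) {
      src <- deps$gu[r]
      tgt <- redirect_unit(deps$du[r], src)
      if (src == tgt) next
      rs <- redirect[[as.character(src)]]
      if (!is.null(rs) && rs == tgt) next
      emit(toupper(deps$label[r]), src, tgt)
    }
  }

  # --- assemble nodes and arcs ---------------------------------------------
  units_used <- unique(unlist(lapply(final, function(a) c(a$src, a$tgt))))
  bound_units <- which(vapply(seq_along(st$info), function(u) {
    !is.null(st$info[[u]]) && find_unit_safe(st, u, n) == u &&
      st$info[[u]]$binding != "free"
  }, logical(1)))
  keep <- sort(unique(c(units_used, bound_units)))
  keep <- keep[vapply(keep, function(u) !is.null(st$info[[u]]), logical(1))]
  if (!length(keep)) {
    sg <- structure(list(nodes = empty_nodes(), arcs = empty_arcs(),
                         sentence = sentence), class = "sentence_graph")
    return(sg)
  }
  starts <- vapply(keep, function(u) st$info[[u]]$start, numeric(1))
  ends <- vapply(keep, function(u) st$info[[u]]$end, numeric(1))
  ord <- order(starts, ends)
  keep <- keep[ord]
  ids <- sprintf("s%dn%d", sentence, seq_along(keep))
  id_of <- stats::setNames(ids, as.character(keep))
  nodes <- do.call(rbind, lapply(seq_along(keep), function(k) {
    inf <- st$info[[keep[k]]]
    data.frame(id = ids[k], sentence = sentence,
               first_idx = if (length(inf$tokens)) min(inf$tokens) else NA_integer_,
               last_idx = if (length(inf$tokens)) max(inf$tokens) else NA_integer_,
               start = inf$start, end = inf$end, text = inf$text,
               lemma = inf$lemma, pos = inf$pos, binding = inf$binding,
               ref = inf$ref, sem_type = inf$sem_type,
               polarity = inf$polarity, strength = inf$strength,
               negative_raising = inf$negative_raising, conj = inf$conj,
               stringsAsFactors = FALSE)
  }))
  arcs <- if (length(final)) {
    a <- do.call(rbind, lapply(final, function(x) {
      data.frame(type = x$type, source = id_of[[as.character(x$src)]],
                 target = id_of[[as.character(x$tgt)]],
                 stringsAsFactors = FALSE)
    }))
    unique(a)
  } else empty_arcs()
  arcs <- arcs[arcs$source != arcs$target, , drop = FALSE]

  sg <- structure(list(nodes = nodes, arcs = arcs, sentence = sentence),
                  class = "sentence_graph")
  break_cycles(sg)
}

find_unit_safe <- function(st, i, n) {
  if (i > n) return(i)
  while (st$rep[i] != i) i <- st$rep[i]
  i
}

empty_entities <- function() {
  data.frame(id = character(0), type = character(0), start = integer(0),
             end = integer(0), text = character(0), stringsAsFactors = FALSE)
}

# Acyclicity is required of the embedding graph; collapsed-dependency
# artifacts can create cycles. Break them by dropping the arc whose
# dependent (target) has the latest character offset.
break_cycles <- function(sg) {
  repeat {
    cyc <- find_cycle(sg$nodes, sg$arcs)
    if (is.null(cyc)) return(sg)
    tgt_start <- sg$nodes$start[match(sg$arcs$target[cyc], sg$nodes$id)]
    drop <- cyc[which.max(tgt_start)]
    warning(sprintf("cycle broken: dropped %s(%s, %s)",
                    sg$arcs$type[drop], sg$arcs$source[drop],
                    sg$arcs$target[drop]), call. = FALSE)
    sg$arcs <- sg$arcs[-drop, , drop = FALSE]
  }
}

# returns row indices of arcs forming a directed cycle, or NULL
find_cycle <- function(nodes, arcs) {
  if (!nrow(arcs)) return(NULL)
  g <- igraph::graph_from_data_frame(
    arcs[, c("source", "target")], directed = TRUE,
    vertices = data.frame(name = nodes$id))
  if (igraph::is_dag(g)) return(NULL)
  # find a back arc: iterate arcs, test reachability target -> source
  for (r in seq_len(nrow(arcs))) {
    reach <- igraph::subcomponent(g, arcs$target[r], mode = "out")
    if (arcs$source[r] %in% names(reach)) {
      # arcs on a path target -> source plus this arc
      path <- igraph::shortest_paths(g, arcs$target[r], arcs$source[r],
                                     mode = "out")$vpath[[1]]
      vn <- names(path)
      rows <- r
      if (length(vn) > 1) {
        for (k in seq_len(length(vn) - 1)) {
          rows <- c(rows, which(arcs$source == vn[k] &
                                arcs$target == vn[k + 1])[1])
        }
      }
      return(unique(rows))
    }
  }
  NULL
}

#' Topmost node of a sentence subgraph
#'
#' The unique node with no incoming intra-sentential arc, considering only
#' nodes incident to at least one arc; ties break to the earliest character
#' offset. For an arc-free subgraph the earliest node is returned.
#'
#' @param sg a `sentence_graph` (or a list with `nodes`/`arcs`).
#' @return node id.
#' @export
topmost_node <- function(sg) {
  nodes <- sg$nodes; arcs <- sg$arcs
  if (!nrow(nodes)) stop("empty sentence subgraph")
  if (!nrow(arcs)) return(nodes$id[which.min(nodes$start)])
  incident <- nodes$id %in% c(arcs$source, arcs$target)
  roots <- nodes$id[incident & !(nodes$id %in% arcs$target)]
  if (!length(roots)) roots <- nodes$id[incident]
  roots[which.min(nodes$start[match(roots, nodes$id)])]
}

#' Link sentence subgraphs into a document embedding graph
#'
#' Adds a PREV arc from each sentence's topmost node to the next sentence's
#' topmost node, reflecting the sequence of sentences and enabling
#' inter-sentential processing.
#'
#' @param subgraphs list of `sentence_graph` objects in document order.
#' @param text full document text.
#' @param entities entity mention data.frame.
#' @param doc_id document identifier.
#' @param paragraphs optional integer vector: paragraph index per sentence
#'   (defaults to a single paragraph).
#' @return an object of class `embedding_graph`.
#' @export
link_sentences <- function(subgraphs, text = "", entities = empty_entities(),
                           doc_id = "doc", paragraphs = NULL) {
  subgraphs <- Filter(function(s) nrow(s$nodes) > 0, subgraphs)
  ns <- length(subgraphs)
  if (is.null(paragraphs)) paragraphs <- rep(1L, ns)
  nodes <- if (ns) do.call(rbind, lapply(subgraphs, `[[`, "nodes"))
           else empty_nodes()
  arcs <- if (ns) do.call(rbind, lapply(subgraphs, `[[`, "arcs"))
          else empty_arcs()
  roots <- vapply(subgraphs, topmost_node, character(1))
  if (ns > 1) {
    prev <- data.frame(type = "PREV", source = roots[-ns],
                       target = roots[-1], stringsAsFactors = FALSE)
    arcs <- rbind(arcs, prev)
  }
  sentences <- data.frame(
    sentence = vapply(subgraphs, `[[`, integer(1), "sentence"),
    root = if (ns) roots else character(0),
    paragraph = paragraphs[seq_len(ns)], stringsAsFactors = FALSE)
  structure(list(nodes = nodes, arcs = arcs, sentences = sentences,
                 entities = entities, text = text, doc_id = doc_id),
            class = "embedding_graph")
}

#' @export
print.embedding_graph <- function(x, ...) {
  cat(sprintf("<embedding_graph %s: %d nodes, %d arcs, %d sentences>\n",
              x$doc_id, nrow(x$nodes), nrow(x$arcs), nrow(x$sentences)))
  invisible(x)
}

#' Arcs of a graph filtered by kind
#'
#' @param graph an `embedding_graph` or `sentence_graph`.
#' @param kind `"intra"` (intra-sentential only), `"linked"` (intra + PREV),
#'   `"coref"` (COREF only) or `"all"`.
#' @return arc data.frame.
#' @export
graph_arcs <- function(graph, kind = c("linked", "intra", "coref", "all")) {
  kind <- match.arg(kind)
  a <- graph$arcs
  switch(kind,
         intra = a[!a$type %in% c("PREV", "COREF"), , drop = FALSE],
         linked = a[a$type != "COREF", , drop = FALSE],
         coref = a[a$type == "COREF", , drop = FALSE],
         all = a)
}

graph_node <- function(graph, id) {
  graph$nodes[match(id, graph$nodes$id), , drop = FALSE]
}

#' Assert that the non-COREF part of an embedding graph is acyclic
#' @param graph an `embedding_graph`.
#' @return `TRUE` invisibly; errors on a cycle.
#' @export
assert_acyclic <- function(graph) {
  a <- graph_arcs(graph, "linked")
  if (!is.null(find_cycle(graph$nodes, a)))
    stop("embedding graph contains a cycle")
  invisible(TRUE)
}
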