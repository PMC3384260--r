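# Independent recursive evaluator of the composition semantics: argument
# typing, propagation through free chains, polarity composition and
# modality value composition are re-derived here directly from their
# definitions, by plain depth-first recursion, without sharing code with
# the production composer. Used as the oracle in randomized equivalence
# tests (tree-shaped graphs, no coordination or coreference).

ORACLE_POLARITY_TABLE <- matrix(c(
  # trigger    embedded    composite
  "neutral",  "positive", "positive",
  "neutral",  "negative", "negative",
  "neutral",  "neutral",  "neutral",
  "neutral",  "*",        "neutral",
  "negative", "positive", "negative",
  "negative", "negative", "negative",
  "negative", "neutral",  "negative",
  "negative", "*",        "negative",
  "positive", "negative", "negative",
  "positive", "positive", "positive",
  "positive", "neutral",  "positive",
  "positive", "*",        "positive"), ncol = 3, byrow = TRUE)

oracle_polarity <- function(trigger, embedded) {
  if (is.null(embedded)) embedded <- "*"
  hit <- ORACLE_POLARITY_TABLE[, 1] == trigger &
    ORACLE_POLARITY_TABLE[, 2] == embedded
  ORACLE_POLARITY_TABLE[hit, 3][1]
}

#' Reference evaluator for document composition
#'
#' A direct recursive implementation of the composition semantics, used as
#' an independent oracle for [compose_document()] on randomly generated
#' tree-shaped graphs. Returns one record per composed predication in
#' canonical (node-keyed) form.
#'
#' @param graph an `embedding_graph` (tree-shaped, no coordination or
#'   COREF arcs).
#' @param config a [compose_config()] (`arg_rules` and `propagation_depth`
#'   are honoured).
#' @return data.frame with one row per predication: `node`, `sem_type`,
#'   `mv`, `polarity`, `negated`, `object`, `subject`, `adjuncts` (argument
#'   references as `E:<entity>`, `F:<node>` or `P:<node>`).
#' @export
compose_oracle <- function(graph, config = compose_config()) {
  nodes <- graph$nodes
  arcs <- graph$arcs[!graph$arcs$type %in% c("PREV", "COREF"), , drop = FALSE]
  rules <- config$arg_rules
  depth_limit <- config$propagation_depth

  nrow_of <- function(id) nodes[nodes$id == id, , drop = FALSE]
  kids_of <- function(id) {
    k <- arcs[arcs$source == id, , drop = FALSE]
    k[order(nodes$start[match(k$target, nodes$id)]), , drop = FALSE]
  }
  klass_of <- function(id) {
    nd <- nrow_of(id)
    if (nd$binding != "predicate") return(nd$binding)
    embedding_class(nd$sem_type)
  }

  preds <- new.env(parent = emptyenv())

  # literal rule application per the typing-function definition
  arg_type_for <- function(nd, rel_type) {
    for (r in seq_len(nrow(rules))) {
      rule <- rules[r, ]
      if (rule$relation != rel_type) next
      if (nzchar(rule$pos) && !is.na(nd$pos) &&
          !(rule$pos == nd$pos || startsWith(nd$pos, rule$pos))) next
      inset <- function(C) {
        length(C) && (tolower(nd$lemma) %in% tolower(C) ||
                        (!is.na(nd$sem_type) &&
                           toupper(nd$sem_type) %in% toupper(C)))
      }
      if (length(rule$inc[[1]]) && !inset(rule$inc[[1]])) next
      if (inset(rule$exc[[1]])) next
      return(rule$arg_type)
    }
    NA_character_
  }

  # nearest bound descendant through an all-free path (recursive search)
  free_chain_target <- function(id, d) {
    if (d > depth_limit) return(NULL)
    best <- NULL
    for (tgt in kids_of(id)$target) {
      kl <- klass_of(tgt)
      if (kl %in% c("entity", "atomic", "modal", "relational",
                    "attributive")) {
        cand <- list(node = tgt, depth = d)
      } else {
        cand <- free_chain_target(tgt, d + 1)
        if (!is.null(cand)) cand$depth <- cand$depth  # depth of discovery
      }
      if (!is.null(cand) &&
          (is.null(best) || cand$depth < best$depth ||
             (cand$depth == best$depth &&
                nrow_of(cand$node)$start < nrow_of(best$node)$start)))
        best <- cand
    }
    best
  }

  arg_ref <- function(id) {
    nd <- nrow_of(id)
    kl <- klass_of(id)
    if (kl == "entity") return(paste0("E:", nd$ref))
    if (kl %in% c("atomic", "modal", "relational", "attributive")) {
      if (!is.null(preds[[id]])) return(paste0("P:", id))
      return(paste0("F:", id))
    }
    hit <- free_chain_target(id, 1)
    if (!is.null(hit)) return(arg_ref(hit$node))
    paste0("F:", id)
  }

  compose_here <- function(id) {
    nd <- nrow_of(id)
    obj <- NA_character_; subj <- NA_character_; adj <- character(0)
    for (r in seq_len(nrow(kids_of(id)))) {
      arc <- kids_of(id)[r, ]
      at <- arg_type_for(nd, arc$type)
      if (is.na(at)) next
      ref <- arg_ref(arc$target)
      if (at == "Object" && is.na(obj)) obj <- ref
      else if (at == "Subject" && is.na(subj)) subj <- ref
      else if (at == "Adjunct") adj <- c(adj, ref)
    }
    emb_pol <- NULL
    for (ref in c(obj, subj, adj)) {
      if (!is.na(ref) && startsWith(ref, "P:")) {
        emb_pol <- preds[[substring(ref, 3)]]$polarity
        break
      }
    }
    mv <- if (is.na(nd$strength)) 1.0 else nd$strength
    pol <- oracle_polarity(if (is.na(nd$polarity)) "neutral"
                           else nd$polarity, emb_pol)
    preds[[id]] <- list(node = id, sem_type = nd$sem_type, mv = mv,
                        polarity = pol, negated = FALSE, object = obj,
                        subject = subj, adjuncts = adj)
  }

  nearest_preds_below <- function(id) {
    out <- character(0)
    for (tgt in kids_of(id)$target) {
      if (!is.null(preds[[tgt]])) out <- c(out, tgt)
      else out <- c(out, nearest_preds_below(tgt))
    }
    unique(out)
  }

  operate <- function(id) {
    nd <- nrow_of(id)
    s <- if (is.na(nd$strength)) 1 else nd$strength
    for (tp in nearest_preds_below(id)) {
      p <- preds[[tp]]
      if (nd$sem_type == "NEGATOR") {
        p$mv <- 1 - p$mv
        p$polarity <- "negative"
        p$negated <- TRUE
      } else if (nd$sem_type == "DIMINISHER") {
        p$mv <- if (p$mv >= 0.5) s * p$mv else p$mv + (1 - s) * (1 - p$mv)
      } else if (nd$sem_type == "INTENSIFIER") {
        p$mv <- if (p$mv >= 0.5) p$mv + (1 - s) * (1 - p$mv) else s * p$mv
      } else {  # MODAL
        p$mv <- if (p$mv >= 0.5) s * p$mv else p$mv + (1 - s) * (1 - p$mv)
      }
      p$mv <- min(1, max(0, p$mv))
      preds[[tp]] <- p
    }
  }

  eval_node <- function(id) {
    for (tgt in kids_of(id)$target) eval_node(tgt)
    kl <- klass_of(id)
    if (kl %in% c("atomic", "modal", "relational", "attributive"))
      compose_here(id)
    if (kl %in% c("valence_shifter", "modal")) operate(id)
  }

  roots <- setdiff(nodes$id, arcs$target)
  roots <- roots[order(nodes$start[match(roots, nodes$id)])]
  for (r in roots) eval_node(r)

  ids <- ls(preds)
  if (!length(ids))
    return(data.frame(node = character(0), sem_type = character(0),
                      mv = numeric(0), polarity = character(0),
                      negated = logical(0), object = character(0),
                      subject = character(0), adjuncts = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(ids, function(id) {
    p <- preds[[id]]
    data.frame(node = p$node, sem_type = p$sem_type, mv = p$mv,
               polarity = p$polarity, negated = p$negated,
               object = p$object, subject = p$subject,
               adjuncts = paste(p$adjuncts, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  out[order(out$node), , drop = FALSE]
}

#' Canonicalize a composed predication set for oracle comparison
#'
#' Valid only when each node carries at most one predication (no
#' coordination / plural anaphora), as in the random-tree test regime.
#'
#' @param ps a `predication_set`.
#' @return data.frame in the same canonical form as [compose_oracle()].
#' @export
canonicalize_predications <- function(ps) {
  node_of <- stats::setNames(
    vapply(ps$predications, `[[`, character(1), "node"),
    names(ps$predications))
  if (anyDuplicated(node_of))
    stop("canonical form requires at most one predication per node")
  ref_str <- function(a) {
    if (is.null(a)) return(NA_character_)
    switch(a$kind,
           entity = paste0("E:", a$ref),
           free = paste0("F:", a$ref),
           predication = paste0("P:", node_of[[a$ref]]))
  }
  if (!length(ps$predications))
    return(data.frame(node = character(0), sem_type = character(0),
                      mv = numeric(0), polarity = character(0),
                      negated = logical(0), object = character(0),
                      subject = character(0), adjuncts = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(ps$predications, function(p) {
    data.frame(node = p$node, sem_type = p$sem_type, mv = p$mv,
               polarity = p$polarity, negated = p$negated,
               object = ref_str(p$object), subject = ref_str(p$subject),
               adjuncts = paste(vapply(p$adjuncts, ref_str, character(1)),
                                collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$node), , drop = FALSE]
}
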