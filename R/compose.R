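# Composition phase: bottom-up traversal of the embedding graph composing
# predications — argument identification, argument propagation, polarity
# composition, modality value composition, coordination distribution,
# negative raising and anaphor substitution.

#' Load argument identification rules
#'
#' Each rule is a typed 4-tuple (relation type, POS, inclusions, exclusions)
#' mapping to a logical argument type (Object, Subject or Adjunct).
#' Constraints test the predicate's lemma or semantic type; a rule applies
#' when the inclusion set is empty or satisfied, and the exclusion set is
#' not satisfied. Rules apply in file order; the first match wins.
#'
#' @param source path to a 5-column TSV (`-` marks an empty constraint) or
#'   a data.frame with columns `relation`, `pos`, `inclusions`,
#'   `exclusions`, `arg_type`.
#' @return data.frame of class `argument_rules`.
#' @export
load_argument_rules <- function(source) {
  if (is.character(source)) {
    lines <- readLines(source, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 5)
    if (length(bad)) stop("argument rule rows need 5 fields: line ", bad[1])
    m <- do.call(rbind, parts)
    df <- data.frame(relation = m[, 1], pos = m[, 2], inclusions = m[, 3],
                     exclusions = m[, 4], arg_type = m[, 5],
                     stringsAsFactors = FALSE)
  } else df <- as.data.frame(source, stringsAsFactors = FALSE)
  stopifnot(all(df$arg_type %in% c("Object", "Subject", "Adjunct")))
  parse_set <- function(x) {
    lapply(x, function(s) {
      if (is.na(s) || s == "-" || !nzchar(s)) character(0)
      else trimws(strsplit(s, ",", fixed = TRUE)[[1]])
    })
  }
  df$inc <- parse_set(df$inclusions)
  df$exc <- parse_set(df$exclusions)
  both <- mapply(function(i, e) length(intersect(tolower(i), tolower(e))) > 0,
                 df$inc, df$exc)
  if (any(both)) stop("inclusion and exclusion sets overlap at row ",
                      which(both)[1])
  class(df) <- c("argument_rules", "data.frame")
  df
}

#' The argument identification rules shipped with the package
#' @return an `argument_rules` data.frame.
#' @export
default_argument_rules <- function() {
  load_argument_rules(system.file("extdata", "argument_rules.tsv",
                                  package = "bioscope"))
}

# does predicate (lemma, sem_type) satisfy constraint set C?
satisfies_constraint <- function(lemma, sem_type, C) {
  length(C) > 0 && (tolower(lemma) %in% tolower(C) ||
                      (!is.na(sem_type) && toupper(sem_type) %in% toupper(C)))
}

rule_applies <- function(rule, rel_type, lemma, pos, sem_type) {
  if (rule$relation != rel_type) return(FALSE)
  if (!pos_matches(rule$pos, pos)) return(FALSE)
  inc <- rule$inc[[1]]; exc <- rule$exc[[1]]
  if (length(inc) && !satisfies_constraint(lemma, sem_type, inc))
    return(FALSE)
  if (satisfies_constraint(lemma, sem_type, exc)) return(FALSE)
  TRUE
}

#' Identify logical arguments of a predicate node
#'
#' For each outgoing embedding relation of `node`, the first matching rule
#' (in rule order) assigns the target as Object, Subject or Adjunct; a
#' relation matched by no rule licenses no argument.
#'
#' @param node node id of a predicate mention.
#' @param graph an `embedding_graph` or `sentence_graph`.
#' @param rules an `argument_rules` table.
#' @return data.frame with `relation`, `target`, `arg_type` (`NA` when no
#'   rule applies).
#' @export
identify_arguments <- function(node, graph, rules = default_argument_rules()) {
  nd <- graph_node(graph, node)
  arcs <- graph$arcs
  out <- arcs[arcs$source == node &
                !arcs$type %in% c("PREV", "COREF"), , drop = FALSE]
  if (!nrow(out))
    return(data.frame(relation = character(0), target = character(0),
                      arg_type = character(0), stringsAsFactors = FALSE))
  tstart <- graph$nodes$start[match(out$target, graph$nodes$id)]
  out <- out[order(tstart), , drop = FALSE]
  arg_type <- vapply(seq_len(nrow(out)), function(i) {
    for (r in seq_len(nrow(rules))) {
      if (rule_applies(rules[r, ], out$type[i], nd$lemma, nd$pos,
                       nd$sem_type))
        return(rules$arg_type[r])
    }
    NA_character_
  }, character(1))
  data.frame(relation = out$type, target = out$target, arg_type = arg_type,
             stringsAsFactors = FALSE)
}

#' Bound descendants reachable by argument propagation
#'
#' A bound descendant can serve as an argument of a predicate when every
#' node on the path from the licensed child down to it is semantically free
#' (valence-shifter operators count as transparent). The search follows
#' outgoing arcs only, up to `depth` free nodes.
#'
#' @param graph an `embedding_graph`.
#' @param from node id of the (free) child licensed by an argument rule.
#' @param depth maximum number of free nodes on the path (`Inf` for
#'   unlimited).
#' @return data.frame with `node` and `depth`, nearest first.
#' @export
propagate_arguments <- function(graph, from, depth = Inf) {
  arcs <- graph_arcs(graph, "intra")
  found <- data.frame(node = character(0), depth = integer(0),
                      stringsAsFactors = FALSE)
  is_terminal <- function(id) {
    nd <- graph_node(graph, id)
    (nd$binding == "entity") || nd$conj ||
      (nd$binding == "predicate" &&
         embedding_class(nd$sem_type) != "valence_shifter") ||
      any(graph$arcs$type == "COREF" & graph$arcs$source == id)
  }
  frontier <- from
  d <- 1L
  visited <- character(0)
  while (length(frontier) && d <= depth) {
    visited <- c(visited, frontier)
    kids <- unique(arcs$target[arcs$source %in% frontier])
    kids <- setdiff(kids, visited)
    if (!length(kids)) break
    term <- vapply(kids, is_terminal, logical(1))
    if (any(term)) {
      found <- rbind(found, data.frame(node = kids[term], depth = d,
                                       stringsAsFactors = FALSE))
    }
    frontier <- kids[!term]
    d <- d + 1L
  }
  found[order(found$depth,
              graph$nodes$start[match(found$node, graph$nodes$id)]), ,
        drop = FALSE]
}

# ---------------------------------------------------------------------------
# Polarity and modality operators
# ---------------------------------------------------------------------------

#' Compose the polarity of an embedding predication
#'
#' A neutral trigger passes the embedded polarity through; a negative
#' trigger is absorbing; a positive trigger yields negative iff the
#' embedded polarity is negative, else positive.
#'
#' @param trigger_polarity polarity of the trigger (from the dictionary).
#' @param embedded_polarity polarity of the embedded predication, or `NULL`
#'   / `NA` when there is none (wildcard).
#' @return composite polarity.
#' @export
compose_polarity <- function(trigger_polarity, embedded_polarity = NULL) {
  stopifnot(trigger_polarity %in% POLARITIES)
  if (is.null(embedded_polarity) || is.na(embedded_polarity))
    embedded_polarity <- "*"
  if (trigger_polarity == "negative") return("negative")
  if (trigger_polarity == "positive") {
    return(if (embedded_polarity == "negative") "negative" else "positive")
  }
  # neutral trigger passes the embedded value through
  if (embedded_polarity == "*") "neutral" else embedded_polarity
}

#' Invert a modality value (negative valence shifter)
#'
#' @param mv modality value in \[0, 1\].
#' @return `1 - mv`.
#' @export
apply_negator <- function(mv) {
  stopifnot(mv >= 0, mv <= 1)
  1 - mv
}

#' Shift a modality value by a modal predicate
#'
#' A modal lowers the modality value proportional to its category strength
#' when the embedded value is closer to 1 (`mv >= 0.5`), and raises it
#' otherwise: `strength * mv` versus `mv + (1 - strength) * (1 - mv)`.
#'
#' @param strength category strength in \[0, 1\].
#' @param mv embedded modality value in \[0, 1\].
#' @return shifted modality value.
#' @export
apply_modal <- function(strength, mv) {
  stopifnot(strength >= 0, strength <= 1, mv >= 0, mv <= 1)
  out <- if (mv >= 0.5) strength * mv else mv + (1 - strength) * (1 - mv)
  clamp_mv(out)
}

#' Shift a modality value by a diminisher or intensifier
#'
#' Diminishers behave like modals (lowering toward the scale midpoint
#' according to their strength); intensifiers apply the symmetric raising
#' branch, pushing the value away from the midpoint.
#'
#' @param sem_type `"DIMINISHER"` or `"INTENSIFIER"`.
#' @param strength category strength in \[0, 1\].
#' @param mv embedded modality value.
#' @return shifted modality value.
#' @export
apply_shifter <- function(sem_type, strength, mv) {
  stopifnot(sem_type %in% c("DIMINISHER", "INTENSIFIER"),
            mv >= 0, mv <= 1)
  if (sem_type == "DIMINISHER") return(apply_modal(strength, mv))
  out <- if (mv >= 0.5) mv + (1 - strength) * (1 - mv) else strength * mv
  clamp_mv(out)
}

# ---------------------------------------------------------------------------
# Configuration
# ---------------------------------------------------------------------------

#' Pipeline and composition configuration
#'
#' @param track shared-task track: `"GENIA"`, `"EPI"` or `"ID"`.
#' @param lexicon a `trigger_lexicon`.
#' @param arg_rules argument identification rules.
#' @param type_rules predication-to-event type mapping rules.
#' @param role_rules logical-argument-to-role mapping rules.
#' @param event_defs event definition table.
#' @param propagation_depth maximum number of free nodes an argument may
#'   propagate through (`Inf` = unlimited, the default submission
#'   behaviour; `1` trades recall for precision).
#' @param coref_classes coreference classes to resolve (`"relat"`,
#'   `"appos"`, `"pron"`, `"dnp"`), or `"none"`.
#' @param compat_lexicons hypernym/meronym lists from [compat_lexicons()].
#' @param graph_opts graph transformation options from [graph_options()].
#' @return configuration list of class `compose_config`.
#' @export
compose_config <- function(track = "GENIA",
                           lexicon = default_lexicon(),
                           arg_rules = default_argument_rules(),
                           type_rules = default_type_mapping(),
                           role_rules = default_role_mapping(),
                           event_defs = default_event_definitions(),
                           propagation_depth = Inf,
                           coref_classes = c("relat", "appos", "pron", "dnp"),
                           compat_lexicons = bioscope::compat_lexicons(),
                           graph_opts = graph_options()) {
  stopifnot(track %in% c("GENIA", "EPI", "ID"),
            is.infinite(propagation_depth) || propagation_depth >= 1)
  structure(list(track = track, lexicon = lexicon, arg_rules = arg_rules,
                 type_rules = type_rules, role_rules = role_rules,
                 event_defs = event_defs,
                 propagation_depth = propagation_depth,
                 coref_classes = coref_classes,
                 compat_lexicons = compat_lexicons,
                 graph_opts = graph_opts),
            class = "compose_config")
}

# ---------------------------------------------------------------------------
# Document composition
# ---------------------------------------------------------------------------

# deterministic reverse-topological order (children before parents);
# ties broken by earliest character offset, then node id
reverse_topo_order <- function(graph) {
  nodes <- graph$nodes
  arcs <- graph_arcs(graph, "linked")
  indeg <- stats::setNames(rep(0L, nrow(nodes)), nodes$id)
  tab <- table(arcs$target)
  indeg[names(tab)] <- as.integer(tab)
  order_key <- order(nodes$start, nodes$id)
  pending <- nodes$id[order_key]
  out <- character(0)
  while (length(pending)) {
    avail <- pending[indeg[pending] == 0]
    if (!length(avail)) stop("embedding graph contains a cycle")
    v <- avail[1]
    pending <- setdiff(pending, v)
    out <- c(out, v)
    kids <- arcs$target[arcs$source == v]
    indeg[kids] <- indeg[kids] - 1L
  }
  rev(out)
}

#' Compose predications over a document embedding graph
#'
#' Traverses the graph bottom-up (children before parents). At each
#' trigger-bound node the logical arguments are identified via the rule
#' table, with argument propagation through semantically free chains,
#' substitution of anaphors by their COREF antecedents, and distribution
#' over coordination. Atomic predications initialize with the dictionary
#' polarity and modality value 1.0; embedding predications with the
#' category-strength-scaled default and the composed polarity. MODAL and
#' VALENCE_SHIFTER nodes percolate their modality effect onto the nearest
#' predication(s) in their scope, innermost operators first; negators
#' transfer to the complement of negative-raising predicates.
#'
#' @param graph an `embedding_graph` (with COREF arcs already added if
#'   coreference is enabled).
#' @param config a [compose_config()].
#' @return a `predication_set`.
#' @export
compose_document <- function(graph, config = compose_config()) {
  nodes <- graph$nodes
  arcs_all <- graph$arcs
  coref <- arcs_all[arcs_all$type == "COREF", , drop = FALSE]
  st <- new.env(parent = emptyenv())
  st$preds <- list()
  st$node_preds <- list()   # node id -> pred ids
  st$count <- 0L
  st$composed <- character(0)
  st$in_progress <- character(0)

  node_row <- function(id) nodes[match(id, nodes$id), , drop = FALSE]

  add_pred <- function(pr) {
    st$count <- st$count + 1L
    pr$id <- sprintf("p%d", st$count)
    st$preds[[pr$id]] <- pr
    st$node_preds[[pr$node]] <- c(st$node_preds[[pr$node]], pr$id)
    pr$id
  }

  # resolve a node into one or more argument values
  resolve_arg <- function(id, visited = character(0)) {
    if (id %in% visited) return(list())
    visited <- c(visited, id)
    nd <- node_row(id)
    if (isTRUE(nd$conj)) {  # conjunction nodes are never anaphors
      kids <- conjunct_nodes(graph, id)
      kids <- kids[order(nodes$start[match(kids, nodes$id)])]
      return(unlist(lapply(kids, resolve_arg, visited = visited),
                    recursive = FALSE))
    }
    ants <- coref$target[coref$source == id]
    if (length(ants) && nd$binding != "entity") {
      out <- unlist(lapply(ants, resolve_arg, visited = visited),
                    recursive = FALSE)
      if (length(out)) return(out)
    }
    if (nd$binding == "entity")
      return(list(pred_arg("entity", nd$ref, nd$text)))
    if (nd$binding == "predicate" &&
        embedding_class(nd$sem_type) != "valence_shifter") {
      # a COREF antecedent may sit higher in the graph than the anaphor and
      # not be composed yet: compose it on demand (guarded for re-entrancy)
      if (!length(st$node_preds[[id]]) && !(id %in% st$in_progress)) {
        compose_node(id)
      }
      pids <- st$node_preds[[id]]
      if (length(pids))
        return(lapply(pids, function(p) pred_arg("predication", p, nd$text)))
      return(list(pred_arg("free", id, nd$text)))
    }
    # semantically free (or transparent operator): argument propagation
    cands <- propagate_arguments(graph, id, config$propagation_depth)
    cands <- cands[!cands$node %in% visited, , drop = FALSE]
    if (nrow(cands)) {
      best <- cands$node[1]
      out <- resolve_arg(best, visited = visited)
      if (length(out)) return(out)
    }
    list(pred_arg("free", id, nd$text))
  }

  compose_node <- function(id) {
    if (id %in% st$composed) return(invisible(NULL))
    st$composed <- c(st$composed, id)
    st$in_progress <- c(st$in_progress, id)
    on.exit(st$in_progress <- setdiff(st$in_progress, id))
    nd <- node_row(id)
    assign <- identify_arguments(id, graph, config$arg_rules)
    assign <- assign[!is.na(assign$arg_type), , drop = FALSE]
    klass <- embedding_class(nd$sem_type)
    obj_opts <- list(NULL); subj_opts <- list(NULL); adj_opts <- list()
    obj_taken <- FALSE; subj_taken <- FALSE
    for (i in seq_len(nrow(assign))) {
      vals <- resolve_arg(assign$target[i], visited = id)
      if (!length(vals)) next
      at <- assign$arg_type[i]
      if (at == "Object" && !obj_taken) {
        obj_opts <- vals; obj_taken <- TRUE
      } else if (at == "Subject" && !subj_taken) {
        subj_opts <- vals; subj_taken <- TRUE
      } else if (at == "Adjunct") {
        adj_opts[[length(adj_opts) + 1]] <- vals
      }
    }
    # distribution over coordination / plural anaphora: one predication per
    # combination of slot values
    combos <- expand_slots(obj_opts, subj_opts, adj_opts)
    for (cb in combos) {
      # uniform initialization: the category strength scales the default
      # modality value (atomic triggers default to strength 1, hence mv 1);
      # the trigger polarity composes with the embedded polarity (reducing
      # to the dictionary polarity when no predication argument exists)
      emb_pol <- embedded_polarity(cb, st)
      pol <- compose_polarity(
        if (is.na(nd$polarity) || !nzchar(nd$polarity)) "neutral"
        else nd$polarity, emb_pol)
      mv <- clamp_mv((if (is.na(nd$strength)) 1 else nd$strength) *
                       default_mv())
      add_pred(new_predication(
        id = "pending", node = id, lemma = nd$lemma, sem_type = nd$sem_type,
        klass = klass, mv = mv, polarity = pol, object = cb$object,
        subject = cb$subject, adjuncts = cb$adjuncts,
        trigger = list(polarity = nd$polarity, strength = nd$strength,
                       negative_raising = isTRUE(nd$negative_raising))))
    }
  }

  # nearest predication-bearing nodes strictly below an operator node
  operator_targets <- function(id) {
    arcs <- graph_arcs(graph, "intra")
    frontier <- arcs$target[arcs$source == id]
    seen <- id
    hits <- character(0)
    while (length(frontier)) {
      frontier <- setdiff(unique(frontier), seen)
      seen <- c(seen, frontier)
      nxt <- character(0)
      for (f in frontier) {
        if (length(st$node_preds[[f]])) hits <- c(hits, st$node_preds[[f]])
        else nxt <- c(nxt, arcs$target[arcs$source == f])
      }
      frontier <- nxt
    }
    unique(hits)
  }

  apply_operator <- function(id) {
    nd <- node_row(id)
    strength <- if (is.na(nd$strength)) 1.0 else nd$strength
    for (pid in operator_targets(id)) {
      pr <- st$preds[[pid]]
      if (nd$sem_type == "NEGATOR") {
        emb <- embedded_pred_ids(pr)
        if (isTRUE(pr$trigger$negative_raising) && length(emb)) {
          # negative raising: negation transfers to the complement
          cp <- st$preds[[emb[1]]]
          cp$mv <- clamp_mv(apply_negator(cp$mv))
          cp$polarity <- compose_polarity("negative", cp$polarity)
          cp$negated <- TRUE
          st$preds[[cp$id]] <- cp
        } else {
          pr$mv <- clamp_mv(apply_negator(pr$mv))
          pr$polarity <- compose_polarity("negative", pr$polarity)
          pr$negated <- TRUE
        }
      } else if (nd$sem_type %in% c("DIMINISHER", "INTENSIFIER")) {
        pr$mv <- apply_shifter(nd$sem_type, strength, pr$mv)
      } else {  # MODAL
        pr$mv <- apply_modal(strength, pr$mv)
      }
      st$preds[[pid]] <- pr
    }
  }

  for (id in reverse_topo_order(graph)) {
    nd <- node_row(id)
    if (nd$binding != "predicate") next
    klass <- embedding_class(nd$sem_type)
    if (klass != "valence_shifter") compose_node(id)
    if (klass %in% c("valence_shifter", "modal")) apply_operator(id)
  }
  predication_set(st$preds, graph)
}

# cartesian expansion of multi-valued slots
expand_slots <- function(obj_opts, subj_opts, adj_opts) {
  combos <- list(list(object = NULL, subject = NULL, adjuncts = list()))
  expand_one <- function(combos, opts, slot) {
    out <- list()
    for (cb in combos) {
      for (v in opts) {
        cb2 <- cb
        if (slot == "adjunct") {
          if (!is.null(v)) cb2$adjuncts <- c(cb2$adjuncts, list(v))
        } else cb2[[slot]] <- v
        out[[length(out) + 1]] <- cb2
      }
    }
    out
  }
  combos <- expand_one(combos, obj_opts, "object")
  combos <- expand_one(combos, subj_opts, "subject")
  for (av in adj_opts) combos <- expand_one(combos, av, "adjunct")
  combos
}

embedded_polarity <- function(cb, st) {
  for (a in c(list(cb$object), list(cb$subject), cb$adjuncts)) {
    if (!is.null(a) && a$kind == "predication")
      return(st$preds[[a$ref]]$polarity)
  }
  NULL
}
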