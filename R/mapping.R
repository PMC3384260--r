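# Mapping phase: convert composed predications into shared-task event and
# modification annotations — type mapping, role mapping, pruning.

#' Load predication-to-event type mapping rules
#'
#' Rules constrain on track, predication (embedding) type, polarity and
#' modality value, and output an event type or a modification type
#' (NEGATION / SPECULATION). The shipped table marks rows taken from the
#' published core mapping versus rows added as consistent extensions in a
#' `source` column.
#'
#' @param source path to a 6-column TSV or a data.frame.
#' @return data.frame of class `type_mapping`.
#' @export
load_type_mapping <- function(source) {
  if (is.character(source)) {
    lines <- readLines(source, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    pad <- function(p) c(p, rep("core", 6 - length(p)))[1:6]
    m <- do.call(rbind, lapply(parts, pad))
    df <- data.frame(tracks = m[, 1], pred_type = m[, 2], polarity = m[, 3],
                     mv = m[, 4], output = m[, 5], source = m[, 6],
                     stringsAsFactors = FALSE)
  } else df <- as.data.frame(source, stringsAsFactors = FALSE)
  df$track_set <- lapply(strsplit(df$tracks, ",", fixed = TRUE), trimws)
  class(df) <- c("type_mapping", "data.frame")
  df
}

#' @rdname load_type_mapping
#' @export
default_type_mapping <- function() {
  load_type_mapping(system.file("extdata", "type_mapping.tsv",
                                package = "bioscope"))
}

#' Load logical-argument-to-role mapping rules
#'
#' @param source path to a 4-column TSV (`logical`, `constrained_to`,
#'   `exclusions`, `role`) or a data.frame.
#' @return data.frame of class `role_mapping`.
#' @export
load_role_mapping <- function(source) {
  if (is.character(source)) {
    lines <- readLines(source, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    m <- do.call(rbind, parts)
    df <- data.frame(logical = m[, 1], constrained_to = m[, 2],
                     exclusions = m[, 3], role = m[, 4],
                     stringsAsFactors = FALSE)
  } else df <- as.data.frame(source, stringsAsFactors = FALSE)
  parse_set <- function(x) lapply(x, function(s) {
    if (is.na(s) || s == "-" || !nzchar(s)) character(0)
    else toupper(trimws(strsplit(s, ",", fixed = TRUE)[[1]]))
  })
  df$con <- parse_set(df$constrained_to)
  df$exc <- parse_set(df$exclusions)
  bad <- mapply(function(a, b) length(intersect(a, b)) > 0, df$con, df$exc)
  if (any(bad)) stop("role rule constraint sets overlap at row ",
                     which(bad)[1])
  class(df) <- c("role_mapping", "data.frame")
  df
}

#' @rdname load_role_mapping
#' @export
default_role_mapping <- function() {
  load_role_mapping(system.file("extdata", "role_mapping.tsv",
                                package = "bioscope"))
}

#' Load per-track event definitions
#'
#' @param source path to a 4-column TSV (`track`, `event_type`,
#'   `allowed roles`, `mandatory roles`) or a data.frame. `Role+` marks a
#'   repeatable role; `-` means no mandatory role (e.g. PROCESS, which may
#'   take no participants at all).
#' @return data.frame of class `event_definitions`.
#' @export
load_event_definitions <- function(source) {
  if (is.character(source)) {
    lines <- readLines(source, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    m <- do.call(rbind, parts)
    df <- data.frame(track = m[, 1], event_type = m[, 2], allowed = m[, 3],
                     mandatory = m[, 4], stringsAsFactors = FALSE)
  } else df <- as.data.frame(source, stringsAsFactors = FALSE)
  parse_roles <- function(x) lapply(x, function(s) {
    if (is.na(s) || s == "-" || !nzchar(s)) character(0)
    else trimws(strsplit(s, ",", fixed = TRUE)[[1]])
  })
  df$allowed_set <- lapply(parse_roles(df$allowed),
                           function(r) sub("\\+$", "", r))
  df$mandatory_set <- parse_roles(df$mandatory)
  class(df) <- c("event_definitions", "data.frame")
  df
}

#' @rdname load_event_definitions
#' @export
default_event_definitions <- function() {
  load_event_definitions(system.file("extdata", "event_definitions.tsv",
                                     package = "bioscope"))
}

parse_mv_constraint <- function(s) {
  if (is.na(s) || s == "-" || !nzchar(s)) return(function(mv) TRUE)
  m <- regmatches(s, regexec("^(>=|<=|>|<|=)\\s*([0-9.]+)$", s))[[1]]
  if (length(m) != 3) stop("bad modality value constraint: ", s)
  thr <- as.numeric(m[3])
  switch(m[2],
         ">" = function(mv) mv > thr, ">=" = function(mv) mv >= thr,
         "<" = function(mv) mv < thr, "<=" = function(mv) mv <= thr,
         "=" = function(mv) mv == thr)
}

#' Map predication types to event / modification types
#'
#' Atomic predications keep their event type. Embedding predications match
#' against the type-mapping rules (track, predication type, polarity,
#' modality value); unmatched embedding predications are unmappable
#' (`NA`). Attributive predications are always unmappable themselves (their
#' arguments transfer to the embedded predication, see [map_events()]).
#'
#' @param ps a `predication_set`.
#' @param rules a `type_mapping` table.
#' @param track track name.
#' @return data.frame with `pred_id`, `out_type` (`NA` if unmappable) and
#'   `is_mod` (modification vs event type).
#' @export
map_types <- function(ps, rules = default_type_mapping(), track = "GENIA") {
  rows <- lapply(ps$predications, function(pr) {
    out <- NA_character_
    if (pr$klass == "atomic") {
      out <- pr$sem_type
    } else if (pr$klass != "attributive") {
      for (r in seq_len(nrow(rules))) {
        if (!track %in% rules$track_set[[r]]) next
        if (rules$pred_type[r] != pr$sem_type) next
        polc <- rules$polarity[r]
        if (polc != "-" && nzchar(polc) && polc != pr$polarity) next
        if (!parse_mv_constraint(rules$mv[r])(pr$mv)) next
        out <- rules$output[r]
        break
      }
    }
    data.frame(pred_id = pr$id, out_type = out,
               is_mod = !is.na(out) && out %in% c("NEGATION", "SPECULATION"),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame(pred_id = character(0),
                                    out_type = character(0),
                                    is_mod = logical(0))
  rownames(df) <- NULL
  df
}

#' Map logical arguments to semantic roles
#'
#' Object maps to Theme (except PROCESS), Subject to Cause (except BINDING,
#' whose Subject is a Theme), Object to Participant for PROCESS and to
#' Scope for SPECULATION/NEGATION. Arguments matched by no rule carry no
#' role and are discarded during pruning.
#'
#' @param pr a `predication`.
#' @param out_type mapped event/modification type of the predication.
#' @param rules a `role_mapping` table.
#' @return list of participants: `role`, `kind` (`entity`/`free`/
#'   `predication`), `ref`.
#' @export
map_roles <- function(pr, out_type, rules = default_role_mapping()) {
  logi <- c(if (!is.null(pr$object)) list(list(arg = pr$object,
                                               logical = "Object")),
            if (!is.null(pr$subject)) list(list(arg = pr$subject,
                                                logical = "Subject")),
            lapply(pr$adjuncts, function(a) list(arg = a,
                                                 logical = "Adjunct")))
  out <- list()
  for (la in logi) {
    role <- NA_character_
    for (r in seq_len(nrow(rules))) {
      if (rules$logical[r] != la$logical) next
      con <- rules$con[[r]]
      if (length(con) && !(toupper(out_type) %in% con)) next
      if (toupper(out_type) %in% rules$exc[[r]]) next
      role <- rules$role[r]
      break
    }
    if (is.na(role)) next
    out[[length(out) + 1]] <- list(role = role, kind = la$arg$kind,
                                   ref = la$arg$ref)
  }
  out
}

# transfer entity/free arguments of attributive predications to the
# embedded predication (e.g. "p105 undergoes degradation": p105 becomes the
# Theme of the degradation)
transfer_attributive <- function(ps) {
  for (pr in ps$predications) {
    if (pr$klass != "attributive") next
    emb <- embedded_pred_ids(pr)
    if (!length(emb)) next
    target <- ps$predications[[emb[1]]]
    simple <- Filter(function(a) !is.null(a) && a$kind != "predication",
                     c(list(pr$object), list(pr$subject), pr$adjuncts))
    for (a in simple) {
      if (is.null(target$object)) target$object <- a
      else if (is.null(target$subject)) target$subject <- a
      else target$adjuncts <- c(target$adjuncts, list(a))
    }
    ps$predications[[target$id]] <- target
  }
  ps
}

#' Prune role-bound events against the event definitions
#'
#' Drops participants that do not conform to the event definition or are
#' semantically free, drops predications whose types could not be mapped,
#' drops events missing a mandatory participant (PROCESS excepted: it may
#' take no participants at all), and cascades: an event referencing a
#' dropped sub-event loses that participant and is re-tested.
#'
#' @param events list of candidate events (as built by [map_events()]).
#' @param defs an `event_definitions` table.
#' @param track track name.
#' @return pruned list of events.
#' @export
prune_events <- function(events, defs = default_event_definitions(),
                         track = "GENIA") {
  defs <- defs[defs$track == track, , drop = FALSE]
  alive <- events
  repeat {
    changed <- FALSE
    # drop events of undefined type
    keep <- vapply(alive, function(ev) ev$type %in% defs$event_type,
                   logical(1))
    if (any(!keep)) changed <- TRUE
    alive <- alive[keep]
    mapped_preds <- vapply(alive, `[[`, character(1), "pred_id")
    nxt <- list()
    for (ev in alive) {
      def <- defs[defs$event_type == ev$type, , drop = FALSE][1, ]
      roles <- Filter(function(r) {
        if (!(r$role %in% def$allowed_set[[1]])) return(FALSE)
        if (r$kind == "free") return(FALSE)
        if (r$kind == "predication" && !(r$ref %in% mapped_preds))
          return(FALSE)
        TRUE
      }, ev$roles)
      if (length(roles) != length(ev$roles)) changed <- TRUE
      ev$roles <- roles
      have <- vapply(roles, `[[`, character(1), "role")
      mandatory_ok <- all(def$mandatory_set[[1]] %in% have)
      if (!mandatory_ok) {
        changed <- TRUE
        next
      }
      nxt[[length(nxt) + 1]] <- ev
    }
    alive <- nxt
    if (!changed) break
  }
  alive
}

# coordination distribution over adjunct slots can yield events that are
# indistinguishable in the output (same type, trigger and roles); keep the
# first of each equivalence class and remember the representative so scope
# lookups still resolve
dedup_events <- function(events, mod_sources) {
  pred_rep <- list()
  repeat {
    canon <- function(ref) if (!is.null(pred_rep[[ref]])) pred_rep[[ref]] else ref
    keys <- vapply(events, function(ev) {
      rr <- vapply(ev$roles, function(r) {
        ref <- if (r$kind == "predication") canon(r$ref) else r$ref
        paste(r$role, r$kind, ref)
      }, character(1))
      paste(ev$type, ev$trigger_start, ev$trigger_end,
            paste(sort(rr), collapse = "|"))
    }, character(1))
    dup <- duplicated(keys)
    if (!any(dup)) break
    for (i in which(dup)) {
      keep <- which(keys == keys[i])[1]
      pred_rep[[events[[i]]$pred_id]] <- events[[keep]]$pred_id
    }
    events <- events[!dup]
  }
  # rewrite role references through the representatives
  events <- lapply(events, function(ev) {
    ev$roles <- lapply(ev$roles, function(r) {
      if (r$kind == "predication" && !is.null(pred_rep[[r$ref]]))
        r$ref <- pred_rep[[r$ref]]
      r
    })
    ev
  })
  list(events = events, pred_rep = pred_rep)
}

#' Map a predication set to shared-task annotations
#'
#' Runs type mapping, attributive-argument transfer, role mapping and
#' pruning, and derives Speculation/Negation modifications: a predication
#' mapped to a modification type marks the nearest mapped event(s) in its
#' scope; an event whose predication was negated by a NEGATOR carries a
#' Negation modification.
#'
#' @param ps a `predication_set` (with its graph, for trigger spans).
#' @param config a [compose_config()].
#' @return an `event_set`: list with `events`, `modifications`, `track`.
#' @export
map_events <- function(ps, config = compose_config()) {
  ps <- transfer_attributive(ps)
  tm <- map_types(ps, config$type_rules, config$track)
  graph <- ps$graph
  events <- list()
  mod_sources <- list()
  for (i in seq_len(nrow(tm))) {
    pr <- ps$predications[[tm$pred_id[i]]]
    if (is.na(tm$out_type[i])) next
    if (tm$is_mod[i]) {
      mod_sources[[length(mod_sources) + 1]] <-
        list(type = if (tm$out_type[i] == "NEGATION") "NEGATION"
             else "SPECULATION", pred = pr)
      next
    }
    nd <- if (!is.null(graph)) graph_node(graph, pr$node) else NULL
    ev <- list(pred_id = pr$id, type = tm$out_type[i],
               trigger_start = if (!is.null(nd)) nd$start else 0L,
               trigger_end = if (!is.null(nd)) nd$end else 0L,
               trigger_text = if (!is.null(nd)) nd$text else pr$lemma,
               roles = map_roles(pr, tm$out_type[i], config$role_rules))
    events[[length(events) + 1]] <- ev
  }
  events <- prune_events(events, config$event_defs, config$track)
  dd <- dedup_events(events, mod_sources)
  events <- dd$events
  pred_rep <- dd$pred_rep
  mapped <- vapply(events, `[[`, character(1), "pred_id")

  # nearest mapped events within the scope of a predication
  scope_events <- function(pr) {
    frontier <- embedded_pred_ids(pr)
    seen <- character(0)
    hits <- character(0)
    while (length(frontier)) {
      frontier <- setdiff(frontier, seen)
      seen <- c(seen, frontier)
      nxt <- character(0)
      for (f in frontier) {
        fr <- if (!is.null(pred_rep[[f]])) pred_rep[[f]] else f
        if (fr %in% mapped) hits <- c(hits, fr)
        else nxt <- c(nxt, embedded_pred_ids(ps$predications[[f]]))
      }
      frontier <- nxt
    }
    unique(hits)
  }

  mods <- list()
  add_mod <- function(type, target_pred) {
    key <- paste(type, target_pred)
    have <- vapply(mods, function(m) paste(m$type, m$target), character(1))
    if (!key %in% have)
      mods[[length(mods) + 1]] <<- list(type = type, target = target_pred)
  }
  for (ms in mod_sources) {
    mtype <- if (ms$type == "NEGATION") "NEGATION" else "SPECULATION"
    for (tp in scope_events(ms$pred)) add_mod(mtype, tp)
  }
  negated_nodes <- unique(vapply(
    Filter(function(p) isTRUE(p$negated), ps$predications),
    `[[`, character(1), "node"))
  for (ev in events) {
    pr <- ps$predications[[ev$pred_id]]
    if (isTRUE(pr$negated) || pr$node %in% negated_nodes)
      add_mod("NEGATION", ev$pred_id)
  }
  structure(list(events = events, modifications = mods,
                 track = config$track), class = "event_set")
}

#' @export
print.event_set <- function(x, ...) {
  cat(sprintf("<event_set (%s): %d events, %d modifications>\n", x$track,
              length(x$events), length(x$modifications)))
  invisible(x)
}
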