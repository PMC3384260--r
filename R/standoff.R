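# Standoff I/O: .txt/.a1 readers, dependency parse readers (two dialects),
# .a2 writer/reader, and the document pipeline.

#' Read a document and its entity annotations
#'
#' Reads BioNLP standoff input: the document text and the `.a1` file of
#' text-bound entity annotations (`T` lines, tab-separated:
#' `Tid <TAB> Type start end <TAB> text`). Offsets are 0-based, half-open.
#' Each entity's quoted text is validated against the document substring.
#'
#' @param txt_path path to the `.txt` file.
#' @param a1_path path to the `.a1` file (may be missing: no entities).
#' @return a list of class `standoff_document` with `doc_id`, `text` and
#'   `entities` (data.frame `id`, `type`, `start`, `end`, `text`).
#' @export
read_txt_a1 <- function(txt_path, a1_path = NULL) {
  text <- paste(readLines(txt_path, warn = FALSE, encoding = "UTF-8"),
                collapse = "\n")
  doc_id <- sub("\\.txt$", "", basename(txt_path))
  entities <- empty_entities()
  if (!is.null(a1_path) && file.exists(a1_path)) {
    lines <- readLines(a1_path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    for (ln in lines) {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (!startsWith(f[1], "T"))
        stop("unsupported .a1 line (only T lines allowed): ", ln)
      if (length(f) < 3) stop("malformed .a1 line: ", ln)
      hdr <- strsplit(f[2], " ", fixed = TRUE)[[1]]
      start <- as.integer(hdr[2]); end <- as.integer(hdr[3])
      span_text <- substring(text, start + 1, end)
      if (!identical(span_text, f[3]))
        stop(sprintf("entity text mismatch at %s: span [%d,%d) is %s, line says %s",
                     f[1], start, end, dQuote(span_text), dQuote(f[3])))
      entities <- rbind(entities,
                        data.frame(id = f[1], type = hdr[1], start = start,
                                   end = end, text = f[3],
                                   stringsAsFactors = FALSE))
    }
    if (anyDuplicated(entities$id)) stop("duplicate entity ids in ", a1_path)
  }
  structure(list(doc_id = doc_id, text = text, entities = entities),
            class = "standoff_document")
}

#' @export
print.standoff_document <- function(x, ...) {
  cat(sprintf("<standoff_document %s: %d chars, %d entities>\n",
              x$doc_id, nchar(x$text), nrow(x$entities)))
  invisible(x)
}

# special bracket tokens used by constituency-derived tokenisation
PTB_FORMS <- c("-LRB-" = "(", "-RRB-" = ")", "``" = "\"", "''" = "\"",
               "-LSB-" = "[", "-RSB-" = "]")

align_tokens <- function(forms, text, cursor = 0L) {
  starts <- integer(length(forms)); ends <- integer(length(forms))
  for (i in seq_along(forms)) {
    f <- forms[i]
    if (f %in% names(PTB_FORMS)) f <- PTB_FORMS[[f]]
    at <- regexpr(f, substring(text, cursor + 1), fixed = TRUE)
    if (at < 0) {  # not found: synthesize position after cursor
      starts[i] <- cursor
      ends[i] <- cursor + nchar(f)
    } else {
      starts[i] <- cursor + at - 1L
      ends[i] <- starts[i] + nchar(f)
    }
    cursor <- ends[i]
  }
  list(starts = starts, ends = ends, cursor = cursor)
}

#' Read per-sentence dependency parses
#'
#' Two documented dialects, auto-detected per file:
#' \describe{
#'   \item{CoNLL-style}{tab-separated rows `index form lemma pos head label`,
#'     one sentence per blank-line-separated block. `head = 0` marks the
#'     root.}
#'   \item{Constraint-style}{`label(governor-form-idx, dependent-form-idx)`
#'     lines, e.g. `prep_of(involvement-3, HCMV-5)`, one sentence per
#'     blank-line-separated block. Token forms are recovered from the
#'     mentions; lemma defaults to the lowercased form and POS is unknown.}
#' }
#' Labels are preserved verbatim (e.g. `conj_and`, `prep_of`). If `text` is
#' supplied, token character offsets are aligned to it left to right.
#'
#' @param path dependency file.
#' @param text optional document text for offset alignment.
#' @return list of sentences, each a list with `tokens` and `deps`
#'   data.frames.
#' @export
read_dependencies <- function(path, text = NULL) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*#", lines)]
  blocks <- split_blocks(lines)
  cursor <- 0L
  out <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    blk <- blocks[[b]]
    parsed <- if (all(grepl("^[^\t]+\\(.*\\)\\s*$", blk)))
      parse_paren_block(blk, b) else parse_conll_block(blk, b)
    if (!is.null(text)) {
      al <- align_tokens(parsed$tokens$form, text, cursor)
      parsed$tokens$start <- al$starts
      parsed$tokens$end <- al$ends
      cursor <- al$cursor
    }
    out[[b]] <- parsed
  }
  out
}

split_blocks <- function(lines) {
  blank <- !nzchar(trimws(lines))
  grp <- cumsum(blank)
  keep <- split(lines[!blank], grp[!blank])
  unname(keep[lengths(keep) > 0])
}

parse_conll_block <- function(blk, b) {
  parts <- strsplit(blk, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 6)
  if (length(bad))
    stop(sprintf("malformed CoNLL row (sentence %d, line %d): %s",
                 b, bad[1], blk[bad[1]]))
  m <- do.call(rbind, lapply(parts, `[`, 1:6))
  idx_all <- as.integer(m[, 1])
  if (any(is.na(idx_all)))
    stop("malformed CoNLL token index in sentence ", b)
  # a repeated index row adds a further dependency for that token (tokens
  # may have several governors in the collapsed representation); token
  # attributes come from its first row
  first <- !duplicated(idx_all)
  tokens <- data.frame(idx = idx_all[first], form = m[first, 2],
                       lemma = m[first, 3], pos = m[first, 4],
                       start = NA_integer_, end = NA_integer_,
                       stringsAsFactors = FALSE)
  tokens <- tokens[order(tokens$idx), , drop = FALSE]
  deps <- data.frame(label = m[, 6], gov = as.integer(m[, 5]),
                     dep = idx_all, stringsAsFactors = FALSE)
  deps <- deps[deps$gov > 0, , drop = FALSE]
  # synthetic offsets when no text is supplied (space-joined)
  tokens$start <- cumsum(c(0L, nchar(tokens$form[-nrow(tokens)]) + 1L))
  tokens$end <- tokens$start + nchar(tokens$form)
  rownames(deps) <- NULL
  list(tokens = tokens, deps = deps)
}

parse_paren_block <- function(blk, b) {
  rx <- "^([^()\t]+)\\((.+)-([0-9]+)'*,\\s*(.+)-([0-9]+)'*\\)\\s*$"
  m <- regmatches(blk, regexec(rx, blk))
  bad <- which(lengths(m) != 6)
  if (length(bad))
    stop(sprintf("malformed dependency line (sentence %d, line %d): %s",
                 b, bad[1], blk[bad[1]]))
  lab <- vapply(m, `[`, character(1), 2)
  gform <- vapply(m, `[`, character(1), 3)
  gidx <- as.integer(vapply(m, `[`, character(1), 4))
  dform <- vapply(m, `[`, character(1), 5)
  didx <- as.integer(vapply(m, `[`, character(1), 6))
  idx <- sort(unique(c(gidx, didx)))
  forms <- character(max(idx))
  forms[gidx] <- gform; forms[didx] <- dform
  present <- seq_len(max(idx)) %in% idx
  tokens <- data.frame(idx = which(present), form = forms[present],
                       lemma = tolower(forms[present]), pos = "",
                       start = NA_integer_, end = NA_integer_,
                       stringsAsFactors = FALSE)
  tokens$start <- cumsum(c(0L, nchar(tokens$form[-nrow(tokens)]) + 1L))
  tokens$end <- tokens$start + nchar(tokens$form)
  deps <- data.frame(label = lab, gov = gidx, dep = didx,
                     stringsAsFactors = FALSE)
  list(tokens = tokens, deps = deps)
}

# ---------------------------------------------------------------------------
# .a2 serialization
# ---------------------------------------------------------------------------

task_type_label <- function(type) {
  paste0(substr(type, 1, 1), tolower(substring(type, 2)))
}

#' Serialize events and modifications to .a2 standoff lines
#'
#' Trigger `T` lines are numbered after the highest `T` index of the input
#' `.a1` entities; `E` lines render as
#' `E<k><TAB><Type>:<Ttrigger> <Role>:<ref> ...`; `M` lines as
#' `M<k><TAB><Negation|Speculation> E<j>`. Ordering is deterministic:
#' document order of the trigger span, then event type. Repeated roles on
#' one event are numbered (`Theme`, `Theme2`, ...). Dangling references
#' cause an error before anything is written.
#'
#' @param es an `event_set` from [map_events()].
#' @param entities entity data.frame (the `.a1` content).
#' @param path optional output file.
#' @return character vector of `.a2` lines (invisibly if `path` given).
#' @export
write_a2 <- function(es, entities = empty_entities(), path = NULL) {
  events <- es$events
  mods <- es$modifications
  a1_max <- if (nrow(entities)) {
    suppressWarnings(max(as.integer(sub("^T", "", entities$id)), 0L))
  } else 0L
  if (length(events)) {
    ord <- order(vapply(events, `[[`, numeric(1), "trigger_start"),
                 vapply(events, `[[`, numeric(1), "trigger_end"),
                 vapply(events, `[[`, character(1), "type"))
    events <- events[ord]
  }
  eid_of <- stats::setNames(sprintf("E%d", seq_along(events)),
                            vapply(events, `[[`, character(1), "pred_id"))
  # referential closure check
  for (ev in events) {
    for (role in ev$roles) {
      ok <- if (role$kind == "entity") role$ref %in% entities$id
            else role$ref %in% names(eid_of)
      if (!ok)
        stop("dangling reference in event ", ev$pred_id, ": ",
             role$role, ":", role$ref)
    }
  }
  for (m in mods) {
    if (!m$target %in% names(eid_of))
      stop("dangling modification target: ", m$target)
  }
  # trigger T lines: one per (type, span)
  tkey <- vapply(events, function(ev)
    paste(ev$type, ev$trigger_start, ev$trigger_end), character(1))
  t_unique <- !duplicated(tkey)
  t_ids <- stats::setNames(sprintf("T%d", a1_max + seq_len(sum(t_unique))),
                           tkey[t_unique])
  t_lines <- vapply(which(t_unique), function(i) {
    ev <- events[[i]]
    sprintf("%s\t%s %d %d\t%s", t_ids[[tkey[i]]],
            task_type_label(ev$type), ev$trigger_start, ev$trigger_end,
            ev$trigger_text)
  }, character(1))
  e_lines <- vapply(seq_along(events), function(i) {
    ev <- events[[i]]
    role_names <- vapply(ev$roles, `[[`, character(1), "role")
    counts <- stats::ave(seq_along(role_names), role_names, FUN = seq_along)
    rendered <- vapply(seq_along(ev$roles), function(k) {
      r <- ev$roles[[k]]
      nm <- if (counts[k] > 1) paste0(r$role, counts[k]) else r$role
      ref <- if (r$kind == "entity") r$ref else eid_of[[r$ref]]
      paste0(nm, ":", ref)
    }, character(1))
    paste0(sprintf("E%d\t%s:%s", i, task_type_label(ev$type),
                   t_ids[[tkey[i]]]),
           if (length(rendered)) paste0(" ", paste(rendered, collapse = " "))
           else "")
  }, character(1))
  m_lines <- if (length(mods)) {
    ord <- order(vapply(mods, function(m) eid_of[[m$target]], character(1)),
                 vapply(mods, `[[`, character(1), "type"))
    mods <- mods[ord]
    vapply(seq_along(mods), function(i)
      sprintf("M%d\t%s %s", i, task_type_label(mods[[i]]$type),
              eid_of[[mods[[i]]$target]]), character(1))
  } else character(0)
  lines <- c(t_lines, e_lines, m_lines)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Parse .a2 standoff lines
#'
#' Inverse of [write_a2()] up to identifier naming: returns triggers, events
#' and modifications as data.frames for round-trip checks and downstream
#' comparison.
#'
#' @param lines character vector of `.a2` lines, or a file path.
#' @return list with `triggers`, `events`, `modifications` data.frames.
#' @export
read_a2 <- function(lines) {
  if (length(lines) == 1 && file.exists(lines)) {
    lines <- readLines(lines, warn = FALSE, encoding = "UTF-8")
  }
  lines <- lines[nzchar(trimws(lines))]
  triggers <- data.frame(id = character(0), type = character(0),
                         start = integer(0), end = integer(0),
                         text = character(0), stringsAsFactors = FALSE)
  events <- list(); mods <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    tag <- substr(f[1], 1, 1)
    if (tag == "T") {
      hdr <- strsplit(f[2], " ", fixed = TRUE)[[1]]
      triggers <- rbind(triggers, data.frame(
        id = f[1], type = hdr[1], start = as.integer(hdr[2]),
        end = as.integer(hdr[3]), text = f[3], stringsAsFactors = FALSE))
    } else if (tag == "E") {
      parts <- strsplit(f[2], " ", fixed = TRUE)[[1]]
      head <- strsplit(parts[1], ":", fixed = TRUE)[[1]]
      roles <- lapply(parts[-1], function(p) {
        kv <- strsplit(p, ":", fixed = TRUE)[[1]]
        list(role = kv[1], ref = kv[2])
      })
      events[[length(events) + 1]] <- list(id = f[1], type = head[1],
                                           trigger = head[2], roles = roles)
    } else if (tag == "M") {
      kv <- strsplit(f[2], " ", fixed = TRUE)[[1]]
      mods[[length(mods) + 1]] <- list(id = f[1], type = kv[1],
                                       target = kv[2])
    } else stop("unsupported .a2 line: ", ln)
  }
  list(triggers = triggers, events = events, modifications = mods)
}

# ---------------------------------------------------------------------------
# Pipeline
# ---------------------------------------------------------------------------

#' Process one standoff document end to end
#'
#' Read the text/entities/parses, build the embedding graph, resolve
#' coreference, compose predications, map them to shared-task annotations.
#'
#' @param doc a `standoff_document` (or path to a `.txt`; the matching `.a1`
#'   and `.dep` are looked up next to it).
#' @param deps per-sentence parses from [read_dependencies()] (required when
#'   `doc` is an object).
#' @param config pipeline configuration from [compose_config()].
#' @return list with `graph`, `predications`, `events`, `a2` (lines) and
#'   per-stage counters.
#' @export
extract_events <- function(doc, deps = NULL, config = compose_config()) {
  if (is.character(doc)) {
    txt <- doc
    a1 <- sub("\\.txt$", ".a1", txt)
    dp <- sub("\\.txt$", ".dep", txt)
    if (!file.exists(dp)) dp <- sub("\\.txt$", ".sd", txt)
    doc <- read_txt_a1(txt, if (file.exists(a1)) a1 else NULL)
    if (!file.exists(dp)) stop("no dependency file found for ", txt)
    deps <- read_dependencies(dp, doc$text)
  }
  if (is.null(deps)) stop("per-sentence dependency parses are required")
  subgraphs <- lapply(seq_along(deps), function(i) {
    build_sentence_graph(deps[[i]]$tokens, deps[[i]]$deps, doc$entities,
                         config$lexicon, sentence = i,
                         opts = config$graph_opts)
  })
  graph <- link_sentences(subgraphs, doc$text, doc$entities, doc$doc_id)
  assert_acyclic(graph)
  graph <- resolve_coreference(graph, classes = config$coref_classes,
                               lexicons = config$compat_lexicons)
  ps <- compose_document(graph, config)
  es <- map_events(ps, config)
  a2 <- write_a2(es, doc$entities)
  counters <- c(nodes = nrow(graph$nodes),
                arcs = nrow(graph$arcs),
                coref_arcs = nrow(graph_arcs(graph, "coref")),
                predications = length(ps$predications),
                events = length(es$events),
                modifications = length(es$modifications))
  list(doc = doc, graph = graph, predications = ps, events = es, a2 = a2,
       counters = counters)
}

#' Run the pipeline over a directory of standoff documents
#'
#' For every `<id>.txt` in `input_dir` with a matching `<id>.dep` (or
#' `<id>.sd`) dependency file and optional `<id>.a1`, produces `<id>.a2` in
#' `output_dir`.
#'
#' @param input_dir directory of input documents.
#' @param output_dir directory for `.a2` output (created if needed).
#' @param config pipeline configuration from [compose_config()].
#' @param verbose print per-document stage counters.
#' @return data.frame of per-document counters, invisibly.
#' @export
run_pipeline <- function(input_dir, output_dir, config = compose_config(),
                         verbose = FALSE) {
  txts <- sort(list.files(input_dir, pattern = "\\.txt$", full.names = TRUE))
  if (!length(txts)) stop("no .txt documents in ", input_dir)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(txts, function(txt) {
    res <- extract_events(txt, config = config)
    out <- file.path(output_dir, paste0(res$doc$doc_id, ".a2"))
    writeLines(res$a2, out)
    if (verbose)
      message(res$doc$doc_id, ": ",
              paste(names(res$counters), res$counters, sep = "=",
                    collapse = " "))
    data.frame(doc_id = res$doc$doc_id, t(res$counters),
               stringsAsFactors = FALSE)
  })
  invisible(do.call(rbind, rows))
}
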