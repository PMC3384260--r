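# Trigger lexicon: load/validate the six-feature dictionary, match triggers
# in tokenized text, assign atomic event types by maximum likelihood.

#' Load a trigger lexicon
#'
#' The lexicon file is tab-separated with six columns per record and `#`
#' comments: lemma, POS, semantic type, polarity, category strength,
#' negative-raising. Multi-word triggers use spaces inside the lemma column.
#' Blank feature columns default to polarity `neutral`, strength `1.0` and
#' negative raising `false`.
#'
#' @param source path to a lexicon TSV, or a data.frame with columns
#'   `lemma`, `pos`, `sem_type`, `polarity`, `strength`, `negative_raising`.
#' @return an object of class `trigger_lexicon`: a data.frame of entries
#'   indexed by (lemma, pos).
#' @export
load_lexicon <- function(source) {
  if (is.character(source)) {
    lines <- readLines(source, warn = FALSE, encoding = "UTF-8")
    lines <- sub("#.*$", "", lines)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) return(as_lexicon(empty_lexicon_df()))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 3)
    if (length(bad))
      stop("lexicon rows with fewer than 3 fields: line(s) ",
           paste(bad, collapse = ", "))
    pad <- function(p) c(p, rep("", 6 - length(p)))[1:6]
    m <- do.call(rbind, lapply(parts, pad))
    df <- data.frame(lemma = trimws(m[, 1]), pos = trimws(m[, 2]),
                     sem_type = trimws(m[, 3]), polarity = trimws(m[, 4]),
                     strength = trimws(m[, 5]),
                     negative_raising = trimws(m[, 6]),
                     stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(source, stringsAsFactors = FALSE)
  }
  df$lemma <- tolower(df$lemma)
  df$sem_type <- toupper(df$sem_type)
  df$polarity[!nzchar(as.character(df$polarity)) | is.na(df$polarity)] <- "neutral"
  s <- as.character(df$strength)
  s[!nzchar(s) | is.na(s)] <- "1"
  df$strength <- suppressWarnings(as.numeric(s))
  nr <- tolower(as.character(df$negative_raising))
  df$negative_raising <- nr %in% c("true", "t", "1", "yes")

  errs <- character(0)
  bad_str <- which(is.na(df$strength) | df$strength < 0 | df$strength > 1)
  if (length(bad_str))
    errs <- c(errs, paste0("strength outside [0,1] at row(s) ",
                           paste(bad_str, collapse = ", ")))
  bad_pol <- which(!df$polarity %in% POLARITIES)
  if (length(bad_pol))
    errs <- c(errs, paste0("unknown polarity at row(s) ",
                           paste(bad_pol, collapse = ", ")))
  key <- paste(df$lemma, df$pos)
  dup <- duplicated(key)
  if (any(dup)) {
    # duplicates that agree on the semantic type are merged silently;
    # conflicting types violate the one-type-per-predicate constraint
    conflict <- vapply(unique(key[dup]), function(k) {
      length(unique(df$sem_type[key == k])) > 1
    }, logical(1))
    if (any(conflict))
      errs <- c(errs, paste0("conflicting semantic types for (lemma,pos): ",
                             paste(unique(key[dup])[conflict], collapse = "; ")))
    df <- df[!dup, , drop = FALSE]
  }
  if (length(errs)) stop("lexicon load errors:\n  ", paste(errs, collapse = "\n  "))
  rownames(df) <- NULL
  as_lexicon(df)
}

empty_lexicon_df <- function() {
  data.frame(lemma = character(0), pos = character(0),
             sem_type = character(0), polarity = character(0),
             strength = numeric(0), negative_raising = logical(0),
             stringsAsFactors = FALSE)
}

as_lexicon <- function(df) {
  df$n_words <- lengths(strsplit(df$lemma, " ", fixed = TRUE))
  class(df) <- c("trigger_lexicon", "data.frame")
  df
}

#' Write a trigger lexicon to a TSV file
#' @param lexicon a `trigger_lexicon`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  df <- as.data.frame(lexicon)[, c("lemma", "pos", "sem_type", "polarity",
                                   "strength", "negative_raising")]
  df$negative_raising <- ifelse(df$negative_raising, "true", "false")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' The trigger lexicon shipped with the package
#'
#' A seed dictionary covering common GENIA/EPI/ID event triggers and the
#' embedding predicates (modals, relationals, valence shifters) used in the
#' package's worked examples and tests.
#'
#' @return a `trigger_lexicon`.
#' @export
default_lexicon <- function() {
  load_lexicon(system.file("extdata", "triggers.tsv", package = "bioscope"))
}

# coarse POS match: lexicon entries carry coarse tags (VB, NN, JJ, RB, MD,
# DT, PRP); token tags may be fine-grained (VBZ, NNS, ...)
pos_matches <- function(entry_pos, token_pos) {
  if (is.na(entry_pos) || !nzchar(entry_pos)) return(TRUE)
  if (is.na(token_pos) || !nzchar(token_pos)) return(TRUE)
  entry_pos == token_pos || startsWith(token_pos, entry_pos)
}

# affix-based polarity for atomic triggers: applied only when the stripped
# lemma is itself in the lexicon
AFFIX_POLARITY <- c(non = "negative", un = "negative", "in" = "negative",
                    up = "positive", down = "negative")

lookup_entry <- function(lexicon, lemma, pos) {
  hit <- lexicon$lemma == lemma &
    vapply(lexicon$pos, pos_matches, logical(1), token_pos = pos)
  if (any(hit)) return(cbind(lexicon[which(hit)[1], , drop = FALSE],
                             affix_polarity = NA_character_))
  # affix stripping
  for (p in names(AFFIX_POLARITY)) {
    for (pref in c(paste0(p, "-"), p)) {
      if (startsWith(lemma, pref) && nchar(lemma) > nchar(pref) + 2) {
        base <- substring(lemma, nchar(pref) + 1)
        hit <- lexicon$lemma == base &
          vapply(lexicon$pos, pos_matches, logical(1), token_pos = pos)
        if (any(hit)) {
          e <- lexicon[which(hit)[1], , drop = FALSE]
          return(cbind(e, affix_polarity = AFFIX_POLARITY[[p]]))
        }
      }
    }
  }
  NULL
}

#' Match trigger mentions in a tokenized sentence
#'
#' Tokens must carry `lemma` and `pos`. Multi-word triggers are matched
#' greedily, longest first, left to right; matched spans never overlap.
#' Affixed forms (`nonexpression`, `upregulation`) match the base entry with
#' the affix polarity overriding the dictionary polarity.
#'
#' @param tokens data.frame with columns `idx`, `form`, `lemma`, `pos`,
#'   `start`, `end`.
#' @param lexicon a `trigger_lexicon`.
#' @return data.frame of predicate mentions: one row per match with the
#'   matched entry features and token span (`first_idx`, `last_idx`,
#'   `start`, `end`, `text`).
#' @export
match_triggers <- function(tokens, lexicon) {
  out <- list()
  n <- nrow(tokens)
  max_len <- if (nrow(lexicon)) max(lexicon$n_words) else 1
  i <- 1
  while (i <= n) {
    matched <- NULL
    for (len in seq(min(max_len, n - i + 1), 1)) {
      lem <- paste(tolower(tokens$lemma[i:(i + len - 1)]), collapse = " ")
      e <- lookup_entry(lexicon, lem, tokens$pos[i + len - 1])
      if (is.null(e) && len > 1) next
      if (is.null(e)) break
      pol <- if (!is.na(e$affix_polarity)) e$affix_polarity else e$polarity
      matched <- data.frame(
        lemma = e$lemma, pos = e$pos, sem_type = e$sem_type,
        polarity = pol, strength = e$strength,
        negative_raising = e$negative_raising,
        first_idx = tokens$idx[i], last_idx = tokens$idx[i + len - 1],
        start = tokens$start[i], end = tokens$end[i + len - 1],
        text = substr_span(tokens, i, i + len - 1),
        stringsAsFactors = FALSE)
      i <- i + len
      break
    }
    if (is.null(matched)) i <- i + 1 else out[[length(out) + 1]] <- matched
  }
  if (!length(out)) {
    return(data.frame(lemma = character(0), pos = character(0),
                      sem_type = character(0), polarity = character(0),
                      strength = numeric(0), negative_raising = logical(0),
                      first_idx = integer(0), last_idx = integer(0),
                      start = integer(0), end = integer(0),
                      text = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

substr_span <- function(tokens, i, j) {
  paste(tokens$form[i:j], collapse = " ")
}

#' Assign atomic event types by maximum likelihood
#'
#' Given a count table of (lemma, pos, event_type, count) observations, the
#' event type with the maximum count is assigned to each (lemma, pos)
#' trigger. Ties break to the lexicographically smallest type name;
#' triggers whose counts are all zero are excluded.
#'
#' @param counts data.frame with columns `lemma`, `pos`, `event_type`,
#'   `count`, or path to a 4-column TSV.
#' @return data.frame with columns `lemma`, `pos`, `sem_type`.
#' @export
assign_types_mle <- function(counts) {
  if (is.character(counts)) {
    counts <- utils::read.table(counts, sep = "\t", header = FALSE,
                                col.names = c("lemma", "pos", "event_type",
                                              "count"),
                                stringsAsFactors = FALSE, comment.char = "#")
  }
  stopifnot(all(counts$count >= 0))
  key <- paste(tolower(counts$lemma), counts$pos, sep = "\r")
  out <- lapply(split(counts, key), function(g) {
    tot <- tapply(g$count, g$event_type, sum)
    tot <- tot[tot > 0]
    if (!length(tot)) return(NULL)
    best <- sort(names(tot)[tot == max(tot)])[1]
    data.frame(lemma = tolower(g$lemma[1]), pos = g$pos[1],
               sem_type = toupper(best), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    return(data.frame(lemma = character(0), pos = character(0),
                      sem_type = character(0), stringsAsFactors = FALSE))
  out <- out[order(out$lemma, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}
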