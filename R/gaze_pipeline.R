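#' Read a fixation log
#'
#' TSV with header columns `participant_id`, `trial_id`, `seq_index`,
#' `line_id`, `char_pos`, `duration`, `blink`. One row per fixation event;
#' `char_pos` is the horizontal landing position in character units local to
#' the display line, `duration` in ms, `blink` 0/1.
#'
#' @param path path to the TSV file.
#' @return data frame of fixations, ordered by participant, trial and
#'   `seq_index`.
#' @export
load_fixations <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          fileEncoding = "UTF-8",
                          colClasses = c(participant_id = "character"))
  needed <- c("participant_id", "trial_id", "seq_index", "line_id",
              "char_pos", "duration", "blink")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("fixation log is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(df$duration <= 0)) {
    stop("non-positive fixation duration at row ",
         which(df$duration <= 0)[1L], call. = FALSE)
  }
  df$blink <- as.logical(df$blink)
  df <- df[order(df$participant_id, df$trial_id, df$seq_index), , drop = FALSE]
  rownames(df) <- NULL
  key <- paste(df$participant_id, df$trial_id)
  for (g in split(seq_len(nrow(df)), key)) {
    s <- df$seq_index[g]
    if (any(diff(s) <= 0)) {
      stop("seq_index not strictly increasing within trial ",
           df$trial_id[g[1L]], " of participant ", df$participant_id[g[1L]],
           call. = FALSE)
    }
  }
  df
}

#' Write a fixation log
#' @param fixations fixation data frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_fixations <- function(fixations, path) {
  out <- fixations
  out$blink <- as.integer(out$blink)
  cols <- c("participant_id", "trial_id", "seq_index", "line_id",
            "char_pos", "duration", "blink")
  utils::write.table(out[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# Map line-local positions to tokens.
# Returns token_id (NA if not mapped) and a status: "mapped", "boundary"
# (landing exactly on a span edge) or "offtext".
.map_positions <- function(line_id, char_pos, text) {
  toks <- text$tokens
  line_start <- tapply(toks$char_start, toks$line_id, min)
  n <- length(line_id)
  token_id <- rep(NA_integer_, n)
  status <- rep("offtext", n)
  for (i in seq_len(n)) {
    ls_key <- as.character(line_id[i])
    if (!ls_key %in% names(line_start)) next
    doc_pos <- line_start[[ls_key]] + char_pos[i]
    on_line <- toks$line_id == line_id[i]
    if (any(doc_pos == toks$char_start[on_line] |
            doc_pos == toks$char_end[on_line])) {
      status[i] <- "boundary"
      next
    }
    hit <- which(on_line & toks$char_start < doc_pos & doc_pos < toks$char_end)
    if (length(hit) == 1L) {
      token_id[i] <- toks$token_id[hit]
      status[i] <- "mapped"
    }
  }
  list(token_id = token_id, status = status)
}

#' Map one fixation to its word region
#'
#' Assigns a fixation to the token on the same display line whose character
#' span strictly contains the landing position (line-local character units).
#' A landing exactly on a span boundary, or outside the line's text, is
#' unmapped and returns `NA` (boundary saccades are excluded from analysis,
#' not assigned to either neighbour).
#'
#' @param fix a one-row fixation data frame (or list) with `line_id` and
#'   `char_pos`.
#' @param text a `text_structure`.
#' @return the `token_id`, or `NA` if unmapped.
#' @export
map_fixation_to_token <- function(fix, text) {
  .map_positions(fix$line_id[1L], fix$char_pos[1L], text)$token_id[1L]
}

.exclusion_reasons <- c("blink", "trial_first_last", "line_switch",
                        "duration_low", "duration_high",
                        "line_first_last_word", "boundary_saccade", "unmapped")

#' Filter a fixation stream for analysis
#'
#' Applies the standard reading-research exclusions, in a fixed precedence
#' order per fixation (each excluded fixation is counted under the first rule
#' it violates): blink; first/last fixation of the trial; line-switch
#' fixation (line differs from the previous fixation's line); duration below
#' `min_dur` or above `max_dur` (bounds themselves are retained); fixation on
#' the first or last word of its display line; landing exactly on a word
#' boundary; unmapped (off-text) landing.
#'
#' The retained output carries the mapped `token_id` plus provenance columns
#' (`.prev_line_id`, `.trial_edge`) recording the original stream context, so
#' that re-filtering already-filtered output is a no-op.
#'
#' @param fixations fixation data frame as from [load_fixations()].
#' @param text a `text_structure`.
#' @param min_dur,max_dur inclusive duration bounds in ms (default 80/800).
#' @return A list with `retained` (data frame with `token_id`) and `report`
#'   (a `filter_report`: `n_input`, `n_retained` and per-reason exclusion
#'   counts partitioning the input).
#' @export
filter_fixations <- function(fixations, text, min_dur = 80, max_dur = 800) {
  n <- nrow(fixations)
  if (n == 0L) {
    warning("empty fixation stream")
    report <- filter_report(0L, stats::setNames(integer(length(.exclusion_reasons)),
                                               .exclusion_reasons))
    return(list(retained = fixations, report = report))
  }
  fx <- fixations
  key <- paste(fx$participant_id, fx$trial_id)

  if (is.null(fx$.prev_line_id)) {
    fx$.prev_line_id <- NA_integer_
    for (g in split(seq_len(n), key)) {
      if (length(g) > 1L) fx$.prev_line_id[g[-1L]] <- fx$line_id[g[-length(g)]]
    }
  }
  if (is.null(fx$.trial_edge)) {
    fx$.trial_edge <- FALSE
    for (g in split(seq_len(n), key)) {
      fx$.trial_edge[c(g[1L], g[length(g)])] <- TRUE
    }
  }

  mp <- .map_positions(fx$line_id, fx$char_pos, text)
  toks <- text$tokens
  line_first <- tapply(toks$token_id, toks$line_id, min)
  line_last <- tapply(toks$token_id, toks$line_id, max)
  edge_token <- !is.na(mp$token_id) &
    (mp$token_id %in% line_first | mp$token_id %in% line_last)

  reason <- rep(NA_character_, n)
  pick <- function(cond, r) {
    sel <- cond & is.na(reason)
    reason[sel] <<- r
  }
  pick(fx$blink, "blink")
  pick(fx$.trial_edge, "trial_first_last")
  pick(!is.na(fx$.prev_line_id) & fx$line_id != fx$.prev_line_id, "line_switch")
  pick(fx$duration < min_dur, "duration_low")
  pick(fx$duration > max_dur, "duration_high")
  pick(edge_token, "line_first_last_word")
  pick(mp$status == "boundary", "boundary_saccade")
  pick(mp$status == "offtext", "unmapped")

  keep <- is.na(reason)
  counts <- vapply(.exclusion_reasons,
                   function(r) sum(reason == r, na.rm = TRUE), 0L)
  retained <- fx[keep, , drop = FALSE]
  retained$token_id <- mp$token_id[keep]
  retained$.trial_edge <- FALSE
  rownames(retained) <- NULL
  if (nrow(retained) == 0L) warning("no fixations retained")
  list(retained = retained, report = filter_report(n, counts))
}

filter_report <- function(n_input, exclusions) {
  structure(
    list(n_input = as.integer(n_input),
         n_retained = as.integer(n_input - sum(exclusions)),
         exclusions = exclusions),
    class = "filter_report"
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report> ", x$n_input, " fixations in, ", x$n_retained,
      " retained\n", sep = "")
  ex <- x$exclusions[x$exclusions > 0]
  if (length(ex)) {
    for (r in names(ex)) cat("  ", r, ": ", ex[[r]], "\n", sep = "")
  }
  invisible(x)
}

#' Map retained fixations without filtering
#'
#' Attaches `token_id` to every fixation of a (typically clean, synthetic)
#' stream. Fixations that do not map strictly inside a word are an error here;
#' use [filter_fixations()] for real data.
#'
#' @param fixations fixation data frame.
#' @param text a `text_structure`.
#' @return the data frame with a `token_id` column.
#' @export
map_fixations <- function(fixations, text) {
  mp <- .map_positions(fixations$line_id, fixations$char_pos, text)
  if (any(mp$status != "mapped")) {
    stop(sum(mp$status != "mapped"),
         " fixation(s) do not map inside a word; run filter_fixations first",
         call. = FALSE)
  }
  fixations$token_id <- mp$token_id
  fixations
}

#' Decompose per-word viewing time into FFD, RFD and RRD
#'
#' For each (participant, trial, word): the *first pass* is the maximal run
#' of consecutive fixations on the word that starts with its first arrival
#' from an earlier word via a forward saccade (the trial-initial fixation
#' counts as a forward arrival). FFD is the duration of the first fixation of
#' that run; RFD the summed durations of the run's remaining fixations; RRD
#' the summed durations of every other fixation on the word (re-visits after
#' the eyes first left it). A word first entered by a regressive (backward)
#' saccade has FFD = RFD = 0 and all of its time in RRD. GD = FFD + RFD and
#' total = FFD + RFD + RRD hold exactly by construction.
#'
#' @param retained fixation data frame with a `token_id` column (from
#'   [filter_fixations()] or [map_fixations()]).
#' @param text a `text_structure`; needed to emit skipped words.
#' @param emit_skipped if `TRUE` (default), words of the trial's paragraph
#'   that received no retained fixation are emitted with zero durations and
#'   `skipped = TRUE` (assumes the trial-per-paragraph convention
#'   `trial_id == paragraph_id`; skipped rows are omitted for trial ids with
#'   no matching paragraph).
#' @return data frame with columns `participant_id`, `trial_id`, `token_id`,
#'   `FFD`, `RFD`, `RRD`, `GD`, `total`, `skipped`.
#' @export
decompose_viewing_times <- function(retained, text, emit_skipped = TRUE) {
  if (is.null(retained$token_id) || anyNA(retained$token_id)) {
    stop("fixations must be mapped to tokens; run filter_fixations first",
         call. = FALSE)
  }
  key <- paste(retained$participant_id, retained$trial_id, sep = "\r")
  groups <- split(seq_len(nrow(retained)), key)
  out <- vector("list", length(groups))
  gi <- 0L
  for (g in groups) {
    gi <- gi + 1L
    tok <- retained$token_id[g]
    dur <- retained$duration[g]
    runs <- rle(tok)
    run_tok <- runs$values
    run_end <- cumsum(runs$lengths)
    run_start <- run_end - runs$lengths + 1L
    first_run <- !duplicated(run_tok)
    forward <- c(TRUE, run_tok[-1L] > run_tok[-length(run_tok)])

    ids <- sort(unique(tok))
    ffd <- rfd <- rrd <- stats::setNames(numeric(length(ids)), ids)
    for (r in seq_along(run_tok)) {
      t_key <- as.character(run_tok[r])
      d <- dur[run_start[r]:run_end[r]]
      if (first_run[r] && forward[r]) {
        ffd[t_key] <- d[1L]
        rfd[t_key] <- rfd[t_key] + sum(d[-1L])
      } else {
        rrd[t_key] <- rrd[t_key] + sum(d)
      }
    }
    out[[gi]] <- data.frame(
      participant_id = retained$participant_id[g[1L]],
      trial_id = retained$trial_id[g[1L]],
      token_id = ids,
      FFD = unname(ffd), RFD = unname(rfd), RRD = unname(rrd)
    )
  }
  res <- do.call(rbind, out)
  res$GD <- res$FFD + res$RFD
  res$total <- res$FFD + res$RFD + res$RRD
  res$skipped <- FALSE

  if (emit_skipped) {
    seen <- unique(res[, c("participant_id", "trial_id")])
    skip_rows <- vector("list", nrow(seen))
    for (i in seq_len(nrow(seen))) {
      trial <- seen$trial_id[i]
      para_toks <- text$tokens$token_id[text$tokens$paragraph_id == trial]
      if (!length(para_toks)) next
      fixated <- res$token_id[res$participant_id == seen$participant_id[i] &
                              res$trial_id == trial]
      miss <- setdiff(para_toks, fixated)
      if (!length(miss)) next
      skip_rows[[i]] <- data.frame(
        participant_id = seen$participant_id[i], trial_id = trial,
        token_id = miss, FFD = 0, RFD = 0, RRD = 0, GD = 0, total = 0,
        skipped = TRUE
      )
    }
    skip_rows <- skip_rows[!vapply(skip_rows, is.null, TRUE)]
    if (length(skip_rows)) res <- rbind(res, do.call(rbind, skip_rows))
  }
  res <- res[order(res$participant_id, res$trial_id, res$token_id), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write per-word viewing-time measures
#' @param measures data frame from [decompose_viewing_times()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_word_measures <- function(measures, path) {
  out <- measures
  out$skipped <- as.integer(out$skipped)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
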