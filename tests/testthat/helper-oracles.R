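# Independent brute-force oracles. These deliberately avoid the package's
# data structures: n-grams are recounted by scanning the raw stream, and
# viewing-time components are derived by replaying the scanpath event by
# event with an explicit per-word state machine.

# Count occurrences of the exact token sequence `gram` in `stream` by
# rebuilding every length-k window of the raw stream.
oracle_count <- function(stream, gram) {
  k <- length(gram)
  n <- length(stream)
  if (n < k) return(0L)
  m <- n - k + 1L
  win <- stream[seq_len(m)]
  if (k > 1L) {
    for (j in 2:k) win <- paste(win, stream[seq(j, j + m - 1L)])
  }
  sum(win == paste(gram, collapse = " "))
}

# Surprisal of `target` after `context`, recounted from the raw stream.
# Same stated rule as the implementation (back off whenever the higher-order
# estimate is zero or undefined; add-one floor for unseen unigrams), but
# computed from scratch.
oracle_surprisal <- function(stream, context, target) {
  V <- length(unique(stream))
  N <- length(stream)
  if (length(context) > 2L) context <- utils::tail(context, 2L)
  for (k in rev(seq_len(length(context)))) {
    ctx <- utils::tail(context, k)
    joint <- oracle_count(stream, c(ctx, target))
    denom <- oracle_count(stream, ctx)
    if (denom > 0L && joint > 0L) return(-log(joint / denom))
  }
  cnt <- oracle_count(stream, target)
  if (cnt > 0L) -log(cnt / N) else -log(1 / (N + V + 1))
}

# Per-token surprisal for a document whose token stream is also the counting
# corpus; contexts never cross sentence boundaries.
oracle_annotate <- function(text, stream) {
  toks <- text$tokens
  vapply(seq_len(nrow(toks)), function(i) {
    sid <- toks$sentence_id[i]
    ctx <- character(0)
    if (i >= 2L && toks$sentence_id[i - 1L] == sid) ctx <- toks$surface[i - 1L]
    if (i >= 3L && toks$sentence_id[i - 2L] == sid) {
      ctx <- toks$surface[c(i - 2L, i - 1L)]
    }
    oracle_surprisal(stream, ctx, toks$surface[i])
  }, 0)
}

# Event-replay decomposition: one trial's fixations (token_id, duration, in
# order). Walks the scanpath keeping per-word state: whether the word has
# been visited, whether the eyes have left it since its first-pass run, and
# whether its first arrival was a forward saccade.
oracle_decompose_trial <- function(token_id, duration) {
  ffd <- rfd <- rrd <- list()
  visited <- character(0)
  in_first_pass <- character(0)   # words whose first-pass run is still open
  add <- function(store, tok, d) {
    key <- as.character(tok)
    store[[key]] <- (if (is.null(store[[key]])) 0 else store[[key]]) + d
    store
  }
  prev <- NA_integer_
  for (e in seq_along(token_id)) {
    tok <- token_id[e]
    d <- duration[e]
    key <- as.character(tok)
    if (!is.na(prev) && prev != tok) {
      # eyes left the previous word: its first-pass run (if open) is closed
      in_first_pass <- setdiff(in_first_pass, as.character(prev))
    }
    if (!key %in% visited) {
      visited <- c(visited, key)
      forward <- is.na(prev) || prev < tok
      if (forward) {
        ffd <- add(ffd, tok, d)
        in_first_pass <- c(in_first_pass, key)
      } else {
        rrd <- add(rrd, tok, d)
      }
    } else if (tok == prev && key %in% in_first_pass) {
      rfd <- add(rfd, tok, d)
    } else {
      rrd <- add(rrd, tok, d)
    }
    prev <- tok
  }
  ids <- sort(as.integer(visited))
  get0 <- function(store, id) {
    v <- store[[as.character(id)]]
    if (is.null(v)) 0 else v
  }
  data.frame(token_id = ids,
             FFD = vapply(ids, function(i) get0(ffd, i), 0),
             RFD = vapply(ids, function(i) get0(rfd, i), 0),
             RRD = vapply(ids, function(i) get0(rrd, i), 0))
}

# Replay a whole mapped fixation log (participant_id, trial_id, token_id,
# duration).
oracle_decompose <- function(mapped) {
  key <- paste(mapped$participant_id, mapped$trial_id, sep = "\r")
  out <- lapply(split(seq_len(nrow(mapped)), key), function(g) {
    res <- oracle_decompose_trial(mapped$token_id[g], mapped$duration[g])
    res$participant_id <- mapped$participant_id[g[1L]]
    res$trial_id <- mapped$trial_id[g[1L]]
    res
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
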