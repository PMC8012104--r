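#' Tokenized hierarchical text
#'
#' A `text_structure` holds a document as an ordered token table nested in
#' sentences, paragraphs and display lines. Character spans are 0-based,
#' half-open intervals `[char_start, char_end)` over the concatenated document
#' (no whitespace between tokens, as in Chinese running text).
#'
#' @param tokens data frame with columns `surface`, `char_start`, `char_end`,
#'   `sentence_id`, `paragraph_id`, `line_id`. Ids are 0-based integers.
#' @return An object of class `text_structure`: a list with elements
#'   `tokens` (the validated token table, with `token_id` added),
#'   `sentence_index` (one row per sentence: token range and paragraph) and
#'   `paragraph_index` (one row per paragraph: sentence range).
#' @export
text_structure <- function(tokens) {
  if (!is.data.frame(tokens) || nrow(tokens) == 0L) {
    stop("no tokens", call. = FALSE)
  }
  needed <- c("surface", "char_start", "char_end",
              "sentence_id", "paragraph_id", "line_id")
  missing_cols <- setdiff(needed, names(tokens))
  if (length(missing_cols)) {
    stop("text table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tokens <- as.data.frame(tokens)[, needed]
  tokens$char_start <- as.integer(tokens$char_start)
  tokens$char_end <- as.integer(tokens$char_end)
  for (id in c("sentence_id", "paragraph_id", "line_id")) {
    tokens[[id]] <- as.integer(tokens[[id]])
  }
  tokens$token_id <- seq_len(nrow(tokens)) - 1L

  if (any(bad <- tokens$char_end <= tokens$char_start)) {
    stop("empty or inverted spans at token_id ",
         paste(tokens$token_id[bad], collapse = ", "), call. = FALSE)
  }
  if (nrow(tokens) > 1L) {
    overlap <- tokens$char_start[-1L] < tokens$char_end[-nrow(tokens)]
    if (any(overlap)) {
      ids <- tokens$token_id[c(which(overlap), which(overlap) + 1L)]
      stop("overlapping spans at token_id ",
           paste(sort(unique(ids)), collapse = ", "), call. = FALSE)
    }
    if (any(diff(tokens$sentence_id) < 0L)) {
      stop("sentence_id must be non-decreasing in token order", call. = FALSE)
    }
    if (any(diff(tokens$sentence_id) > 1L)) {
      stop("non-contiguous sentence ids", call. = FALSE)
    }
    if (any(diff(tokens$paragraph_id) < 0L) ||
        any(diff(tokens$paragraph_id) > 1L)) {
      stop("non-contiguous paragraph ids", call. = FALSE)
    }
  }
  if (tokens$sentence_id[1L] != 0L || tokens$paragraph_id[1L] != 0L) {
    stop("sentence and paragraph ids must start at 0", call. = FALSE)
  }
  # a sentence must not straddle paragraphs
  para_of_sent <- tapply(tokens$paragraph_id, tokens$sentence_id,
                         function(p) length(unique(p)))
  if (any(para_of_sent > 1L)) {
    stop("sentence spans more than one paragraph", call. = FALSE)
  }

  sent_first <- tapply(tokens$token_id, tokens$sentence_id, min)
  sent_last <- tapply(tokens$token_id, tokens$sentence_id, max)
  sent_para <- tapply(tokens$paragraph_id, tokens$sentence_id, function(p) p[1L])
  sentence_index <- data.frame(
    sentence_id = as.integer(names(sent_first)),
    first_token = as.integer(sent_first),
    last_token = as.integer(sent_last),
    paragraph_id = as.integer(sent_para)
  )
  para_first <- tapply(sentence_index$sentence_id, sentence_index$paragraph_id, min)
  para_last <- tapply(sentence_index$sentence_id, sentence_index$paragraph_id, max)
  paragraph_index <- data.frame(
    paragraph_id = as.integer(names(para_first)),
    first_sentence = as.integer(para_first),
    last_sentence = as.integer(para_last)
  )
  structure(
    list(tokens = tokens,
         sentence_index = sentence_index,
         paragraph_index = paragraph_index),
    class = "text_structure"
  )
}

#' Read a tokenized text table
#'
#' Reads a UTF-8 TSV with header columns `surface`, `char_start`, `char_end`,
#' `sentence_id`, `paragraph_id`, `line_id` and validates it into a
#' [text_structure()].
#'
#' @param path path to the TSV file.
#' @return A `text_structure`.
#' @export
load_text_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = c(surface = "character"),
                          quote = "", fileEncoding = "UTF-8")
  if (nrow(df) == 0L) stop("no tokens", call. = FALSE)
  text_structure(df)
}

#' Write a text table
#' @param text a `text_structure`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_text_table <- function(text, path) {
  cols <- c("surface", "char_start", "char_end",
            "sentence_id", "paragraph_id", "line_id")
  utils::write.table(text$tokens[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.text_structure <- function(x, ...) {
  cat("<text_structure> ", nrow(x$tokens), " tokens, ",
      nrow(x$sentence_index), " sentences, ",
      nrow(x$paragraph_index), " paragraphs, ",
      length(unique(x$tokens$line_id)), " lines\n", sep = "")
  invisible(x)
}

## ---------------------------------------------------------------------------
## N-gram tables

.ngram_key <- function(tokens) paste(tokens, collapse = " ")

#' Build an n-gram count table from named counts
#'
#' @param counts named numeric vector; names are space-separated n-grams
#'   (orders 1 to `max_order`), values are non-negative counts.
#' @param max_order highest n-gram order kept (1-3).
#' @return An object of class `ngram_table` with per-order count environments,
#'   `total_unigrams` (sum of order-1 counts) and `vocab_size`.
#' @export
ngram_table <- function(counts, max_order = 3L) {
  max_order <- as.integer(max_order)
  stopifnot(max_order >= 1L, max_order <= 3L)
  if (is.null(names(counts)) && length(counts)) {
    stop("counts must be named by space-separated n-grams", call. = FALSE)
  }
  if (any(counts < 0)) stop("negative n-gram count", call. = FALSE)
  envs <- lapply(seq_len(max_order), function(i) new.env(hash = TRUE, parent = emptyenv()))
  orders <- lengths(strsplit(names(counts), " ", fixed = TRUE))
  keep <- orders <= max_order
  for (i in which(keep)) {
    env <- envs[[orders[i]]]
    key <- names(counts)[i]
    env[[key]] <- (if (is.null(env[[key]])) 0 else env[[key]]) + counts[[i]]
  }
  total <- sum(unlist(as.list(envs[[1L]])), 0)
  if (total <= 0) stop("total unigram count must be positive", call. = FALSE)
  structure(
    list(order = max_order, counts = envs,
         total_unigrams = total,
         vocab_size = length(ls(envs[[1L]]))),
    class = "ngram_table"
  )
}

#' Read a Google-style n-gram count file
#'
#' One record per line: space-separated tokens, a TAB, then a non-negative
#' integer count. Records of order above `max_order` are skipped (with a
#' message).
#'
#' @param path path to the UTF-8 count file.
#' @param max_order highest order retained (default 3).
#' @return An `ngram_table`.
#' @export
load_ngram_table <- function(path, max_order = 3L) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty n-gram file", call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    stop("malformed n-gram record at line ", bad[1L], call. = FALSE)
  }
  grams <- vapply(parts, `[[`, "", 1L)
  count_str <- vapply(parts, `[[`, "", 2L)
  counts <- suppressWarnings(as.numeric(count_str))
  if (anyNA(counts)) {
    stop("non-numeric count at line ", which(is.na(counts))[1L], call. = FALSE)
  }
  if (any(counts < 0)) {
    stop("negative count at line ", which(counts < 0)[1L], call. = FALSE)
  }
  orders <- lengths(strsplit(grams, " ", fixed = TRUE))
  if (any(orders > max_order)) {
    message(sum(orders > max_order), " record(s) above order ", max_order,
            " skipped")
  }
  keep <- orders <= max_order
  ngram_table(stats::setNames(counts[keep], grams[keep]), max_order = max_order)
}

#' Write an n-gram table to the count-file format
#' @param table an `ngram_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ngram_table <- function(table, path) {
  out <- character(0)
  for (k in seq_len(table$order)) {
    env <- table$counts[[k]]
    keys <- sort(ls(env))
    if (length(keys)) {
      vals <- vapply(keys, function(k2) env[[k2]], 0)
      out <- c(out, paste0(keys, "\t", format(vals, scientific = FALSE, trim = TRUE)))
    }
  }
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.ngram_table <- function(x, ...) {
  n_per <- vapply(x$counts, function(e) length(ls(e)), 0L)
  cat("<ngram_table> max order ", x$order,
      "; types per order: ", paste(n_per, collapse = "/"),
      "; total unigram tokens: ", x$total_unigrams, "\n", sep = "")
  invisible(x)
}

ngram_count <- function(table, tokens) {
  k <- length(tokens)
  if (k < 1L || k > table$order) return(0)
  v <- table$counts[[k]][[.ngram_key(tokens)]]
  if (is.null(v)) 0 else v
}

#' Log relative word frequency
#'
#' Returns `ln(count(w) / total_unigrams)` for words present in the table.
#' Unseen words receive the add-one floor `ln(1 / (total_unigrams +
#' vocab_size + 1))`, which is strictly below every seen word's value, so the
#' measure is strictly increasing in count.
#'
#' @param table an `ngram_table`.
#' @param surface character vector of word surfaces.
#' @return numeric vector of log relative frequencies (natural log).
#' @export
word_frequency <- function(table, surface) {
  if (any(!nzchar(surface))) stop("empty surface", call. = FALSE)
  total <- table$total_unigrams
  floor_p <- 1 / (total + table$vocab_size + 1)
  vapply(surface, function(w) {
    cnt <- ngram_count(table, w)
    if (cnt > 0) log(cnt / total) else log(floor_p)
  }, 0, USE.NAMES = FALSE)
}

#' N-gram surprisal with backoff
#'
#' Computes `-ln P(target | context)` where the conditional probability is the
#' ratio of the joint n-gram count to the context count at the highest usable
#' order. Contexts are limited to the previous two words (trigram model). The
#' estimate backs off trigram -> bigram -> unigram whenever the joint or the
#' context count at the current order is zero, so the value is always finite;
#' at the unigram level an unseen target receives the same add-one floor as
#' [word_frequency()].
#'
#' @param table an `ngram_table`.
#' @param context character vector of 0-2 preceding surfaces (earlier word
#'   first).
#' @param target the word surface to score.
#' @return A list with `value` (surprisal in nats, >= 0) and `order_used`
#'   (1-3, the n-gram order that supplied the estimate).
#' @export
surprisal <- function(table, context, target) {
  if (length(target) != 1L || !nzchar(target)) {
    stop("target must be a single non-empty surface", call. = FALSE)
  }
  if (length(context) > 2L) context <- utils::tail(context, 2L)
  if (table$total_unigrams <= 0) stop("n-gram table has no unigram mass", call. = FALSE)
  k_max <- min(length(context) + 1L, table$order)
  if (k_max >= 2L) {
    for (k in seq(k_max, 2L)) {
      ctx <- utils::tail(context, k - 1L)
      ctx_count <- ngram_count(table, ctx)
      joint <- ngram_count(table, c(ctx, target))
      if (ctx_count > 0 && joint > 0) {
        return(list(value = max(0, -log(joint / ctx_count)), order_used = k))
      }
    }
  }
  cnt <- ngram_count(table, target)
  p <- if (cnt > 0) cnt / table$total_unigrams
       else 1 / (table$total_unigrams + table$vocab_size + 1)
  list(value = max(0, -log(p)), order_used = 1L)
}

#' Per-token surprisal over a document
#'
#' Applies [surprisal()] to every token using up to the two preceding tokens
#' of the *same sentence* as context (contexts never cross sentence
#' boundaries; sentence-initial words are scored from shorter or empty
#' context).
#'
#' @param text a `text_structure`.
#' @param table an `ngram_table`.
#' @return data frame with `token_id`, `surprisal` (nats) and `order_used`.
#' @export
annotate_surprisal <- function(text, table) {
  toks <- text$tokens
  n <- nrow(toks)
  value <- numeric(n)
  order_used <- integer(n)
  for (i in seq_len(n)) {
    sid <- toks$sentence_id[i]
    ctx <- character(0)
    if (i >= 2L && toks$sentence_id[i - 1L] == sid) {
      if (i >= 3L && toks$sentence_id[i - 2L] == sid) {
        ctx <- toks$surface[c(i - 2L, i - 1L)]
      } else {
        ctx <- toks$surface[i - 1L]
      }
    }
    s <- surprisal(table, ctx, toks$surface[i])
    value[i] <- s$value
    order_used[i] <- s$order_used
  }
  data.frame(token_id = toks$token_id, surprisal = value,
             order_used = order_used)
}
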