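#' Cosine similarity of two vectors
#'
#' `dot(x, y) / (|x| |y|)`, clamped to `[-1, 1]` against floating-point
#' round-off.
#'
#' @param x,y numeric vectors of equal length, neither all-zero.
#' @return a single number in `[-1, 1]`.
#' @export
cosine_similarity <- function(x, y) {
  if (length(x) != length(y)) stop("dimension mismatch", call. = FALSE)
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop("zero vector", call. = FALSE)
  min(1, max(-1, sum(x * y) / (nx * ny)))
}

#' Embedding sets
#'
#' An `embedding_set` maps text-unit keys to fixed-dimension real vectors.
#' Keys encode the unit level and id: `word:<token_id>`, `sent:<sentence_id>`,
#' `para:<paragraph_id>`.
#'
#' @param vectors numeric matrix, one row per unit, rownames are unit keys.
#' @return An object of class `embedding_set` with elements `dimension` and
#'   `vectors`.
#' @export
embedding_set <- function(vectors) {
  if (!is.matrix(vectors) || is.null(rownames(vectors))) {
    stop("vectors must be a matrix with unit keys as rownames", call. = FALSE)
  }
  if (anyDuplicated(rownames(vectors))) {
    stop("duplicate key ", rownames(vectors)[duplicated(rownames(vectors))][1L],
         call. = FALSE)
  }
  if (any(rowSums(vectors != 0) == 0L)) {
    stop("all-zero embedding vector", call. = FALSE)
  }
  structure(list(dimension = ncol(vectors), vectors = vectors),
            class = "embedding_set")
}

#' @export
print.embedding_set <- function(x, ...) {
  cat("<embedding_set> ", nrow(x$vectors), " vectors of dimension ",
      x$dimension, "\n", sep = "")
  invisible(x)
}

#' Read embeddings from word2vec text format
#'
#' First line is `<n> <dim>`; each following line is a key and `dim`
#' whitespace-separated values.
#'
#' @param path path to the embedding file.
#' @param expected_dim required vector dimension; a mismatch is a format
#'   error.
#' @return An `embedding_set`.
#' @export
load_embeddings <- function(path, expected_dim) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) < 1L) stop("empty embedding file", call. = FALSE)
  header <- scan(text = lines[1L], what = integer(), n = 2L, quiet = TRUE)
  if (length(header) != 2L) stop("malformed header line", call. = FALSE)
  n <- header[1L]; dim <- header[2L]
  if (dim != expected_dim) {
    stop("dimension mismatch: file declares ", dim, ", expected ",
         expected_dim, call. = FALSE)
  }
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (length(body) != n) {
    stop("header declares ", n, " vectors but file has ", length(body),
         call. = FALSE)
  }
  parts <- strsplit(body, "[ \t]+")
  bad <- which(lengths(parts) != dim + 1L)
  if (length(bad)) {
    stop("wrong number of values at line ", bad[1L] + 1L, call. = FALSE)
  }
  keys <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(keys)) {
    stop("duplicate key ", keys[duplicated(keys)][1L], call. = FALSE)
  }
  mat <- t(vapply(parts, function(p) as.numeric(p[-1L]), numeric(dim)))
  if (anyNA(mat)) stop("non-numeric embedding value", call. = FALSE)
  rownames(mat) <- keys
  embedding_set(mat)
}

#' Write embeddings in word2vec text format
#' @param emb an `embedding_set`.
#' @param path output path.
#' @param digits significant digits written (default 8).
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(emb, path, digits = 8) {
  mat <- emb$vectors
  rows <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(rownames(mat)[i],
            formatC(mat[i, ], digits = digits, format = "g")), collapse = " ")
  }, "")
  writeLines(c(paste(nrow(mat), ncol(mat)), rows), path, useBytes = TRUE)
  invisible(path)
}

embedding_vector <- function(emb, level, id) {
  key <- paste0(level, ":", id)
  if (!key %in% rownames(emb$vectors)) {
    stop("missing embedding for unit ", key, call. = FALSE)
  }
  emb$vectors[key, ]
}

#' Multi-scale similarity features
#'
#' For every token, computes the four cosine-similarity measures used as
#' reading-time predictors:
#' \describe{
#'   \item{word_sent}{fixated word vs. its containing sentence;}
#'   \item{sent_sent}{containing sentence vs. the preceding sentence in
#'     document order (`NA` for the document-initial sentence);}
#'   \item{sent_para}{containing sentence vs. its containing paragraph;}
#'   \item{para_para}{containing paragraph vs. the preceding paragraph
#'     (`NA` for the first paragraph).}
#' }
#' Sentence- and paragraph-level values are constant across all tokens of a
#' sentence by construction. "Preceding sentence" follows document order and
#' crosses paragraph boundaries.
#'
#' @param text a `text_structure`.
#' @param emb an `embedding_set` covering every word, sentence and paragraph
#'   in `text`.
#' @return data frame with `token_id`, `word_sent`, `sent_sent`, `sent_para`,
#'   `para_para`.
#' @export
similarity_features <- function(text, emb) {
  si <- text$sentence_index
  n_sent <- nrow(si)
  sent_vec <- lapply(si$sentence_id, function(s) embedding_vector(emb, "sent", s))
  para_ids <- text$paragraph_index$paragraph_id
  para_vec <- lapply(para_ids, function(p) embedding_vector(emb, "para", p))
  names(para_vec) <- as.character(para_ids)

  sent_sent <- rep(NA_real_, n_sent)
  sent_para <- numeric(n_sent)
  para_para_by_sent <- rep(NA_real_, n_sent)
  para_para <- stats::setNames(rep(NA_real_, length(para_ids)),
                               as.character(para_ids))
  for (j in seq_along(para_ids)[-1]) {
    para_para[j] <- cosine_similarity(para_vec[[j]], para_vec[[j - 1L]])
  }
  for (s in seq_len(n_sent)) {
    pid <- as.character(si$paragraph_id[s])
    sent_para[s] <- cosine_similarity(sent_vec[[s]], para_vec[[pid]])
    if (s > 1L) sent_sent[s] <- cosine_similarity(sent_vec[[s]], sent_vec[[s - 1L]])
    para_para_by_sent[s] <- para_para[pid]
  }

  toks <- text$tokens
  srow <- match(toks$sentence_id, si$sentence_id)
  word_sent <- vapply(seq_len(nrow(toks)), function(i) {
    cosine_similarity(embedding_vector(emb, "word", toks$token_id[i]),
                      sent_vec[[srow[i]]])
  }, 0)
  data.frame(
    token_id = toks$token_id,
    word_sent = word_sent,
    sent_sent = sent_sent[srow],
    sent_para = sent_para[srow],
    para_para = para_para_by_sent[srow]
  )
}
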