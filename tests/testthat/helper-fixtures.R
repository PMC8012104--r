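# Small builders shared across test files.

# A minimal hand-laid-out text: tokens given as list(surface, len, sentence,
# paragraph, line); spans are assigned consecutively.
make_text <- function(spec) {
  char_at <- 0L
  rows <- lapply(spec, function(s) {
    r <- data.frame(surface = s[[1]], char_start = char_at,
                    char_end = char_at + s[[2]], sentence_id = s[[3]],
                    paragraph_id = s[[4]], line_id = s[[5]])
    char_at <<- char_at + s[[2]]
    r
  })
  text_structure(do.call(rbind, rows))
}

# Two display lines of four 2-character words each, one sentence/paragraph.
two_line_text <- function() {
  make_text(list(
    list("aa", 2L, 0L, 0L, 0L), list("bb", 2L, 0L, 0L, 0L),
    list("cc", 2L, 0L, 0L, 0L), list("dd", 2L, 0L, 0L, 0L),
    list("ee", 2L, 0L, 0L, 1L), list("ff", 2L, 0L, 0L, 1L),
    list("gg", 2L, 0L, 0L, 1L), list("hh", 2L, 0L, 0L, 1L)
  ))
}

# Build a fixation data frame from (line_id, char_pos, duration, blink) rows.
make_fixations <- function(rows, participant = "p1", trial = 0L) {
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(line_id = r[[1]], char_pos = r[[2]], duration = r[[3]],
               blink = if (length(r) > 3L) r[[4]] else FALSE)
  }))
  df$participant_id <- participant
  df$trial_id <- trial
  df$seq_index <- seq_len(nrow(df)) - 1L
  df[, c("participant_id", "trial_id", "seq_index", "line_id", "char_pos",
         "duration", "blink")]
}

# Small generator config for fast tests; any argument can be overridden.
small_config <- function(seed = 1L, ...) {
  args <- list(seed = seed,
               n_per_group = c(poor = 2L, average = 2L, good = 2L),
               grades = c(4L, 5L), n_paragraphs = 4L,
               sentences_per_paragraph = c(5L, 5L),
               words_per_sentence = 6L, vocab_size = 80L,
               embedding_dim = 16L)
  args <- utils::modifyList(args, list(...))
  do.call(generator_config, args)
}

covariate_names <- c("freq", "surprisal", "word_sent", "sent_sent",
                     "sent_para", "para_para")

# Standardized variables following a known mediation chain
# para_para -(b_pp_sp)-> sent_para -(b_sp_dv)-> dv, all other true paths 0.
# The generating equations are written out here, independent of the package.
chain_data <- function(n, b_pp_sp = 0.5, b_sp_dv = 0.4, seed = 1) {
  set.seed(seed)
  pp <- rnorm(n)
  sp <- b_pp_sp * pp + rnorm(n, sd = sqrt(1 - b_pp_sp^2))
  data.frame(
    para_para = pp, sent_para = sp,
    sent_sent = rnorm(n), word_sent = rnorm(n),
    freq = rnorm(n), surprisal = rnorm(n),
    dv = b_sp_dv * sp + rnorm(n, sd = sqrt(1 - b_sp_dv^2))
  )
}
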