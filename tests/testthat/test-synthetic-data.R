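test_that("generation is deterministic under seed and config", {
  cfg <- small_config(seed = 21)
  g1 <- generate_text(cfg)
  g2 <- generate_text(cfg)
  expect_identical(g1, g2)
  e1 <- generate_embeddings(g1$text, cfg)
  e2 <- generate_embeddings(g2$text, cfg)
  expect_identical(e1, e2)
  p <- generate_participants(cfg)
  f <- compute_token_features(g1$text, generate_ngram_counts(g1$stream), e1)
  s1 <- generate_scanpaths(g1$text, f, p, cfg)
  s2 <- generate_scanpaths(g1$text, f, p, cfg)
  expect_identical(s1, s2)

  g3 <- generate_text(small_config(seed = 22))
  expect_false(identical(g1$stream, g3$stream))
})

test_that("generated text respects the configured layout", {
  cfg <- small_config(seed = 1)
  gen <- generate_text(cfg)
  toks <- gen$text$tokens
  expect_equal(nrow(toks), 4L * 5L * 6L)
  expect_true(all(nchar(toks$surface) >= 1 & nchar(toks$surface) <= 5))
  expect_equal(toks$char_end - toks$char_start, nchar(toks$surface))
  # sentences per paragraph within the configured range
  sp <- table(gen$text$sentence_index$paragraph_id)
  expect_true(all(sp == 5))
  # wrapped lines never exceed the width
  width <- tapply(toks$char_end - toks$char_start, toks$line_id, sum)
  expect_true(all(width <= cfg$line_width))
})

test_that("a zero Zipf exponent yields a uniform unigram distribution", {
  cfg <- generator_config(seed = 2, vocab_size = 50L, zipf_exponent = 0,
                          n_paragraphs = 50L, sentences_per_paragraph = c(5L, 5L),
                          words_per_sentence = 8L, embedding_dim = 4L)
  gen <- generate_text(cfg)
  expect_gte(length(gen$stream), 2000)
  counts <- table(factor(gen$stream, levels = sort(unique(gen$stream))))
  p <- suppressWarnings(stats::chisq.test(counts)$p.value)
  expect_gt(p, 0.01)
})

test_that("one-word sentences leave every token without surprisal context", {
  cfg <- small_config(seed = 3, words_per_sentence = 1L)
  gen <- generate_text(cfg)
  ann <- annotate_surprisal(gen$text, generate_ngram_counts(gen$stream))
  expect_true(all(ann$order_used == 1L))
})

test_that("stream n-gram counts are exact and conserve mass", {
  tab <- generate_ngram_counts(c("a", "b", "a", "b"))
  expect_equal(tab$total_unigrams, 4)
  expect_equal(surprisal(tab, character(0), "a")$value, -log(2 / 4))
  expect_equal(surprisal(tab, "a", "b")$value, 0)       # count(a b)/count(a) = 2/2
  expect_equal(surprisal(tab, "b", "a")$value, log(2))  # 1/2

  set.seed(31)
  stream <- sample(letters[1:5], 200, replace = TRUE)
  tab2 <- generate_ngram_counts(stream)
  expect_equal(tab2$total_unigrams, length(stream))
})

test_that("embedding concentration controls parent-child similarity", {
  # exact copy limit: sentence vectors equal their paragraph vector
  cfg_inf <- small_config(seed = 6, conc_sent = Inf)
  gen <- generate_text(cfg_inf)
  feats <- similarity_features(gen$text,
                               generate_embeddings(gen$text, cfg_inf))
  expect_true(all(feats$sent_para == 1))

  # zero concentration: sentence directions unrelated to the paragraph
  cfg0 <- generator_config(seed = 7, vocab_size = 30L, n_paragraphs = 200L,
                           sentences_per_paragraph = c(5L, 5L),
                           words_per_sentence = 1L, embedding_dim = 128L,
                           conc_sent = 0, conc_word = Inf)
  gen0 <- generate_text(cfg0)
  f0 <- similarity_features(gen0$text, generate_embeddings(gen0$text, cfg0))
  sent_level <- f0$sent_para[!duplicated(gen0$text$tokens$sentence_id)]
  expect_gte(length(sent_level), 1000)
  expect_lt(abs(mean(sent_level)), 0.05)

  # persistent topics raise paragraph-paragraph similarity over fresh topics
  mean_pp <- function(shift) {
    cfg <- generator_config(seed = 8, vocab_size = 30L, n_paragraphs = 60L,
                            sentences_per_paragraph = c(5L, 5L),
                            words_per_sentence = 1L, embedding_dim = 32L,
                            conc_para = 8, topic_shift_rate = shift)
    g <- generate_text(cfg)
    f <- similarity_features(g$text, generate_embeddings(g$text, cfg))
    mean(f$para_para, na.rm = TRUE)
  }
  expect_gt(mean_pp(0), mean_pp(1))
})

test_that("degenerate scanpath settings produce the expected limits", {
  # no refixations, no regressions: RFD = RRD = 0 everywhere
  cfg <- small_config(seed = 10, p_refix = 0, p_regress = 0)
  gen <- generate_dataset(cfg, withr::local_tempdir())
  m <- decompose_viewing_times(
    map_fixations(gen$fixations[, 1:7], gen$text), gen$text)
  expect_true(all(m$RFD == 0))
  expect_true(all(m$RRD == 0))

  # no effects, no random variance, no noise: every duration is the intercept
  cfg2 <- small_config(seed = 11, p_skip = 0, p_refix = 0, p_regress = 0,
                       beta = c(intercept = 250, freq = 0, surprisal = 0,
                                word_sent = 0, sent_sent = 0, sent_para = 0,
                                para_para = 0, ability = 0),
                       sd_participant = 0, sd_word = 0, sd_resid = 0)
  gen2 <- generate_dataset(cfg2, withr::local_tempdir())
  expect_true(all(gen2$fixations$duration == 250))
})

test_that("the gaze pipeline recovers generated components exactly (round trip)", {
  cfg <- small_config(seed = 12)
  gen <- generate_dataset(cfg, withr::local_tempdir())
  m <- decompose_viewing_times(
    map_fixations(gen$fixations[, 1:7], gen$text), gen$text)
  tr <- gen$truth$components
  key <- function(d) paste(d$participant_id, d$trial_id, d$token_id)
  m2 <- m[match(key(tr), key(m)), ]
  expect_equal(m2$FFD, tr$FFD)
  expect_equal(m2$RFD, tr$RFD)
  expect_equal(m2$RRD, tr$RRD)
  expect_equal(m2$skipped, tr$skipped)
})

test_that("raising the surprisal effect raises durations on high-surprisal words", {
  mk <- function(b_surp, seed = 13) {
    cfg <- small_config(seed = seed, p_skip = 0, p_refix = 0, p_regress = 0,
                        beta = c(intercept = 250, freq = 0, surprisal = b_surp,
                                 word_sent = 0, sent_sent = 0, sent_para = 0,
                                 para_para = 0, ability = 0),
                        sd_participant = 0, sd_word = 0, sd_resid = 10)
    sim <- simulate_modelling_data(cfg)
    high <- sim$rows$surprisal > stats::median(sim$rows$surprisal)
    mean(sim$rows$dv[high])
  }
  expect_gt(mk(30), mk(0))
})

test_that("the generated dataset files reload consistently", {
  cfg <- small_config(seed = 14)
  dir <- withr::local_tempdir()
  gen <- generate_dataset(cfg, dir)
  expect_setequal(list.files(dir),
                  c("text.tsv", "ngrams.tsv", "embeddings.vec",
                    "participants.tsv", "fixations.tsv", "ground_truth.json"))
  text <- load_text_table(file.path(dir, "text.tsv"))
  expect_equal(text$tokens, gen$text$tokens)
  tab <- load_ngram_table(file.path(dir, "ngrams.tsv"))
  expect_equal(tab$total_unigrams, length(gen$stream))
  emb <- load_embeddings(file.path(dir, "embeddings.vec"), cfg$embedding_dim)
  expect_equal(nrow(emb$vectors), nrow(gen$embeddings$vectors))
  fx <- load_fixations(file.path(dir, "fixations.tsv"))
  expect_equal(nrow(fx), nrow(gen$fixations))
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_equal(unlist(truth$beta), cfg$beta)
})
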