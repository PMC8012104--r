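test_that("fixation logs load ordered with structural validation", {
  path <- withr::local_tempfile(fileext = ".tsv")
  fx <- make_fixations(list(list(0L, 1, 200), list(0L, 3, 180),
                            list(0L, 5, 220), list(1L, 1, 150),
                            list(1L, 3, 240)))
  write_fixations(fx, path)
  back <- load_fixations(path)
  expect_equal(nrow(back), 5L)
  expect_equal(back$duration, fx$duration)
  expect_false(any(back$blink))

  dup <- fx; dup$seq_index[2] <- 0L
  write_fixations(dup, path)
  expect_error(load_fixations(path), "seq_index not strictly increasing")

  writeLines(c("participant_id\ttrial_id\tseq_index\tline_id\tchar_pos",
               "p1\t0\t0\t0\t1.5"), path)
  expect_error(load_fixations(path), "duration")

  bad <- fx; bad$duration[1] <- 0
  write_fixations(bad, path)
  expect_error(load_fixations(path), "non-positive fixation duration")
})

test_that("fixations map to the strictly containing word; boundaries are unmapped", {
  text <- make_text(list(list("abc", 3L, 0L, 0L, 0L),
                         list("de", 2L, 0L, 0L, 0L)))
  expect_equal(map_fixation_to_token(list(line_id = 0L, char_pos = 1.5), text), 0L)
  expect_equal(map_fixation_to_token(list(line_id = 0L, char_pos = 3.5), text), 1L)
  # exactly on the boundary between [0,3) and [3,5): excluded
  expect_true(is.na(map_fixation_to_token(list(line_id = 0L, char_pos = 3), text)))
  expect_true(is.na(map_fixation_to_token(list(line_id = 0L, char_pos = 99), text)))
  expect_true(is.na(map_fixation_to_token(list(line_id = 7L, char_pos = 1), text)))
})

test_that("the filter reproduces the hand-derived partition of a constructed log", {
  text <- two_line_text()
  # line 0 words at local [0,2),[2,4),[4,6),[6,8); line 1 the same
  fx <- make_fixations(list(
    list(0L, 3.0 - 0.5, 210),          # trial-first (would otherwise be clean)
    list(0L, 3.0, 180, TRUE),          # blink (position irrelevant)
    list(0L, 3.0, 150),                # clean on word B        -> retained
    list(1L, 3.0, 200),                # first fixation after line change
    list(1L, 3.0, 70),                 # too short
    list(1L, 3.0, 900),                # too long
    list(1L, 7.0, 250),                # last word of its line
    list(1L, 4.0, 230),                # exactly on a word boundary
    list(1L, 5.0, 260),                # clean on word G        -> retained
    list(1L, 2.5, 240)                 # trial-last
  ))
  res <- filter_fixations(fx, text)
  expect_equal(res$report$n_input, 10L)
  expect_equal(res$report$n_retained, 2L)
  expect_equal(unname(res$report$exclusions),
               c(1L, 2L, 1L, 1L, 1L, 1L, 1L, 0L))
  expect_equal(names(res$report$exclusions),
               c("blink", "trial_first_last", "line_switch", "duration_low",
                 "duration_high", "line_first_last_word", "boundary_saccade",
                 "unmapped"))
  expect_equal(res$report$n_input,
               res$report$n_retained + sum(res$report$exclusions))
  expect_equal(res$retained$token_id, c(1L, 6L))

  # each fixation is counted once, under the first matching rule
  expect_equal(res$retained$duration, c(150, 260))
})

test_that("duration bounds are strict: 80 and 800 ms are retained", {
  text <- two_line_text()
  mid <- function(d) list(0L, 3.0, d)
  fx <- make_fixations(list(mid(100), mid(80), mid(800), mid(79), mid(801),
                            mid(100)))
  res <- filter_fixations(fx, text)
  # trial edges (the two 100 ms fixations) go first; the endpoints survive,
  # 79 and 801 are cut ("less than 80 ms and greater than 800 ms")
  expect_equal(res$retained$duration, c(80, 800))
  expect_equal(unname(res$report$exclusions[c("duration_low", "duration_high")]),
               c(1L, 1L))
})

test_that("re-filtering retained output is a no-op", {
  cfg <- small_config(seed = 2, rate_blink = 0.05, rate_bad_duration = 0.05,
                      rate_boundary = 0.05)
  gen <- generate_dataset(cfg, withr::local_tempdir())
  res1 <- filter_fixations(gen$fixations, gen$text)
  res2 <- filter_fixations(res1$retained, gen$text)
  expect_equal(res2$report$n_retained, res1$report$n_retained)
  expect_equal(sum(res2$report$exclusions), 0L)
  expect_equal(res2$retained$duration, res1$retained$duration)
  expect_equal(res2$retained$token_id, res1$retained$token_id)
})

test_that("decomposition follows the first-pass definitions on crafted scanpaths", {
  text <- make_text(list(list("aa", 2L, 0L, 0L, 0L), list("bb", 2L, 0L, 0L, 0L),
                         list("cc", 2L, 0L, 0L, 0L), list("dd", 2L, 0L, 0L, 0L)))
  at <- function(tok, d) list(0L, tok * 2 + 1, d)   # centre of token `tok`

  # first pass [200, 150] on token 1, later revisit 100 after moving on
  fx <- make_fixations(list(at(0, 210), at(1, 200), at(1, 150), at(2, 180),
                            at(1, 100), at(3, 190)))
  m <- decompose_viewing_times(map_fixations(fx, text), text)
  w <- m[m$token_id == 1L, ]
  expect_equal(c(w$FFD, w$RFD, w$RRD, w$GD, w$total),
               c(200, 150, 100, 350, 450))

  # fixated once, never revisited
  expect_equal(m[m$token_id == 3L, ]$FFD, 190)
  expect_equal(m[m$token_id == 3L, ]$RFD + m[m$token_id == 3L, ]$RRD, 0)

  # token reached only by regression: all time in RRD
  fx2 <- make_fixations(list(at(0, 210), at(2, 180), at(1, 180), at(3, 190)))
  m2 <- decompose_viewing_times(map_fixations(fx2, text), text)
  w2 <- m2[m2$token_id == 1L, ]
  expect_equal(c(w2$FFD, w2$RFD, w2$RRD), c(0, 0, 180))

  # refixations after a regressive first entry stay in RRD
  fx3 <- make_fixations(list(at(0, 210), at(2, 180), at(1, 120), at(1, 110),
                             at(3, 190)))
  m3 <- decompose_viewing_times(map_fixations(fx3, text), text)
  w3 <- m3[m3$token_id == 1L, ]
  expect_equal(c(w3$FFD, w3$RFD, w3$RRD), c(0, 0, 230))

  # unmapped fixations must be resolved before decomposition
  fx4 <- make_fixations(list(at(0, 210)))
  fx4$token_id <- NA_integer_
  expect_error(decompose_viewing_times(fx4, text), "run filter_fixations")
})

test_that("decomposition conserves durations and matches the replay oracle", {
  cfg <- small_config(seed = 4)
  gen <- generate_dataset(cfg, withr::local_tempdir())
  mapped <- map_fixations(gen$fixations[, setdiff(names(gen$fixations),
                                                  c("token_id", "kind"))],
                          gen$text)
  m <- decompose_viewing_times(mapped, gen$text)

  expect_true(all(m$GD == m$FFD + m$RFD))
  expect_true(all(m$total == m$FFD + m$RFD + m$RRD))
  expect_true(all(m$skipped == (m$total == 0)))

  per_trial_in <- aggregate(duration ~ participant_id + trial_id, mapped, sum)
  per_trial_out <- aggregate(total ~ participant_id + trial_id, m, sum)
  mg <- merge(per_trial_in, per_trial_out)
  expect_true(all(mg$duration == mg$total))          # exact, integer ms

  orc <- oracle_decompose(mapped)
  key <- function(d) paste(d$participant_id, d$trial_id, d$token_id)
  m_fix <- m[!m$skipped, ]
  m_ord <- m_fix[match(key(orc), key(m_fix)), ]
  expect_equal(m_ord$FFD, orc$FFD)
  expect_equal(m_ord$RFD, orc$RFD)
  expect_equal(m_ord$RRD, orc$RRD)
})

test_that("contaminant injection shows up in the filter report at predictable counts", {
  # tight residual noise keeps every genuine duration inside [80, 800], so
  # the only out-of-range durations are the injected ones
  cfg <- small_config(seed = 9, rate_blink = 0.08, rate_bad_duration = 0.08,
                      rate_boundary = 0.08, sd_resid = 5)
  gen <- generate_dataset(cfg, withr::local_tempdir())
  res <- filter_fixations(gen$fixations, gen$text)
  ex <- res$report$exclusions

  n_blink <- sum(gen$fixations$blink)
  n_bad <- sum(gen$fixations$duration < 80 | gen$fixations$duration > 800)
  expect_gt(n_blink, 0); expect_gt(n_bad, 0)
  expect_equal(unname(ex["blink"]), n_blink)
  expect_equal(unname(ex["duration_low"] + ex["duration_high"]), n_bad)
  n_trials <- nrow(unique(gen$fixations[, c("participant_id", "trial_id")]))
  expect_equal(unname(ex["trial_first_last"]), 2L * n_trials)
  expect_equal(res$report$n_input,
               res$report$n_retained + sum(res$report$exclusions))
})
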