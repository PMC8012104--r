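#' Configuration for the synthetic reading-study generator
#'
#' Bundles every knob of the synthetic data generator: text layout, vocabulary
#' and Zipf exponent, embedding geometry, the true fixed-effect vector applied
#' to standardized predictors, random-effect and residual SDs, scanpath event
#' probabilities, and contaminant rates. All stages are deterministic given
#' `seed`.
#'
#' @param seed integer RNG seed.
#' @param n_per_group named integer vector: participants per ability group
#'   (`poor`, `average`, `good`) within each grade.
#' @param grades grade levels (default 4 and 5).
#' @param n_paragraphs,words_per_sentence text size parameters.
#' @param sentences_per_paragraph length-2 integer range; each paragraph draws
#'   its sentence count uniformly from it (default 5-7).
#' @param vocab_size,zipf_exponent vocabulary size and Zipf rank exponent for
#'   token sampling.
#' @param word_length_range surface length range in characters (default 1-5).
#' @param line_width display line width in characters for layout wrapping.
#' @param embedding_dim embedding dimension (default 128).
#' @param conc_para,conc_sent,conc_word concentration of paragraph vectors
#'   around their topic, sentence vectors around their paragraph, and word
#'   vectors around their sentence. Noise SD is `1/concentration`; `Inf`
#'   means an exact copy, `0` means an unrelated random direction.
#' @param topic_shift_rate probability that a paragraph starts a new topic.
#' @param beta named true fixed-effect vector in ms per SD of the predictor:
#'   `intercept`, `freq`, `surprisal`, `word_sent`, `sent_sent`, `sent_para`,
#'   `para_para`, `ability` (per ability level, coded -1/0/1).
#' @param ability_interaction named vector of ms/SD interaction slopes of
#'   ability with each similarity measure (default all 0).
#' @param sd_participant,sd_word,sd_resid random-intercept and residual SDs
#'   (ms).
#' @param resid_shape lognormal shape (sdlog) of the centred residual noise;
#'   controls right skew at fixed `sd_resid`.
#' @param p_skip,p_refix,p_regress per-word probabilities of skipping,
#'   refixating in first pass, and being re-visited later.
#' @param refix_scale,regress_scale duration of refixation / re-visit
#'   fixations as a fraction of the word's latent first-fixation level.
#' @param rate_blink,rate_bad_duration,rate_boundary contaminant injection
#'   rates (extra fixations per clean fixation); all 0 by default.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_per_group = c(poor = 20L, average = 20L, good = 19L),
                             grades = c(4L, 5L),
                             n_paragraphs = 12L,
                             sentences_per_paragraph = c(5L, 7L),
                             words_per_sentence = 8L,
                             vocab_size = 500L,
                             zipf_exponent = 1,
                             word_length_range = c(1L, 5L),
                             line_width = 20L,
                             embedding_dim = 128L,
                             conc_para = 3,
                             conc_sent = 4,
                             conc_word = 2,
                             topic_shift_rate = 0.3,
                             beta = c(intercept = 250, freq = -15,
                                      surprisal = 10, word_sent = -8,
                                      sent_sent = -6, sent_para = -5,
                                      para_para = -4, ability = -10),
                             ability_interaction = c(word_sent = 0,
                                                     sent_sent = 0,
                                                     sent_para = 0,
                                                     para_para = 0),
                             sd_participant = 40,
                             sd_word = 25,
                             sd_resid = 50,
                             resid_shape = 0.6,
                             p_skip = 0.10,
                             p_refix = 0.15,
                             p_regress = 0.15,
                             refix_scale = 0.6,
                             regress_scale = 0.7,
                             rate_blink = 0,
                             rate_bad_duration = 0,
                             rate_boundary = 0) {
  cfg <- list(seed = as.integer(seed), n_per_group = n_per_group,
              grades = as.integer(grades),
              n_paragraphs = as.integer(n_paragraphs),
              sentences_per_paragraph = as.integer(sentences_per_paragraph),
              words_per_sentence = as.integer(words_per_sentence),
              vocab_size = as.integer(vocab_size),
              zipf_exponent = zipf_exponent,
              word_length_range = as.integer(word_length_range),
              line_width = as.integer(line_width),
              embedding_dim = as.integer(embedding_dim),
              conc_para = conc_para, conc_sent = conc_sent,
              conc_word = conc_word,
              topic_shift_rate = topic_shift_rate,
              beta = beta, ability_interaction = ability_interaction,
              sd_participant = sd_participant, sd_word = sd_word,
              sd_resid = sd_resid, resid_shape = resid_shape,
              p_skip = p_skip, p_refix = p_refix, p_regress = p_regress,
              refix_scale = refix_scale, regress_scale = regress_scale,
              rate_blink = rate_blink, rate_bad_duration = rate_bad_duration,
              rate_boundary = rate_boundary)
  probs <- c(cfg$topic_shift_rate, cfg$p_skip, cfg$p_refix, cfg$p_regress,
             cfg$rate_blink, cfg$rate_bad_duration, cfg$rate_boundary)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]", call. = FALSE)
  if (any(c(cfg$sd_participant, cfg$sd_word, cfg$sd_resid) < 0)) {
    stop("SDs must be non-negative", call. = FALSE)
  }
  if (cfg$embedding_dim < 2L) stop("embedding dimension must be at least 2", call. = FALSE)
  if (cfg$vocab_size < 1L || cfg$n_paragraphs < 1L ||
      cfg$words_per_sentence < 1L) {
    stop("text size parameters must be positive", call. = FALSE)
  }
  needed_beta <- c("intercept", "freq", "surprisal", "word_sent", "sent_sent",
                   "sent_para", "para_para", "ability")
  if (!all(needed_beta %in% names(cfg$beta))) {
    stop("beta must name: ", paste(needed_beta, collapse = ", "), call. = FALSE)
  }
  structure(cfg, class = "generator_config")
}

#' Read a generator/analysis configuration from YAML
#' @param path YAML file whose keys are [generator_config()] arguments.
#' @return A `generator_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  for (nm in c("n_per_group", "beta", "ability_interaction")) {
    if (!is.null(vals[[nm]])) vals[[nm]] <- unlist(vals[[nm]])
  }
  do.call(generator_config, vals)
}

## ---------------------------------------------------------------------------

.random_surfaces <- function(n, len_range) {
  lens <- seq(len_range[1L], len_range[2L])
  # shorter surfaces more common, as in natural text
  wt <- rev(seq_along(lens))
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    ln <- sample(lens, 2L * need + 8L, replace = TRUE, prob = wt)
    words <- vapply(ln, function(l) {
      paste(sample(letters, l, replace = TRUE), collapse = "")
    }, "")
    out <- unique(c(out, words))
  }
  out[seq_len(n)]
}

#' Generate a synthetic hierarchical text
#'
#' Samples a Zipf-distributed vocabulary of 1-5 character surfaces, arranges
#' tokens into sentences, paragraphs (5-7 sentences each by default) and
#' wrapped display lines, and returns both the structured text and the raw
#' token stream. Deterministic under `config$seed`.
#'
#' @param config a [generator_config()].
#' @return list with `text` (a `text_structure`), `stream` (character vector
#'   of token surfaces in order) and `vocab` (the sampled vocabulary).
#' @export
generate_text <- function(config) {
  set.seed(config$seed)
  V <- config$vocab_size
  vocab <- .random_surfaces(V, config$word_length_range)
  s <- config$zipf_exponent
  zipf <- (seq_len(V))^(-s)
  zipf <- zipf / sum(zipf)

  spp <- config$sentences_per_paragraph
  rows <- list()
  char_at <- 0L
  sent_id <- -1L
  line_id <- 0L
  line_fill <- 0L
  for (p in seq_len(config$n_paragraphs) - 1L) {
    n_sent <- if (spp[1L] == spp[2L]) spp[1L] else
      sample(seq(spp[1L], spp[2L]), 1L)
    if (p > 0L && line_fill > 0L) { # paragraphs start on a fresh line
      line_id <- line_id + 1L
      line_fill <- 0L
    }
    for (snt in seq_len(n_sent)) {
      sent_id <- sent_id + 1L
      idx <- sample.int(V, config$words_per_sentence, replace = TRUE,
                        prob = zipf)
      for (w in vocab[idx]) {
        len <- nchar(w)
        if (line_fill > 0L && line_fill + len > config$line_width) {
          line_id <- line_id + 1L
          line_fill <- 0L
        }
        rows[[length(rows) + 1L]] <- list(
          surface = w, char_start = char_at, char_end = char_at + len,
          sentence_id = sent_id, paragraph_id = p, line_id = line_id
        )
        char_at <- char_at + len
        line_fill <- line_fill + len
      }
    }
  }
  df <- do.call(rbind.data.frame, rows)
  list(text = text_structure(df), stream = df$surface, vocab = vocab)
}

#' Count all n-grams of a token stream
#'
#' Exact 1- to `max_order`-gram counts of the raw stream (counted across the
#' whole stream, as in a plain corpus count file); surprisal computed from the
#' resulting table equals the stream's empirical conditional probabilities.
#'
#' @param stream character vector of token surfaces.
#' @param max_order highest order counted (default 3).
#' @return An `ngram_table`.
#' @export
generate_ngram_counts <- function(stream, max_order = 3L) {
  if (!length(stream)) stop("empty token stream", call. = FALSE)
  counts <- numeric(0)
  names(counts) <- character(0)
  all_counts <- list()
  n <- length(stream)
  for (k in seq_len(max_order)) {
    if (n < k) break
    if (k == 1L) {
      grams <- stream
    } else {
      m <- n - k + 1L
      parts <- lapply(seq_len(k), function(j) stream[seq(j, j + m - 1L)])
      grams <- do.call(paste, parts)
    }
    tab <- table(grams)
    all_counts[[k]] <- stats::setNames(as.numeric(tab), names(tab))
  }
  ngram_table(unlist(all_counts), max_order = max_order)
}

.unit_vector <- function(dim) {
  v <- stats::rnorm(dim)
  v / sqrt(sum(v^2))
}

.perturb <- function(parent, conc, dim) {
  if (is.infinite(conc)) return(parent)
  if (conc <= 0) return(.unit_vector(dim))
  v <- parent + stats::rnorm(dim) / conc
  v / sqrt(sum(v^2))
}

#' Generate hierarchical embeddings with topic structure
#'
#' Paragraphs follow a topic chain (new random topic direction with
#' probability `topic_shift_rate`); paragraph vectors are unit vectors
#' concentrated around their topic, sentence vectors around their paragraph,
#' and word vectors around their sentence. Higher concentration gives higher
#' expected parent-child cosine; `conc_sent = Inf` makes every sentence equal
#' to its paragraph vector (sent_para = 1). Deterministic under
#' `config$seed`.
#'
#' @param text a `text_structure`.
#' @param config a [generator_config()].
#' @return An `embedding_set` with `word:`, `sent:` and `para:` keys.
#' @export
generate_embeddings <- function(text, config) {
  set.seed(config$seed + 1L)
  dim <- config$embedding_dim
  if (dim < 2L) stop("embedding dimension must be at least 2", call. = FALSE)
  para_ids <- text$paragraph_index$paragraph_id
  topic <- .unit_vector(dim)
  para_vecs <- matrix(0, length(para_ids), dim)
  for (j in seq_along(para_ids)) {
    if (j > 1L && stats::runif(1L) < config$topic_shift_rate) {
      topic <- .unit_vector(dim)
    }
    para_vecs[j, ] <- .perturb(topic, config$conc_para, dim)
  }
  si <- text$sentence_index
  sent_vecs <- matrix(0, nrow(si), dim)
  for (s in seq_len(nrow(si))) {
    pj <- match(si$paragraph_id[s], para_ids)
    sent_vecs[s, ] <- .perturb(para_vecs[pj, ], config$conc_sent, dim)
  }
  toks <- text$tokens
  word_vecs <- matrix(0, nrow(toks), dim)
  srow <- match(toks$sentence_id, si$sentence_id)
  for (i in seq_len(nrow(toks))) {
    word_vecs[i, ] <- .perturb(sent_vecs[srow[i], ], config$conc_word, dim)
  }
  mat <- rbind(para_vecs, sent_vecs, word_vecs)
  rownames(mat) <- c(paste0("para:", para_ids),
                     paste0("sent:", si$sentence_id),
                     paste0("word:", toks$token_id))
  embedding_set(mat)
}

#' Generate the participant table
#'
#' One participant row per ability group member per grade; ability is an
#' ordered factor `poor < average < good`.
#'
#' @param config a [generator_config()].
#' @return data frame with `participant_id`, `grade`, `ability`.
#' @export
generate_participants <- function(config) {
  rows <- list()
  for (g in config$grades) {
    for (ab in c("poor", "average", "good")) {
      n <- config$n_per_group[[ab]]
      if (n > 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = sprintf("g%d_%s_%02d", g, ab, seq_len(n)),
          grade = g, ability = ab
        )
      }
    }
  }
  df <- do.call(rbind, rows)
  df$ability <- factor(df$ability, levels = c("poor", "average", "good"),
                       ordered = TRUE)
  rownames(df) <- NULL
  df
}

ability_code <- function(ability) {
  unname(c(poor = -1, average = 0, good = 1)[as.character(ability)])
}

# z-score columns across tokens; NA (document-initial units) -> 0 (the mean),
# so that missing-similarity tokens sit at the neutral point of the latent
# predictor and are later dropped from modelling datasets anyway.
.standardize_features <- function(features) {
  X <- as.matrix(features[, .covariate_names])
  for (j in seq_len(ncol(X))) {
    mu <- mean(X[, j], na.rm = TRUE)
    sd_j <- stats::sd(X[, j], na.rm = TRUE)
    X[, j] <- if (is.na(sd_j) || sd_j == 0) 0 else (X[, j] - mu) / sd_j
    X[is.na(X[, j]), j] <- 0
  }
  X
}

.centered_lognormal <- function(n, sd, shape) {
  if (sd == 0) return(numeric(n))
  raw <- stats::rlnorm(n, 0, shape)
  raw_sd <- sqrt((exp(shape^2) - 1) * exp(shape^2))
  sd * (raw - exp(shape^2 / 2)) / raw_sd
}

.linear_predictor <- function(Xs, config, a_code) {
  beta <- config$beta
  eta <- beta[["intercept"]] +
    as.vector(Xs %*% beta[.covariate_names]) +
    beta[["ability"]] * a_code
  inter <- config$ability_interaction
  for (nm in names(inter)) {
    if (inter[[nm]] != 0) eta <- eta + inter[[nm]] * a_code * Xs[, nm]
  }
  eta
}

#' Generate fixation scanpaths with known effect structure
#'
#' For every participant and word, a latent first-fixation level
#' `eta = beta0 + X beta + beta_ability * ability + u_participant + u_word`
#' (ms; `X` is the per-token standardized predictor matrix) determines the
#' generated durations: the first-pass fixation is `eta` plus centred
#' lognormal noise, a refixation is added with probability `p_refix`, and a
#' later re-visit (read back from the end of the trial, so the arrival
#' saccade is regressive) with probability `p_regress`. One trial per
#' paragraph. Events are serialized as a fixation log landing at each word's
#' centre; optional contaminants (blinks, out-of-range durations, boundary
#' landings) are injected as extra events at the configured rates.
#'
#' @param text a `text_structure`.
#' @param features per-token covariate data frame (`token_id` plus
#'   `freq`, `surprisal`, `word_sent`, `sent_sent`, `sent_para`,
#'   `para_para`), as from [compute_token_features()].
#' @param participants data frame from [generate_participants()].
#' @param config a [generator_config()].
#' @return list with `fixations` (the serialized log) and `truth` (a
#'   `ground_truth` list: `beta`, SDs, the standardized predictor matrix, the
#'   random effects, and the per-(participant, trial, token) generated
#'   `components` table with FFD/RFD/RRD).
#' @export
generate_scanpaths <- function(text, features, participants, config) {
  stopifnot(all(text$tokens$token_id %in% features$token_id))
  set.seed(config$seed + 2L)
  toks <- text$tokens
  n_tok <- nrow(toks)
  features <- features[match(toks$token_id, features$token_id), , drop = FALSE]
  Xs <- .standardize_features(features)

  u_word <- stats::rnorm(n_tok, 0, config$sd_word)
  u_part <- stats::setNames(
    stats::rnorm(nrow(participants), 0, config$sd_participant),
    participants$participant_id)

  line_start <- tapply(toks$char_start, toks$line_id, min)
  local_center <- (toks$char_start + toks$char_end) / 2 -
    line_start[as.character(toks$line_id)]
  local_end <- stats::setNames(
    toks$char_end - line_start[as.character(toks$line_id)], toks$token_id)

  para_ids <- text$paragraph_index$paragraph_id
  fix_rows <- list()
  comp_rows <- list()
  for (pi in seq_len(nrow(participants))) {
    pid <- participants$participant_id[pi]
    a_code <- ability_code(participants$ability[pi])
    eta <- .linear_predictor(Xs, config, a_code) + u_part[[pid]] + u_word

    skip <- stats::runif(n_tok) < config$p_skip
    refix <- stats::runif(n_tok) < config$p_refix
    regress <- stats::runif(n_tok) < config$p_regress
    d_ffd <- pmax(1, round(eta + .centered_lognormal(n_tok, config$sd_resid,
                                                     config$resid_shape)))
    d_rfd <- pmax(1, round(config$refix_scale * eta +
                             .centered_lognormal(n_tok, config$sd_resid,
                                                 config$resid_shape)))
    d_rrd <- pmax(1, round(config$regress_scale * eta +
                             .centered_lognormal(n_tok, config$sd_resid,
                                                 config$resid_shape)))

    for (p in para_ids) {
      in_para <- which(toks$paragraph_id == p)
      fixated <- in_para[!skip[in_para]]
      if (!length(fixated)) next
      last_fix <- max(fixated)
      # re-visits are replayed from the end of the trial backwards so the
      # first arrival on each target is a regressive saccade
      targets <- in_para[regress[in_para]]
      targets <- sort(targets[targets < last_fix], decreasing = TRUE)

      ev_tok <- integer(0); ev_dur <- numeric(0); ev_kind <- character(0)
      for (i in fixated) {
        ev_tok <- c(ev_tok, i); ev_dur <- c(ev_dur, d_ffd[i])
        ev_kind <- c(ev_kind, "FFD")
        if (refix[i]) {
          ev_tok <- c(ev_tok, i); ev_dur <- c(ev_dur, d_rfd[i])
          ev_kind <- c(ev_kind, "RFD")
        }
      }
      for (i in targets) {
        ev_tok <- c(ev_tok, i); ev_dur <- c(ev_dur, d_rrd[i])
        ev_kind <- c(ev_kind, "RRD")
      }

      fix_rows[[length(fix_rows) + 1L]] <- data.frame(
        participant_id = pid, trial_id = p,
        line_id = toks$line_id[ev_tok],
        char_pos = local_center[ev_tok],
        duration = ev_dur, blink = FALSE,
        token_id = toks$token_id[ev_tok], kind = ev_kind
      )
      comp <- data.frame(
        participant_id = pid, trial_id = p,
        token_id = toks$token_id[in_para],
        FFD = 0, RFD = 0, RRD = 0
      )
      rows_of <- match(ev_tok, in_para)
      for (e in seq_along(ev_tok)) {
        comp[rows_of[e], ev_kind[e]] <- comp[rows_of[e], ev_kind[e]] + ev_dur[e]
      }
      comp_rows[[length(comp_rows) + 1L]] <- comp
    }
  }
  fixations <- do.call(rbind, fix_rows)
  fixations <- .inject_contaminants(fixations, local_end, config)
  # renumber events per trial
  key <- paste(fixations$participant_id, fixations$trial_id)
  fixations$seq_index <- stats::ave(seq_len(nrow(fixations)), key,
                                    FUN = seq_along) - 1L
  fixations <- fixations[, c("participant_id", "trial_id", "seq_index",
                             "line_id", "char_pos", "duration", "blink",
                             "token_id", "kind")]
  rownames(fixations) <- NULL
  components <- do.call(rbind, comp_rows)
  components$GD <- components$FFD + components$RFD
  components$total <- components$GD + components$RRD
  components$skipped <- components$total == 0
  rownames(components) <- NULL

  truth <- structure(list(
    beta = config$beta,
    ability_interaction = config$ability_interaction,
    sd_participant = config$sd_participant,
    sd_word = config$sd_word,
    sd_resid = config$sd_resid,
    features_std = data.frame(token_id = toks$token_id, Xs),
    u_participant = u_part,
    u_word = stats::setNames(u_word, toks$token_id),
    components = components
  ), class = "ground_truth")
  list(fixations = fixations, truth = truth)
}

.inject_contaminants <- function(fixations, local_end, config) {
  rates <- c(config$rate_blink, config$rate_bad_duration, config$rate_boundary)
  if (all(rates == 0)) return(fixations)
  n <- nrow(fixations)
  extra <- list()
  bad_dur <- c(40, 900)
  bad_i <- 0L
  # never insert after a trial's final fixation, so injected events cannot
  # occupy a trial-edge slot and per-reason filter counts stay predictable
  key <- paste(fixations$participant_id, fixations$trial_id)
  trial_last <- tapply(seq_len(n), key, max)
  for (i in setdiff(seq_len(n), trial_last)) {
    base <- fixations[i, ]
    if (stats::runif(1L) < config$rate_blink) {
      row <- base; row$blink <- TRUE; row$duration <- 150; row$kind <- "contaminant"
      extra[[length(extra) + 1L]] <- list(after = i, row = row)
    }
    if (stats::runif(1L) < config$rate_bad_duration) {
      bad_i <- bad_i + 1L
      row <- base; row$duration <- bad_dur[1L + bad_i %% 2L]; row$kind <- "contaminant"
      extra[[length(extra) + 1L]] <- list(after = i, row = row)
    }
    if (stats::runif(1L) < config$rate_boundary) {
      row <- base; row$duration <- 200; row$kind <- "contaminant"
      row$char_pos <- unname(local_end[as.character(row$token_id)])
      extra[[length(extra) + 1L]] <- list(after = i, row = row)
    }
  }
  if (!length(extra)) return(fixations)
  pieces <- list()
  prev <- 0L
  for (e in extra) {
    pieces[[length(pieces) + 1L]] <- fixations[seq(prev + 1L, e$after), ,
                                               drop = FALSE]
    pieces[[length(pieces) + 1L]] <- e$row
    prev <- e$after
  }
  if (prev < n) pieces[[length(pieces) + 1L]] <- fixations[seq(prev + 1L, n), ,
                                                           drop = FALSE]
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Compute the per-token predictor table
#'
#' Joins log relative frequency, backoff surprisal and the four similarity
#' measures into one covariate row per token.
#'
#' @param text a `text_structure`.
#' @param table an `ngram_table`.
#' @param emb an `embedding_set`.
#' @return data frame with `token_id`, `surface`, `freq`, `surprisal`,
#'   `order_used`, `word_sent`, `sent_sent`, `sent_para`, `para_para`.
#' @export
compute_token_features <- function(text, table, emb) {
  toks <- text$tokens
  sp <- annotate_surprisal(text, table)
  sim <- similarity_features(text, emb)
  data.frame(
    token_id = toks$token_id,
    surface = toks$surface,
    freq = word_frequency(table, toks$surface),
    surprisal = sp$surprisal,
    order_used = sp$order_used,
    sim[, .sim_names]
  )
}

#' Simulate a ready-to-model dataset with known truth
#'
#' Model-level companion to [generate_scanpaths()] for calibration studies
#' (parameter recovery, type-I error): generates a text, its n-gram counts
#' and embeddings under `config`, standardizes the predictors, and draws the
#' dependent variable directly from the mixed model
#' `dv = beta0 + X beta + beta_a * ability + u_participant + u_word + e`
#' with centred lognormal residuals, skipping scanpath serialization.
#' Document-initial tokens with undefined similarities are excluded.
#'
#' @param config a [generator_config()].
#' @return list with `rows` (modelling data frame: `dv`, standardized
#'   covariates, `ability_code`, `grade`, ids) and `truth` (`beta` and SDs).
#' @export
simulate_modelling_data <- function(config) {
  gen <- generate_text(config)
  table <- generate_ngram_counts(gen$stream)
  emb <- generate_embeddings(gen$text, config)
  features <- compute_token_features(gen$text, table, emb)
  participants <- generate_participants(config)

  set.seed(config$seed + 3L)
  complete <- stats::complete.cases(features[, .covariate_names])
  features <- features[complete, , drop = FALSE]
  Xs <- .standardize_features(features)  # complete rows: no imputation occurs
  # re-standardize on the modelled set so truth applies exactly per SD
  n_tok <- nrow(features)
  u_word <- stats::rnorm(n_tok, 0, config$sd_word)
  u_part <- stats::rnorm(nrow(participants), 0, config$sd_participant)

  rows <- vector("list", nrow(participants))
  for (pi in seq_len(nrow(participants))) {
    a_code <- ability_code(participants$ability[pi])
    eta <- .linear_predictor(Xs, config, a_code) + u_part[pi] + u_word
    dv <- round(eta + .centered_lognormal(n_tok, config$sd_resid,
                                          config$resid_shape))
    rows[[pi]] <- data.frame(
      participant_id = participants$participant_id[pi],
      token_id = features$token_id,
      grade = participants$grade[pi],
      ability = as.character(participants$ability[pi]),
      ability_code = a_code,
      Xs, dv = dv
    )
  }
  rows <- do.call(rbind, rows)
  rows$ability <- factor(rows$ability, levels = c("poor", "average", "good"),
                         ordered = TRUE)
  rownames(rows) <- NULL
  list(rows = rows,
       truth = list(beta = config$beta,
                    ability_interaction = config$ability_interaction,
                    sd_participant = config$sd_participant,
                    sd_word = config$sd_word,
                    sd_resid = config$sd_resid))
}

#' Write the five synthetic input files plus ground truth
#'
#' Emits `text.tsv`, `ngrams.tsv`, `embeddings.vec`, `participants.tsv`,
#' `fixations.tsv` and `ground_truth.json` into `dir`.
#'
#' @param config a [generator_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the generated objects.
#' @export
generate_dataset <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  # each artifact is written as soon as it exists, so a failure mid-way
  # leaves the earlier files on disk
  gen <- generate_text(config)
  write_text_table(gen$text, file.path(dir, "text.tsv"))
  table <- generate_ngram_counts(gen$stream)
  write_ngram_table(table, file.path(dir, "ngrams.tsv"))
  emb <- generate_embeddings(gen$text, config)
  write_embeddings(emb, file.path(dir, "embeddings.vec"))
  participants <- generate_participants(config)
  if (is.null(participants) || nrow(participants) == 0L) {
    stop("configuration yields no participants", call. = FALSE)
  }
  utils::write.table(participants, file.path(dir, "participants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  features <- compute_token_features(gen$text, table, emb)
  sp <- generate_scanpaths(gen$text, features, participants, config)
  write_fixations(sp$fixations, file.path(dir, "fixations.tsv"))

  truth <- sp$truth
  truth_json <- list(
    beta = as.list(truth$beta),
    ability_interaction = as.list(truth$ability_interaction),
    sd_participant = truth$sd_participant,
    sd_word = truth$sd_word,
    sd_resid = truth$sd_resid,
    u_participant = as.list(truth$u_participant),
    u_word = as.list(truth$u_word)
  )
  jsonlite::write_json(truth_json, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = 10)
  invisible(list(text = gen$text, stream = gen$stream, ngrams = table,
                 embeddings = emb, participants = participants,
                 features = features, fixations = sp$fixations,
                 truth = truth))
}
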