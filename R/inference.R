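#' Assemble the modelling dataset for one viewing-time component
#'
#' Joins per-word viewing-time measures, per-token covariates and the
#' participant table into one row per (participant, word) viewing instance
#' with a positive dependent variable. Skipped words and zero-duration
#' components are not valid observations and are excluded, as are rows whose
#' similarity covariates are undefined (document-initial sentence or
#' paragraph); the number of rows dropped for missing covariates is recorded
#' in the `n_dropped_missing` attribute.
#'
#' @param measures data frame from [decompose_viewing_times()].
#' @param features data frame from [compute_token_features()].
#' @param participants participant table (`participant_id`, `grade`,
#'   `ability`).
#' @param dv which component to model: `"FFD"`, `"RFD"` or `"RRD"`.
#' @param standardize z-score the six numeric covariates across the modelled
#'   rows (default `TRUE`; recorded in the `standardized` attribute).
#' @return data frame of class `feature_rows` with columns `participant_id`,
#'   `token_id`, `grade`, `ability`, `ability_code`, the six covariates and
#'   `dv`.
#' @export
build_dataset <- function(measures, features, participants,
                          dv = c("FFD", "RFD", "RRD"), standardize = TRUE) {
  dv <- match.arg(dv)
  orphan_tok <- setdiff(measures$token_id, features$token_id)
  if (length(orphan_tok)) {
    stop("measures reference token_id(s) absent from features: ",
         paste(utils::head(orphan_tok, 5L), collapse = ", "), call. = FALSE)
  }
  orphan_part <- setdiff(measures$participant_id, participants$participant_id)
  if (length(orphan_part)) {
    stop("measures reference participant(s) absent from participant table: ",
         paste(utils::head(orphan_part, 5L), collapse = ", "), call. = FALSE)
  }
  obs <- measures[!measures$skipped & measures[[dv]] > 0, , drop = FALSE]
  df <- merge(obs[, c("participant_id", "token_id", dv)],
              features[, c("token_id", .covariate_names)], by = "token_id")
  df <- merge(df, participants, by = "participant_id")
  complete <- stats::complete.cases(df[, .covariate_names])
  n_dropped <- sum(!complete)
  df <- df[complete, , drop = FALSE]
  if (!nrow(df)) stop("no modellable rows", call. = FALSE)
  if (standardize) {
    for (v in .covariate_names) {
      df[[v]] <- as.vector(scale(df[[v]]))
    }
  }
  df$ability <- factor(as.character(df$ability),
                       levels = c("poor", "average", "good"), ordered = TRUE)
  df$ability_code <- ability_code(df$ability)
  names(df)[names(df) == dv] <- "dv"
  df <- df[order(df$participant_id, df$token_id),
           c("participant_id", "token_id", "grade", "ability", "ability_code",
             .covariate_names, "dv")]
  rownames(df) <- NULL
  structure(df, class = c("feature_rows", "data.frame"),
            dv_name = dv, standardized = standardize,
            n_dropped_missing = n_dropped)
}

.fixed_terms <- c(.covariate_names, "ability_code")

#' Fit the viewing-time linear mixed-effects model
#'
#' REML fit of the viewing-time component on the seven fixed predictors
#' (log frequency, surprisal, the four similarity measures, and reading
#' ability coded -1/0/1) with crossed random intercepts for participant and
#' word:
#' `dv ~ freq + surprisal + word_sent + sent_sent + sent_para + para_para +
#'  ability_code + (1 | participant_id) + (1 | token_id)`.
#'
#' @param rows a `feature_rows` data frame (or any data frame with those
#'   columns).
#' @param interactions also estimate ability-by-similarity interaction terms.
#' @param df_method `"satterthwaite"` (via lmerTest) or `"residual"`
#'   (t against `n - p` residual df; much faster in simulation loops).
#' @param reml fit by REML (default) or ML.
#' @return An object of class `lmm_result`: coefficient table (estimate, SE,
#'   t, df, p per term), variance components, `n_obs`, convergence and
#'   singularity flags, and the underlying fitted model in `$model`.
#' @export
fit_lmm <- function(rows, interactions = FALSE,
                    df_method = c("satterthwaite", "residual"), reml = TRUE) {
  df_method <- match.arg(df_method)
  if (length(unique(rows$participant_id)) < 2L ||
      length(unique(rows$token_id)) < 2L) {
    stop("need at least 2 participants and 2 words", call. = FALSE)
  }
  fixed <- .fixed_terms
  if (interactions) {
    fixed <- c(fixed, paste0("ability_code:", .sim_names))
  }
  form <- stats::as.formula(paste(
    "dv ~", paste(fixed, collapse = " + "),
    "+ (1 | participant_id) + (1 | token_id)"))
  fit <- withCallingHandlers(
    if (df_method == "satterthwaite") {
      lmerTest::lmer(form, data = rows, REML = reml)
    } else {
      lme4::lmer(form, data = rows, REML = reml)
    },
    warning = function(w) invokeRestart("muffleWarning"),
    message = function(m) invokeRestart("muffleMessage")
  )
  singular <- lme4::isSingular(fit, tol = 1e-5)
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  converged <- fit@optinfo$conv$opt == 0 &&
    (is.null(msgs) || all(grepl("singular|boundary", msgs, ignore.case = TRUE)))

  if (df_method == "satterthwaite") {
    ct <- stats::coef(summary(fit))
    coefs <- data.frame(term = rownames(ct), estimate = ct[, "Estimate"],
                        se = ct[, "Std. Error"], t = ct[, "t value"],
                        df = ct[, "df"], p = ct[, "Pr(>|t|)"])
  } else {
    ct <- stats::coef(summary(fit))
    rdf <- nrow(rows) - nrow(ct)
    tval <- ct[, "t value"]
    coefs <- data.frame(term = rownames(ct), estimate = ct[, "Estimate"],
                        se = ct[, "Std. Error"], t = tval, df = rdf,
                        p = 2 * stats::pt(-abs(tval), rdf))
  }
  rownames(coefs) <- NULL
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcor <- stats::setNames(vc$sdcor, ifelse(is.na(vc$grp) | vc$grp == "Residual",
                                             "residual", vc$grp))
  structure(
    list(coefficients = coefs,
         varcor = list(participant = unname(varcor[["participant_id"]]),
                       word = unname(varcor[["token_id"]]),
                       residual = unname(varcor[["residual"]])),
         n_obs = nrow(rows), converged = converged, singular = singular,
         df_method = df_method, formula = form, model = fit),
    class = "lmm_result"
  )
}

#' @export
print.lmm_result <- function(x, ...) {
  cat("<lmm_result> n_obs = ", x$n_obs,
      if (!x$converged) " [NOT CONVERGED]",
      if (x$singular) " [singular fit]", "\n", sep = "")
  print(cbind(x$coefficients[, "term", drop = FALSE],
              round(x$coefficients[, -1L], 4)))
  cat("Random-effect SDs: participant ", round(x$varcor$participant, 2),
      ", word ", round(x$varcor$word, 2),
      ", residual ", round(x$varcor$residual, 2), "\n", sep = "")
  invisible(x)
}
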