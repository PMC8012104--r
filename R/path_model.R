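#' Recursive path analysis of the similarity measures
#'
#' Estimates a causally ordered system of least-squares regressions over
#' standardized observed variables. The ordering runs coarse to fine:
#' `para_para -> sent_para -> sent_sent -> word_sent -> dv`, with word
#' frequency and surprisal entering every equation as exogenous covariates
#' (they are part of the model but have no equations of their own, and
#' `para_para` is the most upstream observed variable). Each endogenous
#' variable is regressed on all of its predecessors plus the two exogenous
#' covariates. The effect of a source on the dependent variable decomposes
#' into a direct effect (its coefficient in the DV equation) and an indirect
#' effect (the sum over all directed paths through mediators of the products
#' of path coefficients); total = direct + indirect.
#'
#' @param rows data frame with columns `freq`, `surprisal`, `word_sent`,
#'   `sent_sent`, `sent_para`, `para_para` and `dv` (complete cases only).
#'   All variables are z-scored internally, so coefficients are standardized.
#' @param dv_label label for the dependent variable in printed output.
#' @return An object of class `path_model`: `edges` (one row per path
#'   coefficient: from, to, estimate, se, t, p), `effects` (per source:
#'   direct, indirect, total on the DV) and `n_obs`.
#' @export
fit_path_model <- function(rows, dv_label = "dv") {
  vars <- c("para_para", "sent_para", "sent_sent", "word_sent", "dv")
  exog <- c("freq", "surprisal")
  need <- c(vars, exog)
  if (!all(need %in% names(rows))) {
    stop("rows must contain: ", paste(need, collapse = ", "), call. = FALSE)
  }
  d <- rows[, need]
  if (anyNA(d)) stop("path analysis requires complete rows", call. = FALSE)
  for (v in need) d[[v]] <- as.vector(scale(d[[v]]))

  endo <- vars[-1L]
  edges <- list()
  for (i in seq_along(endo)) {
    y <- endo[i]
    preds <- c(vars[seq_len(match(y, vars) - 1L)], exog)
    form <- stats::as.formula(paste(y, "~", paste(preds, collapse = " + ")))
    fit <- stats::lm(form, data = d)
    cf <- stats::coef(fit)
    if (anyNA(cf)) {
      stop("rank-deficient equation for ", y, "; collinear predictors: ",
           paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
    }
    # small grouped subsets can fit an upstream equation perfectly; the
    # summary warning about unreliable SEs is expected there
    sm <- suppressWarnings(stats::coef(summary(fit)))
    for (p in preds) {
      edges[[length(edges) + 1L]] <- data.frame(
        from = p, to = y, estimate = sm[p, "Estimate"],
        se = sm[p, "Std. Error"], t = sm[p, "t value"],
        p = sm[p, "Pr(>|t|)"])
    }
  }
  edges <- do.call(rbind, edges)
  rownames(edges) <- NULL

  coef_of <- function(from, to) {
    v <- edges$estimate[edges$from == from & edges$to == to]
    if (length(v)) v else 0
  }
  succ <- function(v) unique(edges$to[edges$from == v])
  # sum over all directed paths v -> ... -> dv of products of coefficients
  total_effect <- function(v) {
    if (v == "dv") return(1)
    sum(vapply(succ(v), function(m) coef_of(v, m) * total_effect(m), 0))
  }
  sources <- c(exog, vars[-length(vars)])
  effects <- data.frame(
    source = sources,
    direct = vapply(sources, function(v) coef_of(v, "dv"), 0),
    total = vapply(sources, total_effect, 0)
  )
  effects$indirect <- effects$total - effects$direct
  effects <- effects[, c("source", "direct", "indirect", "total")]
  rownames(effects) <- NULL

  structure(list(edges = edges, effects = effects, n_obs = nrow(d),
                 dv_label = dv_label),
            class = "path_model")
}

#' @export
print.path_model <- function(x, ...) {
  cat("<path_model> DV = ", x$dv_label, ", n = ", x$n_obs, "\n", sep = "")
  cat("Effect decomposition on the DV (standardized):\n")
  print(cbind(x$effects["source"], round(x$effects[, -1L], 4)))
  invisible(x)
}

#' Run the full analysis grid
#'
#' Reproduces the study's analysis layout on one dataset: for each
#' viewing-time component (FFD, RFD, RRD) an overall LMM and one LMM per
#' grade; and for FFD and RRD (RFD is excluded from path analysis) an overall
#' path model plus path models for the good- and poor-reader subsets.
#' Individual fits that fail (e.g. a grade with too few participants) are
#' recorded as failure markers rather than aborting the grid.
#'
#' @param measures data frame from [decompose_viewing_times()].
#' @param features data frame from [compute_token_features()].
#' @param participants participant table.
#' @param interactions include ability-by-similarity interactions in LMMs.
#' @param df_method degrees-of-freedom method passed to [fit_lmm()].
#' @param meta optional named list recorded verbatim in the bundle metadata
#'   (e.g. seed and config hash).
#' @param grades grade levels the grid should cover; levels with no
#'   observations are emitted as failure markers (default: grades present in
#'   `participants`).
#' @return A `report_bundle`: list with `meta`, `lmm` (per DV: `overall` and
#'   `grade_<g>` entries) and `path` (per DV in FFD/RRD: `overall`,
#'   `ability_good`, `ability_poor`). Failed cells are lists with an `error`
#'   string.
#' @export
run_analysis_suite <- function(measures, features, participants,
                               interactions = FALSE,
                               df_method = "satterthwaite",
                               meta = list(),
                               grades = sort(unique(participants$grade))) {
  try_fit <- function(expr) {
    tryCatch(expr, error = function(e) list(error = conditionMessage(e)))
  }
  bundle <- list(meta = c(meta, list(
    n_participants = length(unique(participants$participant_id)),
    interactions = interactions, df_method = df_method,
    multiple_testing = "none")),
    lmm = list(), path = list())

  for (dv in c("FFD", "RFD", "RRD")) {
    rows <- try_fit(build_dataset(measures, features, participants, dv = dv))
    if (!is.null(rows$error)) {
      bundle$lmm[[dv]] <- list(overall = rows)
      next
    }
    cell <- list(overall = try_fit(fit_lmm(rows, interactions = interactions,
                                           df_method = df_method)))
    for (g in grades) {
      sub <- rows[rows$grade == g, , drop = FALSE]
      cell[[paste0("grade_", g)]] <- if (nrow(sub) == 0L) {
        list(error = "no observations for this grade")
      } else {
        try_fit(fit_lmm(sub, interactions = interactions,
                        df_method = df_method))
      }
    }
    bundle$lmm[[dv]] <- cell
    bundle$meta$n_rows[[dv]] <- nrow(rows)

    if (dv %in% c("FFD", "RRD")) {
      pcell <- list(overall = try_fit(fit_path_model(rows, dv_label = dv)))
      for (ab in c("good", "poor")) {
        sub <- rows[as.character(rows$ability) == ab, , drop = FALSE]
        pcell[[paste0("ability_", ab)]] <- if (nrow(sub) == 0L) {
          list(error = "no observations for this ability group")
        } else {
          try_fit(fit_path_model(sub, dv_label = dv))
        }
      }
      bundle$path[[dv]] <- pcell
    }
  }
  structure(bundle, class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle> LMM grids: ", paste(names(x$lmm), collapse = ", "),
      "; path grids: ", paste(names(x$path), collapse = ", "), "\n", sep = "")
  invisible(x)
}
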