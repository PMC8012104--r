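# End-to-end orchestration and reporting.

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = 12)
  unname(tools::md5sum(tmp))
}

.bundle_to_json <- function(bundle) {
  strip <- function(x) {
    if (inherits(x, "lmm_result")) {
      list(coefficients = x$coefficients, varcor = x$varcor, n_obs = x$n_obs,
           converged = x$converged, singular = x$singular,
           df_method = x$df_method)
    } else if (inherits(x, "path_model")) {
      list(edges = x$edges, effects = x$effects, n_obs = x$n_obs,
           dv_label = x$dv_label)
    } else if (is.list(x)) {
      lapply(x, strip)
    } else x
  }
  strip(unclass(bundle))
}

#' Write a report bundle to disk
#'
#' Writes one TSV per fitted table (`lmm_<dv>_<split>.tsv` coefficient
#' tables, `path_<dv>_<split>_effects.tsv` decompositions) plus a
#' machine-readable `bundle.json`. Output is byte-deterministic for a given
#' bundle.
#'
#' @param bundle a `report_bundle` from [run_analysis_suite()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, path) {
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(x) signif(x, 10))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (dv in names(bundle$lmm)) {
    for (split in names(bundle$lmm[[dv]])) {
      fit <- bundle$lmm[[dv]][[split]]
      if (inherits(fit, "lmm_result")) {
        wt(fit$coefficients,
           file.path(dir, sprintf("lmm_%s_%s.tsv", dv, split)))
      }
    }
  }
  for (dv in names(bundle$path)) {
    for (split in names(bundle$path[[dv]])) {
      fit <- bundle$path[[dv]][[split]]
      if (inherits(fit, "path_model")) {
        wt(fit$effects,
           file.path(dir, sprintf("path_%s_%s_effects.tsv", dv, split)))
        wt(fit$edges,
           file.path(dir, sprintf("path_%s_%s_edges.tsv", dv, split)))
      }
    }
  }
  jsonlite::write_json(.bundle_to_json(bundle), file.path(dir, "bundle.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(dir)
}

#' Run the full synthetic-study pipeline
#'
#' Executes the four stages end to end into `out_dir`:
#' \enumerate{
#'   \item `generate` - synthetic text, n-gram counts, embeddings,
#'     participants and fixation log (the five input files) + ground truth;
#'   \item `features` - reload the input files and compute the per-token
#'     predictor table (`features.tsv`);
#'   \item `gaze` - filter the fixation log and decompose viewing times
#'     (`measures.tsv`, `filter_report.json`);
#'   \item `fit` - assemble datasets and run the LMM/path analysis grid
#'     (`report/`).
#' }
#' A `manifest.json` records the seed, config hash, per-stage status, row
#' counts and md5 digests of every file. Runs are deterministic: identical
#' seed and config give byte-identical output (timestamps are only recorded
#' when `record_timestamp = TRUE`, which breaks byte-level reproducibility).
#' If a stage fails, later stages are skipped and the manifest records the
#' partial completion; earlier outputs are left intact.
#'
#' @param config a [generator_config()] or path to a YAML config file.
#' @param out_dir output directory.
#' @param interactions,df_method analysis options passed to
#'   [run_analysis_suite()].
#' @param record_timestamp record a wall-clock timestamp in the manifest.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir, interactions = FALSE,
                         df_method = "satterthwaite",
                         record_timestamp = FALSE) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "generator_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, config_hash = .config_hash(config),
                   package_version = as.character(utils::packageVersion("readgaze")),
                   stages = list(), counts = list())
  if (record_timestamp) manifest$timestamp <- format(Sys.time(), tz = "UTC")

  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) e)
    ok <- !inherits(res, "error")
    manifest$stages[[name]] <<- if (ok) "ok" else
      paste("failed:", conditionMessage(res))
    if (!ok) NULL else res
  }

  gen <- run_stage("generate", generate_dataset(config, out_dir))
  if (!is.null(gen)) {
    manifest$counts$tokens <- nrow(gen$text$tokens)
    manifest$counts$fixations_generated <- nrow(gen$fixations)

    feat <- run_stage("features", {
      text <- load_text_table(file.path(out_dir, "text.tsv"))
      table <- load_ngram_table(file.path(out_dir, "ngrams.tsv"))
      emb <- load_embeddings(file.path(out_dir, "embeddings.vec"),
                             config$embedding_dim)
      features <- compute_token_features(text, table, emb)
      utils::write.table(
        cbind(features[1:2],
              lapply(features[-(1:2)], function(x)
                if (is.numeric(x)) signif(x, 10) else x)),
        file.path(out_dir, "features.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      list(text = text, features = features)
    })
    if (!is.null(feat)) {
      gz <- run_stage("gaze", {
        fx <- load_fixations(file.path(out_dir, "fixations.tsv"))
        flt <- filter_fixations(fx, feat$text)
        measures <- decompose_viewing_times(flt$retained, feat$text)
        write_word_measures(measures, file.path(out_dir, "measures.tsv"))
        jsonlite::write_json(
          list(n_input = flt$report$n_input,
               n_retained = flt$report$n_retained,
               exclusions = as.list(flt$report$exclusions)),
          file.path(out_dir, "filter_report.json"),
          auto_unbox = TRUE, pretty = TRUE)
        list(measures = measures, report = flt$report)
      })
      if (!is.null(gz)) {
        manifest$counts$fixations_retained <- gz$report$n_retained
        fit <- run_stage("fit", {
          participants <- utils::read.delim(
            file.path(out_dir, "participants.tsv"),
            colClasses = c(participant_id = "character"))
          bundle <- run_analysis_suite(
            gz$measures, feat$features, participants,
            interactions = interactions, df_method = df_method,
            meta = list(seed = config$seed,
                        config_hash = manifest$config_hash),
            grades = config$grades)
          write_report_bundle(bundle, file.path(out_dir, "report"))
          bundle
        })
      }
    }
  }
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.json"))
  digests <- tools::md5sum(file.path(out_dir, files))
  manifest$files <- as.list(stats::setNames(unname(digests), files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Partial-effect plot of a similarity term
#'
#' Plots the dependent variable after removing the estimated participant and
#' word random intercepts (the between-subject and between-word variance)
#' against one model term, with one regression line per level of the chosen
#' split factor.
#'
#' @param fit an `lmm_result` from [fit_lmm()].
#' @param rows the `feature_rows` data the model was fitted on.
#' @param term one of the model's similarity/covariate terms.
#' @param split `"ability"` or `"grade"`.
#' @param file optional output path (png/svg/pdf); if given, the plot is
#'   saved there.
#' @return the ggplot object, invisibly if saved to file.
#' @export
plot_effects <- function(fit, rows, term, split = c("ability", "grade"),
                         file = NULL) {
  split <- match.arg(split)
  if (!term %in% .fixed_terms) {
    stop("unknown term '", term, "'; available: ",
         paste(.fixed_terms, collapse = ", "), call. = FALSE)
  }
  adj <- adjusted_dv(fit, rows)
  d <- data.frame(x = rows[[term]], adj_dv = adj,
                  split = factor(rows[[split]]))
  present <- table(d$split)
  if (any(present == 0L)) {
    warning("split level(s) without observations: ",
            paste(names(present)[present == 0L], collapse = ", "))
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(x = x, y = adj_dv, colour = split)) +
    ggplot2::geom_point(alpha = 0.15, size = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE) +
    ggplot2::labs(x = term, y = "viewing time, random effects removed (ms)",
                  colour = split) +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 7, height = 5, dpi = 150)
    return(invisible(p))
  }
  p
}

#' Dependent variable with random intercepts removed
#'
#' @param fit an `lmm_result`.
#' @param rows the data the model was fitted on.
#' @return numeric vector: `dv` minus the predicted participant and word
#'   random intercepts.
#' @export
adjusted_dv <- function(fit, rows) {
  re <- lme4::ranef(fit$model)
  u_p <- stats::setNames(re$participant_id[, 1L], rownames(re$participant_id))
  u_w <- stats::setNames(re$token_id[, 1L], rownames(re$token_id))
  rows$dv - unname(u_p[as.character(rows$participant_id)]) -
    unname(u_w[as.character(rows$token_id)])
}
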