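# End-to-end orchestration: align -> fields -> QSAR -> hypothesis -> screen
# -> metrics -> predict-hits, behind a single configuration list (or YAML
# file) with per-stage error reporting.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

# small FNV-1a hash so every artifact can embed a config fingerprint
.config_hash <- function(config) {
  s <- utf8ToInt(paste(utils::capture.output(utils::str(config)), collapse = "\n"))
  h <- 216613626
  for (b in s) h <- (bitwXor(h, b) * 16777619) %% 268435456 # 28-bit FNV-style
  sprintf("%07x", h)
}

#' Default pipeline configuration
#'
#' @param out_dir output directory (created if needed).
#' @param seed global seed, recorded into every artifact.
#' @param ... overrides merged over the defaults.
#' @return nested configuration list.
#' @export
pipeline_config <- function(out_dir = tempfile("qsarpharm_"), seed = 1L, ...) {
  cfg <- list(
    out_dir = out_dir, seed = seed,
    molecules = NULL, activities = NULL, template = NULL,
    synthetic = list(n_molecules = 44L, noise_sd = 0.15),
    rmsd_cutoff = 2.0, train_fraction = 0.85,
    grid = list(spacing = 2.0, margin = 4.0),
    variance_cutoff = 1.0,
    qsar = list(max_terms = 4L, min_q2_gain = 0.001, n_latent_max = 5L,
                n_perm = 100L),
    screen = list(must_match = 4L, fitness_threshold = 1.0, tol = 2.0,
                  library = NULL, active_ids = NULL,
                  n_actives = 100L, n_decoys = 900L, jitter_sd = 0.3))
  dots <- list(...)
  for (n in names(dots))
    cfg[[n]] <- if (is.list(dots[[n]]) && is.list(cfg[[n]]))
      utils::modifyList(cfg[[n]], dots[[n]]) else dots[[n]]
  cfg
}

#' Run the QSAR arm of the pipeline
#'
#' Align -> cull -> grid -> descriptors -> variance filter -> split ->
#' stepwise-PLS fit -> validation, writing all intermediates under
#' `config$out_dir`. With `config$molecules`/`config$activities` unset the
#' synthetic series generator supplies the input.
#'
#' @param config list from [pipeline_config()] or a YAML path.
#' @return list with `model` (a `qsar`), `split`, `descriptors`, `grid`,
#'   `molecules` and (synthetic mode) `truth`.
#' @export
run_qsar <- function(config = pipeline_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- NULL
  if (is.null(config$molecules)) {
    gen <- .stage("synthetic", do.call(generate_series,
      c(config$synthetic, list(seed = config$seed,
                               spacing = config$grid$spacing,
                               margin = config$grid$margin))))
    mols <- gen$molecules; acts <- gen$activities
    X <- gen$descriptors; grid <- gen$grid; truth <- gen$truth
  } else {
    mols <- .stage("molecules", read_molecules(config$molecules))
    acts <- .stage("activities", {
      if (is.null(config$activities)) stop("no activity file configured")
      read_activities(config$activities)
    })
    mols <- .stage("alignment", {
      if (is.null(config$template)) stop("no alignment template configured")
      align_series(mols, config$template)
    })
    mols <- .stage("culling", cull_by_rmsd(mols, config$rmsd_cutoff))
    keep <- vapply(mols, `[[`, character(1), "id")
    acts <- acts[acts$molecule_id %in% keep, , drop = FALSE]
    mols <- .stage("charges", lapply(mols, assign_partial_charges))
    grid <- .stage("grid", build_grid(mols, margin = config$grid$margin,
                                      spacing = config$grid$spacing))
    X <- .stage("descriptors", compute_descriptor_matrix(mols, grid))
  }
  split <- .stage("split", split_train_test(acts, config$train_fraction,
                                            config$seed))
  Xf <- .stage("variance_filter",
               drop_invariant_columns(X, config$variance_cutoff,
                                      train_ids = split$train$molecule_id))
  fit <- .stage("qsar_fit", qsar(
    Xf[split$train$molecule_id, , drop = FALSE],
    stats::setNames(split$train$pIC50, split$train$molecule_id),
    x_test = Xf[split$test$molecule_id, , drop = FALSE],
    y_test = stats::setNames(split$test$pIC50, split$test$molecule_id),
    max_terms = config$qsar$max_terms,
    min_q2_gain = config$qsar$min_q2_gain,
    n_latent_max = config$qsar$n_latent_max,
    n_perm = config$qsar$n_perm, seed = config$seed))
  fit$grid <- grid

  out <- config$out_dir
  meta <- list(config_hash = .config_hash(config), seed = config$seed)
  .stage("artifacts", {
    write_molecules(mols, file.path(out, "aligned.sdf"))
    write_descriptors(Xf, file.path(out, "descriptors.csv"))
    save_qsar(fit, file.path(out, "model.yaml"))
    write_fitness_table(fit, file.path(out, "fitness_plot.csv"))
    utils::write.csv(data.frame(
      subset = c("train", "test"),
      do.call(rbind, lapply(list(split$train$pIC50, split$test$pIC50),
        function(v) as.data.frame(unclass(unicolumn_stats(v)))))),
      file.path(out, "unicolumn_stats.csv"), row.names = FALSE)
    yaml::write_yaml(c(meta, list(timestamp = format(Sys.time()))),
                     file.path(out, "run_manifest.yaml"))
  })
  list(model = fit, split = split, descriptors = Xf, grid = grid,
       molecules = mols, truth = truth, meta = meta)
}

#' Run the screening arm of the pipeline
#'
#' Screen -> confusion counts -> EF/GH/ROC -> per-hit QSAR prediction ->
#' re-rank by predicted activity. Hits are carried into the model frame by
#' their pharmacophore alignment before descriptor evaluation.
#'
#' @param config list from [pipeline_config()] or YAML path.
#' @param model fitted `qsar` (with a `grid`) for hit-activity prediction;
#'   `NULL` skips prediction.
#' @param hypothesis scored `pharmacophore_hypothesis`; `NULL` uses the
#'   planted default of the synthetic library.
#' @return list with `result` (`screen_result` + prediction column),
#'   `counts`, `metrics` (EF, GH, Se, Sp), `roc`.
#' @export
run_screen <- function(config = pipeline_config(), model = NULL,
                       hypothesis = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  sc <- config$screen
  if (is.null(sc$library)) {
    gen <- .stage("library", generate_screening_library(
      n_actives = sc$n_actives, n_decoys = sc$n_decoys,
      hypothesis = hypothesis, jitter_sd = sc$jitter_sd, seed = config$seed))
    library <- gen$library; active_ids <- gen$active_ids
    hypothesis <- gen$hypothesis
  } else {
    library <- .stage("library", read_molecules(sc$library))
    active_ids <- .stage("actives", as.character(
      if (length(sc$active_ids) == 1L && file.exists(sc$active_ids))
        readLines(sc$active_ids) else sc$active_ids))
    if (is.null(hypothesis)) stop("a hypothesis is required with a file library")
  }
  kinds_lib <- unique(unlist(lapply(library, function(m) perceive_features(m)$kind)))
  if (!any(hypothesis$sites$kind %in% kinds_lib)) {
    warning("library shares no feature kinds with the hypothesis; empty hit list")
    library <- list()
  }
  res <- .stage("screen", screen_library(
    library, hypothesis, must_match = sc$must_match,
    threshold = sc$fitness_threshold, tol = sc$tol))
  lib_ids <- vapply(library, `[[`, character(1), "id")
  counts <- if (length(lib_ids))
    confusion_counts(res$id[res$hit], intersect(active_ids, lib_ids), lib_ids)
  else screen_counts(0, 0, 0, 0)
  metrics <- list(
    EF = if (counts$Ht > 0 && counts$A > 0) enrichment_factor(counts) else NA_real_,
    GH = if (counts$Ht > 0 && counts$A > 0) gh_score(counts) else NA_real_,
    Se = if (counts$A > 0) sensitivity(counts$TP, counts$FN) else NA_real_,
    Sp = if (counts$D - counts$A > 0) specificity(counts$TN, counts$FP) else NA_real_)
  score <- ifelse(res$matched, res$fitness, 0)
  is_act <- res$id %in% active_ids
  roc <- if (any(is_act) && any(!is_act))
    roc_curve(score[is_act], score[!is_act]) else NULL

  # predicted activity of hits through the QSAR model
  mf <- attr(res, "match_file"); thr <- attr(res, "threshold")
  res$predicted_pIC50 <- NA_real_
  if (!is.null(model) && !is.null(model$grid) && any(res$hit)) {
    idx <- match(res$id[res$hit], lib_ids)
    preds <- vapply(idx, function(i) {
      m <- library[[i]]
      mm <- match_molecule(m, hypothesis, must_match = sc$must_match,
                           tol = sc$tol)
      if (!mm$matched) return(NA_real_)
      al <- mol_transform(m, mm$rotation, mm$translation)
      al <- tryCatch(assign_partial_charges(al), error = function(e) al)
      al$rmsd <- mm$rmsd
      row <- compute_descriptor_matrix(list(al), model$grid)
      as.numeric(predict(model, row))
    }, numeric(1))
    res$predicted_pIC50[res$hit] <- preds
    ord <- order(-ifelse(is.na(res$predicted_pIC50), -Inf, res$predicted_pIC50),
                 -ifelse(is.na(res$fitness), -Inf, res$fitness), res$id)
    res <- res[ord, ]
  }
  attr(res, "match_file") <- mf; attr(res, "threshold") <- thr
  class(res) <- c("screen_result", "data.frame")

  out <- config$out_dir
  .stage("artifacts", {
    utils::write.csv(as.data.frame(res), file.path(out, "hits.csv"),
                     row.names = FALSE)
    write_match_file(res, file.path(out, "match_file.tsv"))
    yaml::write_yaml(list(counts = unclass(counts)[c("D", "A", "Ht", "Ha",
                                                     "TP", "FN", "FP", "TN")],
                          metrics = metrics,
                          auc = if (!is.null(roc)) roc_auc(roc) else NULL,
                          config_hash = .config_hash(config),
                          seed = config$seed),
                     file.path(out, "screen_metrics.yaml"))
    if (!is.null(roc))
      utils::write.csv(as.data.frame(roc), file.path(out, "roc_points.csv"),
                       row.names = FALSE)
  })
  list(result = res, counts = counts, metrics = metrics, roc = roc,
       hypothesis = hypothesis)
}
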