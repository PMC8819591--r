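#' Run the full classification pipeline
#'
#' Executes the stages in order: read and canonicalize the two FASTA inputs,
#' extract the reduced-dipeptide + ACC feature matrix, rank features by
#' MRMD, select the smallest near-optimal ranking prefix, greedily eliminate
#' down to a minimal subset (default 2 features), cross-validate the final
#' model, and export the two-feature scatter with a fitted threshold rule.
#' All randomness (fold shuffles, forest training) derives from `seed`.
#'
#' @param pos_fasta,neg_fasta FASTA files of positive / negative sequences.
#' @param out_dir Optional directory; when given, artifacts `features.tsv`,
#'   `ranking.tsv`, `trajectory.tsv`, `cv_report.tsv` and `scatter.tsv` are
#'   written there.
#' @param scheme Reduction scheme.
#' @param features Optional character vector of feature names (aliases
#'   accepted): skips selection/elimination and evaluates exactly these.
#' @param model `"tree"` or `"forest"`.
#' @param folds Cross-validation folds.
#' @param seed Master seed.
#' @param k_max,select_tolerance Passed to [select_subset()].
#' @param min_features Size of the final subset [backward_eliminate()] runs
#'   down to (the elimination accepts any accuracy drop, mirroring the push
#'   to a minimal interpretable model).
#' @param n_trees,min_leaf Model parameters.
#' @return List with `feature_matrix`, `ranking`, `selection`,
#'   `elimination`, `final_features`, `cv`, `scatter`, `rule`, `seed`.
#' @export
run_pipeline <- function(pos_fasta, neg_fasta, out_dir = NULL,
                         scheme = default_scheme(), features = NULL,
                         model = c("tree", "forest"), folds = 10L, seed = 1L,
                         k_max = 30L, select_tolerance = 0.005,
                         min_features = 2L, n_trees = 100L, min_leaf = 2L) {
  model <- match.arg(model)
  scheme <- as_scheme(scheme)
  records <- read_labeled_fasta(pos_fasta, neg_fasta)
  run_pipeline_records(records, out_dir = out_dir, scheme = scheme,
                       features = features, model = model, folds = folds,
                       seed = seed, k_max = k_max,
                       select_tolerance = select_tolerance,
                       min_features = min_features, n_trees = n_trees,
                       min_leaf = min_leaf)
}

#' Run the pipeline on an in-memory record set
#'
#' Same stages as [run_pipeline()] but starting from a labeled record data
#' frame (e.g. from [generate_dataset()]).
#'
#' @param records Data frame with columns `id`, `seq`, `label`.
#' @inheritParams run_pipeline
#' @export
run_pipeline_records <- function(records, out_dir = NULL,
                                 scheme = default_scheme(), features = NULL,
                                 model = c("tree", "forest"), folds = 10L,
                                 seed = 1L, k_max = 30L,
                                 select_tolerance = 0.005,
                                 min_features = 2L, n_trees = 100L,
                                 min_leaf = 2L) {
  model <- match.arg(model)
  scheme <- as_scheme(scheme)
  fm <- extract_feature_matrix(records, scheme)
  model_spec <- if (model == "tree") {
    list(type = "tree", min_leaf = min_leaf)
  } else {
    list(type = "forest", n_trees = n_trees, min_leaf = 1L)
  }
  evaluator <- cv_evaluator(model_spec, k = folds, seed = seed)
  ranking <- mrmd_rank(fm)
  if (!is.null(features)) {
    canon <- vapply(features, function(f) {
      if (f %in% colnames(fm$values)) f else parse_dipeptide(f)$canonical
    }, character(1), USE.NAMES = FALSE)
    final_features <- canon
    selection <- NULL
    elimination <- NULL
  } else {
    k_max <- min(k_max, ncol(fm$values))
    selection <- select_subset(fm, ranking, evaluator, k_max = k_max,
                               tolerance = select_tolerance)
    elimination <- backward_eliminate(fm_subset(fm, selection$features),
                                      evaluator,
                                      min_features = min_features,
                                      tolerance = Inf, ranking = ranking)
    final_features <- elimination$features
  }
  cv <- cross_validate(fm_subset(fm, final_features), model_spec,
                       k = folds, seed = seed)
  dip_feats <- final_features[grepl("^[A-Z]\\**[A-Z]$", final_features)]
  if (length(dip_feats) >= 2L) {
    scat_feats <- dip_feats[1:2]
  } else {
    scat_feats <- c("F*C", "G*C")
  }
  scatter <- scatter_table(records, scheme, scat_feats[1], scat_feats[2])
  rule <- fit_rule(scatter)
  result <- list(feature_matrix = fm, ranking = ranking,
                 selection = selection, elimination = elimination,
                 final_features = final_features, cv = cv,
                 scatter = scatter, rule = rule, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_feature_tsv(fm, file.path(out_dir, "features.tsv"))
    utils::write.table(as.data.frame(ranking),
                       file.path(out_dir, "ranking.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    traj <- rbind(
      if (!is.null(selection)) {
        data.frame(stage = "select", step = selection$trajectory$k,
                   feature = selection$trajectory$feature_added,
                   n_features = selection$trajectory$k,
                   accuracy = selection$trajectory$accuracy,
                   stringsAsFactors = FALSE)
      },
      if (!is.null(elimination)) {
        data.frame(stage = "eliminate", step = elimination$trajectory$step,
                   feature = elimination$trajectory$removed_feature,
                   n_features = elimination$trajectory$n_features,
                   accuracy = elimination$trajectory$accuracy,
                   stringsAsFactors = FALSE)
      })
    if (!is.null(traj)) {
      utils::write.table(traj, file.path(out_dir, "trajectory.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      utils::write.table(
        data.frame(stage = "fixed", step = 0L,
                   feature = paste(final_features, collapse = ","),
                   n_features = length(final_features),
                   accuracy = unname(cv$metrics["accuracy"])),
        file.path(out_dir, "trajectory.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_cv_tsv(cv, file.path(out_dir, "cv_report.tsv"))
    utils::write.table(scatter, file.path(out_dir, "scatter.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  result
}
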