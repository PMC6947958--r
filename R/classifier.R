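#' Construct an episignature object
#'
#' Bundles the selected signature probes with the group mean betas and
#' selection provenance. Because classifier inputs may come from either
#' array generation, the probe set is restricted to probes present on both
#' dialects (`on_450k & on_epic` in the manifest).
#'
#' @param dmps Significant-probe table (from [select_dmps()]`$table` or
#'   equivalent, with `probe_id`).
#' @param beta Probe x sample beta matrix of the discovery cohort.
#' @param case_ids,control_ids Discovery sample ids.
#' @param manifest Probe manifest with `on_450k`/`on_epic` flags.
#' @param provenance Optional list of thresholds/cohort metadata to store.
#' @return Object of class `episignature`: `probe_ids`, `case_mean`,
#'   `control_mean`, `provenance`.
#' @export
create_episignature <- function(dmps, beta, case_ids, control_ids, manifest,
                                provenance = list()) {
  shared <- manifest$probe_id[manifest$on_450k & manifest$on_epic]
  probes <- intersect(dmps$probe_id, shared)
  probes <- intersect(probes, rownames(beta))
  if (length(probes) == 0)
    stop("no signature probes shared by both array dialects")
  structure(
    list(probe_ids = probes,
         case_mean = rowMeans(beta[probes, case_ids, drop = FALSE]),
         control_mean = rowMeans(beta[probes, control_ids, drop = FALSE]),
         provenance = provenance),
    class = "episignature")
}

#' Build a classifier feature matrix from betas
#'
#' Extracts the samples x signature-probes beta matrix. Probes absent from
#' the input (or `NA` in a sample) are imputed with the discovery-control
#' mean, with a warning; more than `max_missing` missing signature probes is
#' an error, since scores from a mostly-imputed profile are meaningless.
#'
#' @param beta Probe x sample beta matrix to score.
#' @param signature An [create_episignature()] object.
#' @param max_missing Maximum tolerated fraction of missing signature probes
#'   (default 0.05).
#' @return Samples x probes numeric matrix, columns in signature order.
#' @export
build_features <- function(beta, signature, max_missing = 0.05) {
  probes <- signature$probe_ids
  missing <- setdiff(probes, rownames(beta))
  if (length(missing) / length(probes) > max_missing)
    stop(sprintf("%d of %d signature probes missing (> %.0f%%): %s ...",
                 length(missing), length(probes), 100 * max_missing,
                 paste(utils::head(missing, 5), collapse = ", ")))
  X <- matrix(NA_real_, ncol(beta), length(probes),
              dimnames = list(colnames(beta), probes))
  present <- intersect(probes, rownames(beta))
  X[, present] <- t(beta[present, , drop = FALSE])
  if (length(missing)) {
    warning(length(missing), " missing signature probe(s) imputed with ",
            "control means")
    X[, missing] <- rep(signature$control_mean[missing], each = nrow(X))
  }
  na_frac <- rowMeans(is.na(X))
  if (any(na_frac > max_missing))
    stop("samples with > ", 100 * max_missing, "% missing signature values: ",
         paste(rownames(X)[na_frac > max_missing], collapse = ", "))
  if (anyNA(X)) {
    nai <- which(is.na(X), arr.ind = TRUE)
    X[nai] <- signature$control_mean[colnames(X)[nai[, 2]]]
  }
  X
}

# deterministic stratified fold assignment
.stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Train the episignature random-forest classifier
#'
#' Trains a random forest on signature-probe betas with stratified k-fold
#' cross-validation over an `mtry` grid; the final model is refit on all
#' samples at the best `mtry` (ties go to the smallest value, keeping trees
#' more decorrelated). The model is then applied back to its own training
#' samples as a success check, and those scores are stored.
#'
#' @param features Samples x probes matrix from [build_features()].
#' @param labels `"case"`/`"control"` per sample.
#' @param n_trees Trees in the forest (default 500).
#' @param cv_folds Cross-validation folds (default 10).
#' @param mtry_grid Candidate `mtry` values; default brackets the
#'   conventional floor(sqrt(p)): half, exact, double.
#' @param seed Integer seed (mandatory: fold assignment and tree growing are
#'   stochastic).
#' @return Object of class `rf_model`: `forest` (randomForest fit), `mtry`,
#'   `cv_results` (accuracy per mtry), `n_trees`, `feature_probes`,
#'   `training_samples`, `training_scores`, `seed`.
#' @export
train_rf <- function(features, labels, n_trees = 500, cv_folds = 10,
                     mtry_grid = NULL, seed) {
  if (missing(seed)) stop("seed is required")
  labels <- factor(labels, levels = c("control", "case"))
  if (any(is.na(labels))) stop('labels must be "case" or "control"')
  if (nlevels(droplevels(labels)) < 2)
    stop("both classes must be present in the training labels")
  p <- ncol(features)
  if (is.null(mtry_grid)) {
    s <- max(1L, floor(sqrt(p)))
    mtry_grid <- sort(unique(pmin(p, pmax(1L, c(floor(s / 2), s, 2L * s)))))
  }
  set.seed(as.integer(seed))
  fold <- .stratified_folds(labels, cv_folds)
  cv <- data.frame(mtry = mtry_grid, accuracy = NA_real_)
  for (gi in seq_along(mtry_grid)) {
    correct <- 0L; total <- 0L
    for (f in seq_len(cv_folds)) {
      test <- fold == f
      if (!any(test)) next
      if (nlevels(droplevels(labels[!test])) < 2) next
      rf <- randomForest::randomForest(features[!test, , drop = FALSE],
                                       labels[!test], ntree = n_trees,
                                       mtry = mtry_grid[gi])
      pred <- stats::predict(rf, features[test, , drop = FALSE])
      correct <- correct + sum(pred == labels[test])
      total <- total + sum(test)
    }
    cv$accuracy[gi] <- correct / total
  }
  best <- cv$mtry[which.max(cv$accuracy)]   # ties -> smallest (grid sorted)
  forest <- randomForest::randomForest(features, labels, ntree = n_trees,
                                       mtry = best)
  model <- structure(
    list(forest = forest, mtry = best, cv_results = cv, n_trees = n_trees,
         feature_probes = colnames(features),
         training_samples = rownames(features), seed = as.integer(seed)),
    class = "rf_model")
  model$training_scores <- score_samples(model, features)
  model
}

#' Score samples with the episignature classifier
#'
#' The confidence score of a sample is the fraction of trees voting for the
#' case class, in \[0, 1\]; the class call applies the 0.5 cutoff.
#'
#' @param model An [train_rf()] `rf_model`.
#' @param features Samples x probes matrix whose columns match the model's
#'   `feature_probes` (error otherwise).
#' @param cutoff Score cutoff for the class call (default 0.5).
#' @return data.frame of class `score_report`: `sample_id`, `score`, `call`
#'   (logical, `score > cutoff`).
#' @export
score_samples <- function(model, features, cutoff = 0.5) {
  if (!identical(colnames(features), model$feature_probes))
    stop("feature columns do not match the trained model")
  votes <- stats::predict(model$forest, features, type = "vote",
                          norm.votes = TRUE)
  score <- votes[, "case"]
  structure(data.frame(sample_id = rownames(features), score = unname(score),
                       call = unname(score > cutoff), stringsAsFactors = FALSE),
            class = c("score_report", "data.frame"))
}

#' Run the classifier specificity battery
#'
#' Scores a collection of tagged cohorts (healthy populations, isolated cell
#' types, other-syndrome carriers, unresolved screens) and summarises score
#' distributions per cohort. Feature-building errors in one cohort are
#' recorded and do not stop the others.
#'
#' @param model An `rf_model`.
#' @param cohorts Named list of probe x sample beta matrices.
#' @param signature The [create_episignature()] object used for features.
#' @param cutoff Class-call cutoff (default 0.5).
#' @return List: `scores` (long data.frame `cohort`, `sample_id`, `score`,
#'   `call`), `summary` (per cohort: n, max/mean/sd score, n_positive),
#'   `errors` (named character vector of failed cohorts).
#' @export
specificity_battery <- function(model, cohorts, signature, cutoff = 0.5) {
  stopifnot(is.list(cohorts), !is.null(names(cohorts)))
  scores <- list(); errors <- character(0)
  for (tag in names(cohorts)) {
    res <- tryCatch({
      f <- build_features(cohorts[[tag]], signature)
      cbind(cohort = tag, score_samples(model, f, cutoff))
    }, error = function(e) e)
    if (inherits(res, "error")) errors[tag] <- conditionMessage(res)
    else scores[[tag]] <- res
  }
  long <- do.call(rbind, scores)
  rownames(long) <- NULL
  summary <- do.call(rbind, lapply(split(long, long$cohort), function(d)
    data.frame(cohort = d$cohort[1], n = nrow(d),
               max_score = max(d$score), mean_score = mean(d$score),
               sd_score = stats::sd(d$score), n_positive = sum(d$call),
               stringsAsFactors = FALSE)))
  rownames(summary) <- NULL
  list(scores = long, summary = summary, errors = errors)
}
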