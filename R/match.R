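#' Select age- and sex-matched controls for each case
#'
#' Greedy nearest-neighbour matching: cases are processed in input order and
#' each receives its `ratio` nearest-age controls of the same sex, sampled
#' without replacement across cases. Age ties are broken by smallest sample
#' id, which makes the result deterministic.
#'
#' @param cases,pool Sample sheets (data.frames with `sample_id`, `sex`,
#'   `age_years`); `pool` is the candidate-control database.
#' @param ratio Controls per case (default 10).
#' @return An object of class `match_result`: list with `case_ids`,
#'   `controls` (named list, case id -> control ids), `control_ids` (all
#'   selected controls), `iterations`, `removed` (outliers removed per
#'   iteration; empty here).
#' @export
match_controls <- function(cases, pool, ratio = 10) {
  stopifnot(ratio >= 1, !anyDuplicated(pool$sample_id),
            !anyDuplicated(cases$sample_id))
  available <- rep(TRUE, nrow(pool))
  controls <- vector("list", nrow(cases))
  names(controls) <- cases$sample_id
  for (i in seq_len(nrow(cases))) {
    cand <- which(available & pool$sex == cases$sex[i])
    if (length(cand) < ratio)
      stop(sprintf(
        "case %s: only %d same-sex candidate controls available (need %d)",
        cases$sample_id[i], length(cand), ratio))
    o <- order(abs(pool$age_years[cand] - cases$age_years[i]),
               pool$sample_id[cand])
    sel <- cand[o[seq_len(ratio)]]
    controls[[i]] <- pool$sample_id[sel]
    available[sel] <- FALSE
  }
  structure(list(case_ids = cases$sample_id, controls = controls,
                 control_ids = unlist(controls, use.names = FALSE),
                 iterations = 1L, removed = list()),
            class = "match_result")
}

#' Iterative matching with PCA outlier removal
#'
#' Repeats: match controls, run [pca_outliers()] on the cases-plus-matched
#' beta matrix, remove flagged controls from the candidate pool, rematch —
#' until no sample is flagged on the first two principal components (or
#' `max_iter` is hit, which errors). A flagged *case* aborts with
#' diagnostics: with a handful of cases, silently dropping one would change
#' the signature being discovered.
#'
#' @inheritParams match_controls
#' @param beta Probe x sample beta matrix covering cases and pool.
#' @param k_sd Robust-SD threshold passed to [pca_outliers()].
#' @param max_iter Maximum matching iterations (default 20).
#' @return A `match_result` whose final matched set produces zero PCA flags;
#'   `removed` records the controls excluded at each iteration.
#' @export
iterative_match <- function(cases, pool, beta, ratio = 10, k_sd = 3,
                            max_iter = 20) {
  missing_ids <- setdiff(c(cases$sample_id, pool$sample_id), colnames(beta))
  if (length(missing_ids))
    stop("beta matrix lacks samples: ",
         paste(utils::head(missing_ids), collapse = ", "))
  removed <- list()
  for (iter in seq_len(max_iter)) {
    m <- match_controls(cases, pool, ratio)
    ids <- c(cases$sample_id, m$control_ids)
    flagged <- pca_outliers(beta[, ids, drop = FALSE], k_sd = k_sd)
    if (length(flagged) == 0) {
      m$iterations <- iter
      m$removed <- removed
      return(m)
    }
    bad_cases <- intersect(flagged, cases$sample_id)
    if (length(bad_cases))
      stop("case sample(s) flagged as PCA outliers: ",
           paste(bad_cases, collapse = ", "),
           " — inspect the input data before matching")
    removed[[iter]] <- flagged
    pool <- pool[!pool$sample_id %in% flagged, , drop = FALSE]
  }
  stop(sprintf("matching did not converge within %d iterations", max_iter))
}
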