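#' End-to-end episignature discovery
#'
#' Chains the full discovery pipeline on a cohort: array-level QC (failed
#' arrays), probe-level QC filters, iterative age/sex-matched control
#' selection with PCA outlier removal, cell-composition-adjusted
#' differential-probe analysis on the matched set, dual-threshold probe
#' selection, region calling, and construction of the cross-dialect
#' episignature object.
#'
#' @param beta Probe x sample beta matrix (cases plus control pool).
#' @param detp Detection p-value matrix aligned with `beta`, or `NULL`.
#' @param manifest Probe manifest.
#' @param sheet Sample sheet (`sample_id`, `group`, `age_years`, `sex`, ...);
#'   cases are rows with `group == "case"`.
#' @param reference Cell-type reference for composition adjustment, or
#'   `NULL` to skip adjustment.
#' @param ratio Matched controls per case (default 10).
#' @param k_sd PCA outlier threshold (default 3).
#' @param q_max,delta_min Probe significance thresholds (defaults 0.01,
#'   0.10).
#' @param dmr_args Extra arguments passed to [call_regions()].
#' @return List of class `discovery_result`: `qc` (probe filter report),
#'   `match` (`match_result`), `dmp` (`dmp_result`), `dmps` (selected
#'   probes + direction counts), `dmr` (`dmr_table`), `signature`
#'   (`episignature`), `sample_ids` (cases, matched controls).
#' @export
discover_episignature <- function(beta, detp, manifest, sheet, reference,
                                  ratio = 10, k_sd = 3, q_max = 0.01,
                                  delta_min = 0.10, dmr_args = list()) {
  # array-level QC first: a bad array should not doom probes
  if (!is.null(detp)) {
    arr <- filter_failed_arrays(detp)
    beta <- beta[, arr$retained, drop = FALSE]
    detp <- detp[, arr$retained, drop = FALSE]
    sheet <- sheet[sheet$sample_id %in% arr$retained, , drop = FALSE]
  }
  qc <- filter_probes(beta, detp, manifest)
  beta <- qc$beta

  cases <- sheet[sheet$group == "case", , drop = FALSE]
  pool <- sheet[sheet$group != "case", , drop = FALSE]
  if (nrow(cases) == 0) stop('sheet contains no "case" samples')
  m <- iterative_match(cases, pool, beta, ratio = ratio, k_sd = k_sd)

  ids <- c(m$case_ids, m$control_ids)
  groups <- rep(c("case", "control"),
                c(length(m$case_ids), length(m$control_ids)))
  dmp <- dmp_analysis(beta[, ids, drop = FALSE], groups,
                      reference = reference)
  dmps <- select_dmps(dmp, q_max = q_max, delta_min = delta_min)
  dmr <- do.call(call_regions, c(list(dmp = dmp, manifest = manifest),
                                 dmr_args))
  signature <- if (nrow(dmps$table) == 0) NULL else create_episignature(
    dmps$table, beta, m$case_ids, m$control_ids, manifest,
    provenance = list(q_max = q_max, delta_min = delta_min,
                      n_cases = length(m$case_ids),
                      n_controls = length(m$control_ids)))
  structure(list(qc = qc[c("removed", "counts")], match = m, dmp = dmp,
                 dmps = dmps, dmr = dmr, signature = signature,
                 sample_ids = ids),
            class = "discovery_result")
}
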