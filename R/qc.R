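#' Compute beta values from methylated/unmethylated signal intensities
#'
#' The methylation fraction at a probe is the methylated signal over the total
#' signal, `meth / (meth + unmeth)`, in \[0, 1\]. Entries where both signals
#' are zero carry no information and are returned as `NA`.
#'
#' @param meth,unmeth Non-negative numeric vectors or matrices of equal shape.
#' @return Beta values with the shape of the inputs; `NA` where the total
#'   signal is zero.
#' @export
compute_beta <- function(meth, unmeth) {
  if (any(dim(meth) != dim(unmeth)) || length(meth) != length(unmeth))
    stop("meth and unmeth must have the same shape")
  if (any(meth < 0, na.rm = TRUE) || any(unmeth < 0, na.rm = TRUE))
    stop("signal intensities must be non-negative")
  total <- meth + unmeth
  beta <- meth / total
  beta[total == 0] <- NA_real_
  beta
}

#' Probe-level quality-control filtering
#'
#' Removes probes that (i) fail detection (p > `detp_threshold` in any
#' retained sample), (ii) lie on chromosome X or Y, (iii) are flagged as
#' containing a SNP, or (iv) are flagged as cross-reactive. Removal reasons
#' overlap; the retained set is the complement of their union, and per-reason
#' counts are reported so the set algebra can be audited.
#'
#' @param beta Probe x sample beta matrix with probe-id rownames.
#' @param detp Detection p-value matrix aligned with `beta` (or `NULL` to
#'   skip detection filtering).
#' @param manifest Probe manifest with columns `probe_id`, `chrom`, `is_snp`,
#'   `is_crossreactive`; must cover every probe in `beta`.
#' @param detp_threshold Detection p-value above which a probe fails in a
#'   sample (default 0.01).
#' @return A list of class `qc_filter`: `beta` (filtered matrix), `removed`
#'   (per-reason probe-id lists), `counts` (per-reason counts plus
#'   `total_removed` and `retained`).
#' @export
filter_probes <- function(beta, detp, manifest, detp_threshold = 0.01) {
  pid <- rownames(beta)
  if (is.null(pid)) stop("beta must have probe-id rownames")
  mi <- match(pid, manifest$probe_id)
  if (anyNA(mi))
    stop("probes absent from manifest: ",
         paste(utils::head(pid[is.na(mi)]), collapse = ", "))
  man <- manifest[mi, ]

  fail_det <- if (is.null(detp)) rep(FALSE, length(pid)) else {
    stopifnot(all(rownames(detp) == pid))
    rowSums(detp > detp_threshold, na.rm = TRUE) > 0
  }
  sexchr <- man$chrom %in% c("X", "Y", "chrX", "chrY")
  snp <- as.logical(man$is_snp)
  xr <- as.logical(man$is_crossreactive)

  drop <- fail_det | sexchr | snp | xr
  removed <- list(detection = pid[fail_det], sex_chromosome = pid[sexchr],
                  snp = pid[snp], cross_reactive = pid[xr])
  structure(
    list(beta = beta[!drop, , drop = FALSE],
         removed = removed,
         counts = c(vapply(removed, length, 0L),
                    total_removed = sum(drop), retained = sum(!drop))),
    class = "qc_filter")
}

#' Exclude failed arrays
#'
#' An array (sample) is excluded when more than `max_fail_rate` of its probes
#' fail detection (p > `detp_threshold`). A failure rate of exactly the
#' threshold is retained ("more than").
#'
#' @param detp Detection p-value matrix (probes x samples) with sample-id
#'   colnames.
#' @param detp_threshold Per-probe failure threshold (default 0.01).
#' @param max_fail_rate Maximum tolerated failing-probe fraction (default 0.05).
#' @return List with `retained` and `dropped` sample ids and the per-sample
#'   `fail_rate` vector.
#' @export
filter_failed_arrays <- function(detp, detp_threshold = 0.01,
                                 max_fail_rate = 0.05) {
  if (is.null(colnames(detp))) stop("detp must have sample-id colnames")
  fail_rate <- colMeans(detp > detp_threshold, na.rm = TRUE)
  dropped <- colnames(detp)[fail_rate > max_fail_rate]
  list(retained = setdiff(colnames(detp), dropped), dropped = dropped,
       fail_rate = fail_rate)
}

# exact 1-D 2-means (all split points of the sorted values)
.two_means_1d <- function(x) {
  o <- order(x)
  xs <- x[o]
  n <- length(xs)
  best <- NULL; best_ss <- Inf
  for (s in 1:(n - 1)) {
    ss <- sum((xs[1:s] - mean(xs[1:s]))^2) +
          sum((xs[(s + 1):n] - mean(xs[(s + 1):n]))^2)
    if (ss < best_ss) { best_ss <- ss; best <- s }
  }
  cl <- integer(n); cl[o] <- rep(1:2, c(best, n - best))
  centers <- c(mean(xs[1:best]), mean(xs[(best + 1):n]))
  list(cluster = cl, centers = centers)
}

#' Predict sample sex from sex-chromosome signal intensities
#'
#' For each sample, the statistic is the median log2 total intensity over
#' chromosome X probes minus the same over chromosome Y probes; females (two
#' X copies, background-level Y) score high, males low. Samples are split by
#' an exact two-means clustering of the statistic. If the two cluster centres
#' are closer than `min_separation` (e.g. a single-sex cohort), the split
#' falls back to a fixed threshold of 0 with a warning.
#'
#' @param meth,unmeth Signal matrices (probes x samples) with probe rownames.
#' @param manifest Probe manifest with `probe_id` and `chrom`.
#' @param sheet Optional sample sheet with `sample_id` and `sex` to check
#'   label concordance.
#' @param min_separation Minimum log2 distance between cluster centres for the
#'   clustering to be trusted (default 2).
#' @return List with `prediction` (data.frame `sample_id`, `xy_stat`,
#'   `predicted_sex`) and `discordant` (sample ids whose label disagrees, if
#'   `sheet` given).
#' @export
predict_sex <- function(meth, unmeth, manifest, sheet = NULL,
                        min_separation = 2) {
  pid <- rownames(meth)
  mi <- match(pid, manifest$probe_id)
  if (anyNA(mi)) stop("probes absent from manifest")
  chrom <- manifest$chrom[mi]
  xi <- chrom %in% c("X", "chrX")
  yi <- chrom %in% c("Y", "chrY")
  if (!any(xi) || !any(yi))
    stop("manifest contains no chromosome X/Y probes")
  lt <- log2(meth + unmeth + 1)
  stat <- apply(lt[xi, , drop = FALSE], 2, stats::median) -
          apply(lt[yi, , drop = FALSE], 2, stats::median)

  if (length(stat) >= 2) {
    km <- .two_means_1d(stat)
    if (abs(diff(km$centers)) >= min_separation) {
      f_cluster <- which.max(km$centers)
      sex <- ifelse(km$cluster == f_cluster, "F", "M")
    } else {
      warning("sex clusters poorly separated; falling back to fixed threshold 0")
      sex <- ifelse(stat > 0, "F", "M")
    }
  } else {
    sex <- ifelse(stat > 0, "F", "M")
  }
  pred <- data.frame(sample_id = colnames(meth), xy_stat = unname(stat),
                     predicted_sex = unname(sex), stringsAsFactors = FALSE)
  discordant <- character(0)
  if (!is.null(sheet)) {
    lab <- sheet$sex[match(pred$sample_id, sheet$sample_id)]
    discordant <- pred$sample_id[!is.na(lab) & lab != pred$predicted_sex]
  }
  list(prediction = pred, discordant = discordant)
}

#' Check per-sample beta-density bimodality
#'
#' Clean methylation arrays have bimodal beta densities (mass near 0 and 1).
#' A sample fails when the fraction of its betas in the mid-range
#' (`mid_range`) exceeds `max_mid_fraction`; a uniform sample has mid-mass
#' 0.40 and fails at the default 0.35.
#'
#' @param beta Probe x sample beta matrix with at least 1000 probes.
#' @param mid_range Open interval counted as mid-range (default (0.3, 0.7)).
#' @param max_mid_fraction Failure threshold on the mid-range mass.
#' @return data.frame with `sample_id`, `mid_fraction`, `pass`.
#' @export
bimodality_check <- function(beta, mid_range = c(0.3, 0.7),
                             max_mid_fraction = 0.35) {
  if (nrow(beta) < 1000)
    stop("bimodality check requires at least 1000 probes")
  mid <- colMeans(beta > mid_range[1] & beta < mid_range[2], na.rm = TRUE)
  data.frame(sample_id = colnames(beta), mid_fraction = unname(mid),
             pass = unname(mid <= max_mid_fraction), stringsAsFactors = FALSE)
}

# sample-space principal component scores (top `rank`), via the sample Gram
# matrix so that 1e5+ probes stay cheap
.pca_scores <- function(beta, rank = 2L) {
  x <- beta[stats::complete.cases(beta), , drop = FALSE]
  xc <- x - rowMeans(x)
  g <- crossprod(xc)                 # samples x samples
  e <- eigen(g, symmetric = TRUE)
  k <- min(rank, ncol(x) - 1L)
  scores <- e$vectors[, seq_len(k), drop = FALSE] *
    rep(sqrt(pmax(e$values[seq_len(k)], 0)), each = ncol(x))
  rownames(scores) <- colnames(beta)
  scores
}

#' Flag PCA outlier samples
#'
#' Projects samples onto the first two principal components of the beta
#' matrix and flags samples deviating from the component median by more than
#' a robust-SD (median absolute deviation) cutoff, on either component.
#'
#' The cutoff is multiplicity-calibrated: testing every sample on two
#' components is `2n` comparisons, so a fixed 3-SD rule would flag roughly
#' one clean sample per cohort of 60-70 by chance alone — and an iterative
#' matching loop that reacts to every flag would churn forever. The actual
#' cutoff is therefore `(k_sd / 3) * qnorm(1 - alpha / (2 * n * 2))` robust
#' SDs, which holds the family-wise false-alarm probability of a clean
#' cohort near `alpha`. `k_sd` keeps its conventional meaning: 3 is the
#' calibrated default, smaller values tighten the rule proportionally, and 0
#' flags every sample.
#'
#' @param beta Probe x sample beta matrix (>= 3 samples).
#' @param k_sd Flagging stringency on the conventional 3-SD scale
#'   (default 3).
#' @param alpha Target family-wise false-alarm probability for a clean
#'   cohort (default 0.01).
#' @return Character vector of flagged sample ids (possibly empty), with the
#'   score matrix attached as attribute `"scores"`.
#' @export
pca_outliers <- function(beta, k_sd = 3, alpha = 0.01) {
  n <- ncol(beta)
  if (n < 3) stop("PCA outlier detection needs at least 3 samples")
  scores <- .pca_scores(beta, 2L)
  q_n <- stats::qnorm(1 - alpha / (2 * n * ncol(scores)))
  cutoff <- k_sd / 3 * q_n
  flagged <- rep(FALSE, n)
  for (j in seq_len(ncol(scores))) {
    s <- scores[, j]
    dev <- abs(s - stats::median(s))
    flagged <- flagged | dev > cutoff * stats::mad(s)
  }
  structure(colnames(beta)[flagged], scores = scores)
}
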