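#' Logit-transform beta values to M values
#'
#' M = log2(beta / (1 - beta)), the scale on which methylation differences
#' are approximately homoscedastic and suitable for linear modelling. Betas
#' are clipped to \[eps, 1 - eps\] first so boundary values stay finite.
#'
#' @param beta Numeric vector/matrix of betas in \[0, 1\].
#' @param eps Clipping margin (default 0.001).
#' @return M values with the shape of the input.
#' @export
beta_to_m <- function(beta, eps = 0.001) {
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' Estimate leukocyte composition by constrained projection
#'
#' Reference-based deconvolution: for each sample, solve the quadratic
#' program minimise ||beta_markers - R w||^2 subject to w >= 0 and
#' sum(w) <= 1, where R holds the reference profiles at the marker probes.
#' This is the constrained-projection formulation used for whole-blood
#' cell-mixture adjustment.
#'
#' @param beta Probe x sample beta matrix containing the marker probes.
#' @param reference A [simulate_reference()]-style object (`profiles`,
#'   `marker_probes`), or any list with those fields.
#' @param markers Marker probe ids to project onto (default: the reference's).
#' @return Samples x cell-type matrix of weights (class `cell_composition`);
#'   rows satisfy w >= 0, sum(w) <= 1.
#' @export
estimate_cell_composition <- function(beta, reference,
                                      markers = reference$marker_probes) {
  usable <- intersect(markers, rownames(beta))
  if (length(usable) < 10)
    stop("fewer than 10 usable marker probes in the beta matrix")
  R <- reference$profiles[usable, , drop = FALSE]
  k <- ncol(R)
  D <- crossprod(R) + diag(1e-9, k)
  # constraints t(A) w >= b0:  w_k >= 0  and  -sum(w) >= -1
  A <- cbind(diag(k), -1)
  b0 <- c(rep(0, k), -1)
  B <- beta[usable, , drop = FALSE]
  W <- matrix(NA_real_, ncol(beta), k,
              dimnames = list(colnames(beta), colnames(R)))
  for (j in seq_len(ncol(B))) {
    y <- B[, j]
    ok <- !is.na(y)
    if (sum(ok) < 10)
      stop("fewer than 10 usable marker probes for sample ", colnames(B)[j])
    Dj <- if (all(ok)) D else crossprod(R[ok, , drop = FALSE]) + diag(1e-9, k)
    dj <- crossprod(R[ok, , drop = FALSE], y[ok])
    W[j, ] <- quadprog::solve.QP(Dj, dj, A, b0)$solution
  }
  W[W < 0] <- 0
  structure(W, class = c("cell_composition", "matrix", "array"))
}

#' Build the case/control design matrix with cell-composition covariates
#'
#' Columns: intercept, group indicator (case = 1), and K - 1 cell-proportion
#' covariates (one type dropped, since proportions near-sum to 1 and would
#' otherwise be collinear with the intercept).
#'
#' @param groups Character/factor vector, `"case"` or `"control"`, one per
#'   sample.
#' @param composition Optional samples x K composition matrix from
#'   [estimate_cell_composition()].
#' @return Design matrix (samples x p), full column rank checked.
#' @export
build_design <- function(groups, composition = NULL) {
  g <- as.integer(groups == "case")
  X <- cbind(intercept = 1, group = g)
  if (!is.null(composition)) {
    stopifnot(nrow(composition) == length(groups))
    X <- cbind(X, composition[, -ncol(composition), drop = FALSE])
  }
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank-deficient")
  X
}

#' Per-probe ordinary least squares
#'
#' Fits the same linear model to every probe of an M-value matrix by matrix
#' algebra (no per-probe loop). Returns, per probe, the coefficient vector,
#' the residual variance `s2` on `df_residual` degrees of freedom, and the
#' unscaled coefficient variances (diagonal of (X'X)^-1), which
#' [ebayes_moderate()] turns into moderated t-statistics.
#'
#' @param M Probe x sample matrix of M values (no missing values).
#' @param design Samples x p design matrix of full column rank.
#' @return List of class `probe_fit`: `coefficients` (probes x p), `s2`,
#'   `df_residual`, `cov_unscaled` (length-p diagonal of (X'X)^-1).
#' @export
fit_probe_models <- function(M, design) {
  n <- ncol(M); p <- ncol(design)
  if (nrow(design) != n) stop("design rows must equal samples")
  if (n < p + 1) stop("need at least p + 1 samples")
  if (qr(design)$rank < p) stop("design matrix is rank-deficient")
  if (anyNA(M)) stop("M contains missing values; drop incomplete probes first")
  xtx_inv <- chol2inv(chol(crossprod(design)))
  dimnames(xtx_inv) <- list(colnames(design), colnames(design))
  B <- M %*% design %*% xtx_inv              # probes x p
  resid <- M - B %*% t(design)
  df <- n - p
  s2 <- rowSums(resid^2) / df
  colnames(B) <- colnames(design)
  structure(list(coefficients = B, s2 = s2, df_residual = df,
                 cov_unscaled = diag(xtx_inv)),
            class = "probe_fit")
}

# Newton inversion of the trigamma function (monotone decreasing on (0, Inf))
.trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Empirical-Bayes moderation of per-probe variances
#'
#' Fits the scaled inverse-chi-square prior s2_g ~ s0^2 F(df_g, d0) to the
#' observed residual variances by the method of moments on log s2 (matching
#' the closed-form digamma/trigamma estimators of the moderated-t
#' framework), then forms posterior variances
#' s2_post = (d0 s0^2 + df s2) / (d0 + df) and, when coefficients are
#' supplied, moderated t-statistics on d0 + df degrees of freedom with
#' two-sided p-values.
#'
#' @param s2 Per-probe residual variances (>= 100 probes for a stable prior
#'   fit).
#' @param df Residual degrees of freedom (scalar or per-probe).
#' @param coef Optional per-probe coefficient (the contrast of interest).
#' @param unscaled_var Optional unscaled variance of that coefficient (the
#'   corresponding diagonal entry of (X'X)^-1).
#' @param d0_override Force a prior df value (used to probe the d0 -> 0 /
#'   d0 -> Inf limits); skips the moment fit.
#' @return List: `d0`, `s02`, `s2_post`, and when `coef` is given `t`, `p`,
#'   `df_total`.
#' @export
ebayes_moderate <- function(s2, df, coef = NULL, unscaled_var = NULL,
                            d0_override = NULL) {
  if (any(!is.finite(s2))) stop("non-finite residual variances")
  if (is.null(d0_override) && length(s2) < 100)
    stop("need at least 100 probes to estimate the variance prior")
  df <- rep_len(df, length(s2))
  z <- log(pmax(s2, 1e-300))
  e <- z - digamma(df / 2) + log(df / 2)
  if (!is.null(d0_override)) {
    d0 <- d0_override
    s02 <- if (is.finite(d0) && d0 > 0)
      exp(mean(e) + digamma(d0 / 2) - log(d0 / 2)) else exp(mean(z))
  } else {
    n <- length(e)
    evar <- mean((e - mean(e))^2) * n / (n - 1) - mean(trigamma(df / 2))
    if (is.finite(evar) && evar > 0) {
      d0 <- 2 * .trigamma_inverse(evar)
      s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    } else {
      # no excess dispersion beyond chi-square sampling noise: take the
      # variances at face value (geometric mean), infinite prior df
      d0 <- Inf
      s02 <- exp(mean(z))
    }
  }
  s2_post <- if (is.infinite(d0)) rep_len(s02, length(s2))
             else (d0 * s02 + df * s2) / (d0 + df)
  out <- list(d0 = d0, s02 = s02, s2_post = s2_post)
  if (!is.null(coef)) {
    stopifnot(!is.null(unscaled_var))
    out$t <- coef / sqrt(s2_post * unscaled_var)
    out$df_total <- df + d0
    out$p <- 2 * stats::pt(-abs(out$t), df = out$df_total)
  }
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, q_(i) = min_(j >= i)
#' p_(j) m / j capped at 1, returned in input order (delegates to
#' [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return q-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Run the differential-methylation-probe analysis
#'
#' End-to-end probe stage: M-transform, (optional) cell-composition
#' estimation and adjustment, per-probe least squares, empirical-Bayes
#' moderation, BH correction, and beta-scale effect sizes. Testing happens on
#' the M scale; the reported effect `delta_beta` is the difference of group
#' mean betas (an interpretable methylation percentage).
#'
#' @param beta Probe x sample beta matrix (cases and controls only).
#' @param groups `"case"`/`"control"` per sample (aligned with `beta`
#'   columns).
#' @param reference Optional cell-type reference; when supplied, compositions
#'   are estimated and K - 1 of them enter the design as covariates.
#' @param composition Optional precomputed composition matrix (overrides
#'   `reference`-based estimation).
#' @param eps Logit clipping margin for [beta_to_m()].
#' @return List of class `dmp_result`: `table` (data.frame `probe_id`,
#'   `coef_m`, `delta_beta`, `t`, `p`, `q`, `direction`), `model`
#'   (`d0`, `s02`, `df_residual`), `composition`, `design`.
#' @export
dmp_analysis <- function(beta, groups, reference = NULL, composition = NULL,
                         eps = 0.001) {
  stopifnot(length(groups) == ncol(beta))
  if (!all(groups %in% c("case", "control")))
    stop('groups must be "case" or "control"')
  if (!any(groups == "case") || !any(groups == "control"))
    stop("both groups must be present")
  keep <- stats::complete.cases(beta)
  beta <- beta[keep, , drop = FALSE]
  if (is.null(composition) && !is.null(reference))
    composition <- estimate_cell_composition(beta, reference)
  design <- build_design(groups, composition)
  M <- beta_to_m(beta, eps)
  fit <- fit_probe_models(M, design)
  eb <- ebayes_moderate(fit$s2, fit$df_residual,
                        coef = fit$coefficients[, "group"],
                        unscaled_var = fit$cov_unscaled["group"])
  q <- bh_adjust(eb$p)
  delta <- rowMeans(beta[, groups == "case", drop = FALSE]) -
           rowMeans(beta[, groups == "control", drop = FALSE])
  tab <- data.frame(probe_id = rownames(beta),
                    coef_m = unname(fit$coefficients[, "group"]),
                    delta_beta = unname(delta),
                    t = unname(eb$t), p = unname(eb$p), q = unname(q),
                    direction = ifelse(delta < 0, "hypo", "hyper"),
                    stringsAsFactors = FALSE)
  structure(list(table = tab,
                 model = list(d0 = eb$d0, s02 = eb$s02,
                              df_residual = fit$df_residual),
                 composition = composition, design = design),
            class = "dmp_result")
}

#' Select significant differentially methylated probes
#'
#' Dual-threshold rule: corrected p-value (q) below `q_max` AND absolute
#' beta-scale methylation difference above `delta_min`. The effect-size
#' cutoff suppresses probes whose statistical significance rests on tiny,
#' technically fragile differences.
#'
#' @param dmp A `dmp_result` or its `table` data.frame.
#' @param q_max FDR threshold (default 0.01).
#' @param delta_min Minimum |delta beta| (default 0.10, i.e. 10%).
#' @return List: `table` (the significant subset), `n_hypo`, `n_hyper`.
#' @export
select_dmps <- function(dmp, q_max = 0.01, delta_min = 0.10) {
  tab <- if (inherits(dmp, "dmp_result")) dmp$table else dmp
  if (anyNA(tab$q)) stop("missing q-values in DMP table")
  sig <- tab[tab$q < q_max & abs(tab$delta_beta) > delta_min, , drop = FALSE]
  list(table = sig,
       n_hypo = sum(sig$direction == "hypo"),
       n_hyper = sum(sig$direction == "hyper"))
}
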