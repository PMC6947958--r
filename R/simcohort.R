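#' Simulate a leukocyte cell-type methylation reference
#'
#' Builds a probe-by-cell-type matrix of reference beta values with a bimodal
#' baseline (most CpGs near 0 or near 1, a minority intermediate) shared
#' across cell types, plus a designated set of *marker* probes at which the
#' cell types differ strongly. The marker set is what reference-based
#' deconvolution ([estimate_cell_composition()]) projects onto, mirroring the
#' high-contrast CpG panels used for whole-blood deconvolution.
#'
#' @param n_probes Number of CpG probes.
#' @param n_celltypes Number of cell types (at least 2). Default 6, the usual
#'   leukocyte panel (CD4T, CD8T, NK, B cells, monocytes, granulocytes).
#' @param seed Integer seed; mandatory for reproducibility.
#' @param n_markers Number of marker probes with between-type beta contrast of
#'   at least 0.5. Defaults to 5% of probes, floored at 50.
#' @return An object of class `celltype_reference`: a list with
#'   `celltype_names`, `profiles` (probe x cell-type matrix in \[0,1\] with
#'   probe-id rownames) and `marker_probes` (character vector).
#' @export
simulate_reference <- function(n_probes, n_celltypes = 6L, seed,
                               n_markers = max(50L, round(0.05 * n_probes))) {
  if (n_probes < 1 || n_celltypes < 2)
    stop("need n_probes >= 1 and n_celltypes >= 2")
  if (missing(seed)) stop("seed is required")
  if (n_markers > n_probes) stop("n_markers exceeds n_probes")
  set.seed(as.integer(seed))

  probe_ids <- sprintf("cg%08d", seq_len(n_probes))
  celltype_names <- if (n_celltypes == 6L) {
    c("CD4T", "CD8T", "NK", "Bcell", "Mono", "Gran")
  } else {
    sprintf("CT%02d", seq_len(n_celltypes))
  }

  # bimodal baseline: unmethylated / methylated modes plus a small mid class
  mode <- sample.int(3L, n_probes, replace = TRUE, prob = c(0.45, 0.45, 0.10))
  baseline <- numeric(n_probes)
  # mode peaks near 0.12 and 0.88: Infinium betas saturate before 0/1
  baseline[mode == 1L] <- stats::rbeta(sum(mode == 1L), 4, 22)
  baseline[mode == 2L] <- stats::rbeta(sum(mode == 2L), 22, 4)
  baseline[mode == 3L] <- stats::rbeta(sum(mode == 3L), 6, 6)

  # small type-specific wobble around the shared baseline
  profiles <- baseline +
    matrix(stats::rnorm(n_probes * n_celltypes, 0, 0.01), n_probes, n_celltypes)
  profiles <- pmin(pmax(profiles, 0.005), 0.995)

  # marker probes: split cell types into a low and a high camp (contrast >= 0.6)
  marker_idx <- sort(sample.int(n_probes, n_markers))
  for (i in marker_idx) {
    n_low <- sample.int(n_celltypes - 1L, 1L)
    low_types <- sample.int(n_celltypes, n_low)
    lo <- stats::runif(1, 0.03, 0.15)
    hi <- stats::runif(1, 0.75, 0.95)
    profiles[i, ] <- hi + stats::rnorm(n_celltypes, 0, 0.01)
    profiles[i, low_types] <- lo + stats::rnorm(n_low, 0, 0.01)
    profiles[i, ] <- pmin(pmax(profiles[i, ], 0.005), 0.995)
  }

  dimnames(profiles) <- list(probe_ids, celltype_names)
  structure(
    list(celltype_names = celltype_names,
         profiles = profiles,
         marker_probes = probe_ids[marker_idx]),
    class = "celltype_reference")
}

#' Simulation configuration for a synthetic methylation cohort
#'
#' Collects and validates all knobs of [simulate_cohort()]. Defaults emulate
#' the discovery design of a rare-syndrome blood episignature study: 6 cases
#' against 60 controls, a planted predominantly hypomethylated signature of
#' 1000 CpGs (4.6% hypermethylated) concentrated in 100 five-probe regional
#' blocks, leukocyte-composition confounding between groups, and age, sex and
#' batch nuisance structure.
#'
#' @param n_probes Total probes on the master (EPIC-like) manifest.
#' @param n_cases,n_controls Group sizes.
#' @param n_signature_probes Number of planted case-vs-control probes
#'   (includes the regional-block probes).
#' @param effect_size_range Magnitude range for the planted beta shift
#'   (both endpoints in (0, 1)); signs are assigned via `hyper_fraction`.
#' @param hyper_fraction Share of planted effects that are hypermethylated
#'   (positive delta-beta); the remainder are hypomethylated.
#' @param n_dmr_blocks,probes_per_block,block_spacing Planted regional blocks:
#'   number of blocks, probes per block (>= 3), and maximum genomic gap (bp)
#'   between consecutive block members.
#' @param dirichlet_cases,dirichlet_controls Dirichlet concentration vectors
#'   (length = number of reference cell types) for per-sample leukocyte
#'   compositions; different vectors make composition a group confounder.
#' @param noise_precision Beta-noise precision `phi`: observed betas are
#'   Beta(mu*phi, (1-mu)*phi). `Inf` means noise-free.
#' @param n_latent_factors,latent_loading_sd Population-heterogeneity model:
#'   each sample draws standard-normal scores on `n_latent_factors` latent
#'   methylation axes with per-probe loadings of SD `latent_loading_sd`
#'   (beta scale). This emulates the structured inter-individual variation
#'   of real blood methylomes, which dominates the top principal components;
#'   it is identically distributed in both groups. Set
#'   `n_latent_factors = 0` to disable.
#' @param age_range Uniform age range (years).
#' @param batch_effect_sd SD of per-batch, per-probe beta offsets.
#' @param n_batches Number of array batches.
#' @param frac_chrX,frac_chrY,frac_snp,frac_crossreactive Fractions of probes
#'   assigned to chrX/chrY or flagged as SNP-containing / cross-reactive.
#' @param frac_450k Fraction of probes also present on the 450K dialect
#'   (the 450K mask is a strict subset of the EPIC mask).
#' @param detp_fail_rate Fraction of probe-sample entries given a failing
#'   detection p-value (> 0.01).
#' @param seed Integer seed; mandatory.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_probes = 1e5L,
                       n_cases = 6L,
                       n_controls = 60L,
                       n_signature_probes = 1000L,
                       effect_size_range = c(0.10, 0.25),
                       hyper_fraction = 0.046,
                       n_dmr_blocks = 100L,
                       probes_per_block = 5L,
                       block_spacing = 200L,
                       dirichlet_cases = NULL,
                       dirichlet_controls = NULL,
                       noise_precision = 100,
                       n_latent_factors = 5L,
                       latent_loading_sd = 0.01,
                       age_range = c(2, 45),
                       batch_effect_sd = 0.01,
                       n_batches = 3L,
                       frac_chrX = 0.02,
                       frac_chrY = 0.005,
                       frac_snp = 0.01,
                       frac_crossreactive = 0.005,
                       frac_450k = 0.7,
                       detp_fail_rate = 0,
                       seed) {
  if (missing(seed)) stop("seed is required")
  cfg <- list(n_probes = as.integer(n_probes), n_cases = as.integer(n_cases),
              n_controls = as.integer(n_controls),
              n_signature_probes = as.integer(n_signature_probes),
              effect_size_range = sort(abs(effect_size_range)),
              hyper_fraction = hyper_fraction,
              n_dmr_blocks = as.integer(n_dmr_blocks),
              probes_per_block = as.integer(probes_per_block),
              block_spacing = as.integer(block_spacing),
              dirichlet_cases = dirichlet_cases,
              dirichlet_controls = dirichlet_controls,
              noise_precision = noise_precision,
              n_latent_factors = as.integer(n_latent_factors),
              latent_loading_sd = latent_loading_sd,
              age_range = age_range, batch_effect_sd = batch_effect_sd,
              n_batches = as.integer(n_batches),
              frac_chrX = frac_chrX, frac_chrY = frac_chrY,
              frac_snp = frac_snp, frac_crossreactive = frac_crossreactive,
              frac_450k = frac_450k, detp_fail_rate = detp_fail_rate,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_probes > 0, n_cases > 0, n_controls > 0,
              n_signature_probes >= 0, n_signature_probes <= n_probes,
              probes_per_block >= 3, block_spacing > 0,
              hyper_fraction >= 0, hyper_fraction <= 1,
              noise_precision > 0, n_batches >= 1)
    if (any(cfg$effect_size_range <= 0) || any(cfg$effect_size_range >= 1))
      stop("effect sizes must have magnitude in (0, 1)")
    if (n_dmr_blocks * probes_per_block > n_signature_probes)
      stop("regional blocks require more probes than n_signature_probes")
  })
  structure(cfg, class = "sim_config")
}

# default blood compositions: roughly granulocyte-dominated whole blood
.default_alpha <- function(k, case = FALSE) {
  if (k == 6L) {
    base <- if (case) c(0.19, 0.11, 0.04, 0.07, 0.07, 0.52)
            else      c(0.14, 0.09, 0.07, 0.10, 0.06, 0.54)
  } else {
    base <- stats::runif(k, 0.5, 1.5); base <- base / sum(base)
    if (case) base <- rev(base)
  }
  base * 40
}

.rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha), n,
              length(alpha), byrow = TRUE)
  x / rowSums(x)
}

# derive independent per-stage seeds from the single global seed
.stage_seeds <- function(seed, n) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate a full synthetic array cohort with known ground truth
#'
#' Draws per-sample leukocyte compositions from group-specific Dirichlet
#' distributions, mixes the cell-type reference profiles accordingly, plants a
#' case-only signature (isolated probes plus tight regional blocks), adds age,
#' sex and batch nuisance effects, perturbs with beta-distributed noise, and
#' emits methylated/unmethylated signal pairs and detection p-values
#' consistent with the betas. Planted probes are drawn from CpGs with enough
#' headroom for the configured shift, so planted group means stay inside
#' (0, 1); any residual excursion is clipped and counted in
#' `truth$n_clipped`.
#'
#' @param config A [sim_config()] object.
#' @param reference A [simulate_reference()] object with
#'   `config$n_probes` probes.
#' @return A list of class `episim_cohort` with elements `beta` (probe x
#'   sample matrix), `meth`, `unmeth`, `detp` (same shape), `manifest`
#'   (probe_id, chrom, pos, is_snp, is_crossreactive, on_450k, on_epic),
#'   `sheet` (sample_id, group, age_years, sex, batch, array_type) and
#'   `truth` (planted probe deltas, planted regions, true compositions `W`,
#'   clip count).
#' @export
simulate_cohort <- function(config, reference) {
  stopifnot(inherits(config, "sim_config"),
            inherits(reference, "celltype_reference"))
  if (nrow(reference$profiles) != config$n_probes)
    stop("reference probe count does not match config$n_probes")
  k <- length(reference$celltype_names)
  a_case <- config$dirichlet_cases %||% .default_alpha(k, case = TRUE)
  a_ctrl <- config$dirichlet_controls %||% .default_alpha(k, case = FALSE)
  stopifnot(length(a_case) == k, length(a_ctrl) == k)

  seeds <- .stage_seeds(config$seed, 4L)
  probe_ids <- rownames(reference$profiles)

  ## ---- manifest + planted truth -------------------------------------------
  set.seed(seeds[1])
  man <- .sim_manifest(config, reference)

  ## ---- samples -------------------------------------------------------------
  set.seed(seeds[2])
  n <- config$n_cases + config$n_controls
  case_sex <- sample(c("M", "F"), config$n_cases, replace = TRUE)
  # control pool mirrors the case sex mix (matched-control databases are
  # queried by sex, so a 1:ratio match must be feasible per stratum)
  n_m <- round(config$n_controls * mean(case_sex == "M"))
  ctrl_sex <- sample(rep(c("M", "F"), c(n_m, config$n_controls - n_m)))
  sheet <- data.frame(
    sample_id = c(sprintf("case_%02d", seq_len(config$n_cases)),
                  sprintf("ctrl_%03d", seq_len(config$n_controls))),
    group = rep(c("case", "control"), c(config$n_cases, config$n_controls)),
    age_years = round(stats::runif(n, config$age_range[1], config$age_range[2]), 1),
    sex = c(case_sex, ctrl_sex),
    batch = sample.int(config$n_batches, n, replace = TRUE),
    array_type = "EPIC",
    stringsAsFactors = FALSE)
  W <- rbind(.rdirichlet(config$n_cases, a_case),
             .rdirichlet(config$n_controls, a_ctrl))
  dimnames(W) <- list(sheet$sample_id, reference$celltype_names)

  ## ---- expected betas ------------------------------------------------------
  set.seed(seeds[3])
  mu <- reference$profiles %*% t(W)                      # probes x samples
  is_case <- sheet$group == "case"
  if (nrow(man$planted) > 0) {
    pi <- match(man$planted$probe_id, probe_ids)
    mu[pi, is_case] <- mu[pi, is_case] + man$planted$delta
    trunc_n <- sum(mu[pi, is_case] < 0 | mu[pi, is_case] > 1)
    if (trunc_n > 0)
      warning(sprintf(
        "%d planted case beta means fall outside (0,1); effect truncated by clipping",
        trunc_n))
  }
  # age effect on a 1% probe subset; batch offsets on all probes
  n_age <- max(1L, round(0.01 * config$n_probes))
  age_idx <- sample.int(config$n_probes, n_age)
  age_slope <- stats::rnorm(n_age, 0, 0.002)
  mu[age_idx, ] <- mu[age_idx, ] +
    outer(age_slope, sheet$age_years - mean(config$age_range))
  if (config$batch_effect_sd > 0) {
    boff <- matrix(stats::rnorm(config$n_probes * config$n_batches, 0,
                                config$batch_effect_sd),
                   config$n_probes, config$n_batches)
    mu <- mu + boff[, sheet$batch]
  }
  # structured inter-individual variation (population heterogeneity)
  if (config$n_latent_factors > 0 && config$latent_loading_sd > 0) {
    L <- matrix(stats::rnorm(config$n_probes * config$n_latent_factors, 0,
                             config$latent_loading_sd),
                config$n_probes, config$n_latent_factors)
    S <- matrix(stats::rnorm(n * config$n_latent_factors), n,
                config$n_latent_factors)
    mu <- mu + L %*% t(S)
  }
  n_clipped <- sum(mu < 0 | mu > 1)
  mu <- pmin(pmax(mu, 1e-4), 1 - 1e-4)

  ## ---- observation noise + signals ----------------------------------------
  set.seed(seeds[4])
  beta <- .beta_noise(mu, config$noise_precision)
  dimnames(beta) <- list(probe_ids, sheet$sample_id)

  total <- matrix(2000 * exp(stats::rnorm(length(beta), 0, 0.1)),
                  nrow(beta), ncol(beta))
  # sex-dependent sex-chromosome intensities: females have near-background Y,
  # males a single-copy X
  x_idx <- which(man$manifest$chrom == "X")
  y_idx <- which(man$manifest$chrom == "Y")
  female <- sheet$sex == "F"
  if (length(y_idx) && any(female)) {
    total[y_idx, female] <- total[y_idx, female] * 0.02
    beta[y_idx, female] <- stats::runif(length(y_idx) * sum(female), 0.2, 0.8)
  }
  if (length(x_idx) && any(!female))
    total[x_idx, !female] <- total[x_idx, !female] * 0.55

  meth <- beta * total
  unmeth <- (1 - beta) * total
  dimnames(meth) <- dimnames(unmeth) <- dimnames(beta)

  detp <- matrix(stats::runif(length(beta), 0, 0.009), nrow(beta), ncol(beta),
                 dimnames = dimnames(beta))
  if (length(y_idx) && any(female))
    detp[y_idx, female] <- stats::runif(length(y_idx) * sum(female), 0.05, 1)
  if (config$detp_fail_rate > 0) {
    nf <- round(config$detp_fail_rate * length(detp))
    if (nf > 0) {
      fi <- sample.int(length(detp), nf)
      detp[fi] <- stats::runif(nf, 0.011, 0.5)
    }
  }

  structure(
    list(beta = beta, meth = meth, unmeth = unmeth, detp = detp,
         manifest = man$manifest, sheet = sheet,
         truth = list(planted = man$planted, regions = man$regions,
                      W = W, n_clipped = n_clipped)),
    class = "episim_cohort")
}

# observed betas around expected value mu with precision phi
.beta_noise <- function(mu, phi) {
  if (is.infinite(phi)) return(mu)
  m <- pmin(pmax(mu, 1e-4), 1 - 1e-4)
  matrix(stats::rbeta(length(m), m * phi, (1 - m) * phi), nrow(m), ncol(m))
}

# Build the manifest (chrom, pos, flags, array masks) and the planted truth
# (probe deltas + regional blocks). Assumes the stage RNG is already seeded.
.sim_manifest <- function(config, reference) {
  n <- config$n_probes
  probe_ids <- rownames(reference$profiles)

  n_x <- round(config$frac_chrX * n)
  n_y <- round(config$frac_chrY * n)
  n_auto <- n - n_x - n_y
  auto_chrom <- sort(rep_len(as.character(1:22), n_auto))
  chrom <- c(auto_chrom, rep("X", n_x), rep("Y", n_y))

  # large default inter-probe gaps so background probes never form regions
  gaps <- round(stats::runif(n, 1500, 8000))
  is_snp <- stats::runif(n) < config$frac_snp
  is_xr <- stats::runif(n) < config$frac_crossreactive
  on_450k <- stats::runif(n) < config$frac_450k

  marker <- probe_ids %in% reference$marker_probes
  autosomal <- seq_len(n_auto)

  ## planted probes need headroom for the shift and must not be deconvolution
  ## markers, SNP-flagged or cross-reactive (those are removed by QC)
  max_eff <- config$effect_size_range[2] + 0.05
  prof_min <- do.call(pmin, as.data.frame(reference$profiles))
  prof_max <- do.call(pmax, as.data.frame(reference$profiles))
  clean <- !marker & !is_snp & !is_xr
  hypo_ok <- clean & prof_min >= max_eff & seq_len(n) <= n_auto
  hyper_ok <- clean & prof_max <= 1 - max_eff & seq_len(n) <= n_auto
  elig_hypo <- which(hypo_ok)
  elig_hyper <- which(hyper_ok)

  n_block_probes <- config$n_dmr_blocks * config$probes_per_block
  n_single <- config$n_signature_probes - n_block_probes

  ## regional blocks: runs of consecutive eligible probes on one chromosome.
  ## Block sign chosen per block; isolated probes get per-probe signs.
  ## planted direction composition is exact, not sampled: the truth table
  ## should impose the configured hyper share, not draw it
  blocks <- list()
  used <- logical(n)
  ppb <- config$probes_per_block
  n_hyper_total <- round(config$hyper_fraction * config$n_signature_probes)
  n_hyper_blocks <- min(round(config$hyper_fraction * config$n_dmr_blocks),
                        n_hyper_total %/% ppb)
  block_sign <- rep(c(1, -1), c(n_hyper_blocks,
                                config$n_dmr_blocks - n_hyper_blocks))
  for (b in seq_len(config$n_dmr_blocks)) {
    elig <- if (block_sign[b] > 0) elig_hyper else elig_hypo
    elig_mask <- if (block_sign[b] > 0) hyper_ok else hypo_ok
    # candidate run starts: ppb consecutive eligible, unused, same chromosome,
    # with an unused buffer probe on each side so neighbouring blocks
    # cannot merge across a small gap
    found <- FALSE
    for (try in seq_len(2000L)) {
      s <- elig[sample.int(length(elig), 1L)]
      idx <- s:(s + ppb - 1L)
      if (max(idx) > n_auto) next
      if (any(used[max(1L, s - 1L):min(n, max(idx) + 1L)])) next
      if (length(unique(chrom[idx])) != 1L) next
      if (!all(elig_mask[idx])) next
      blocks[[b]] <- idx
      used[idx] <- TRUE
      found <- TRUE
      break
    }
    if (!found) stop("could not place all regional blocks; increase n_probes")
  }
  block_idx <- unlist(blocks)
  # tighten within-block gaps to at most block_spacing
  for (idx in blocks)
    gaps[idx[-1]] <- round(stats::runif(ppb - 1L, 50,
                                        config$block_spacing))

  pos <- stats::ave(gaps, chrom, FUN = cumsum)

  single_pool_h <- setdiff(elig_hypo, block_idx)
  single_pool_H <- setdiff(elig_hyper, block_idx)
  n_sh <- max(0L, n_hyper_total - n_hyper_blocks * ppb)
  if (length(single_pool_H) < n_sh || length(single_pool_h) < n_single - n_sh)
    stop("not enough eligible probes for the planted signature")
  singles <- c(single_pool_H[sample.int(length(single_pool_H), n_sh)],
               single_pool_h[sample.int(length(single_pool_h), n_single - n_sh)])
  single_sign <- rep(c(1, -1), c(n_sh, n_single - n_sh))

  planted_idx <- c(block_idx, singles)
  planted_sign <- c(rep(block_sign, each = ppb), single_sign)
  mag <- stats::runif(length(planted_idx), config$effect_size_range[1],
                      config$effect_size_range[2])
  planted <- data.frame(probe_id = probe_ids[planted_idx],
                        delta = planted_sign * mag,
                        stringsAsFactors = FALSE)

  regions <- if (length(blocks) == 0) data.frame(
    chrom = character(), start = numeric(), end = numeric(),
    n_probes = integer(), sign = numeric(), probe_ids = character(),
    stringsAsFactors = FALSE) else data.frame(
    chrom = vapply(blocks, function(i) chrom[i[1]], ""),
    start = vapply(blocks, function(i) min(pos[i]), 0),
    end = vapply(blocks, function(i) max(pos[i]), 0),
    n_probes = ppb,
    sign = block_sign,
    probe_ids = vapply(blocks, function(i) paste(probe_ids[i], collapse = ";"), ""),
    stringsAsFactors = FALSE)

  manifest <- data.frame(probe_id = probe_ids, chrom = chrom, pos = as.integer(pos),
                         is_snp = is_snp, is_crossreactive = is_xr,
                         on_450k = on_450k, on_epic = TRUE,
                         stringsAsFactors = FALSE)
  list(manifest = manifest, planted = planted, regions = regions)
}

#' Simulate additional samples against an existing reference
#'
#' Lightweight generator for specificity cohorts: healthy controls, carriers
#' of a *different* planted signature, pure cell-type samples, or screening
#' sets with hidden positives. Betas can be restricted to a probe subset
#' (e.g. the episignature probes), which is exact because probes are
#' conditionally independent given the composition.
#'
#' @param reference A [simulate_reference()] object.
#' @param n Number of samples.
#' @param seed Integer seed.
#' @param alpha Dirichlet concentration vector for compositions, or `NULL`
#'   when `compositions` is given.
#' @param compositions Optional n x K matrix of fixed compositions (rows sum
#'   to 1), e.g. simplex vertices for pure cell types.
#' @param planted Optional data.frame (`probe_id`, `delta`) of beta shifts
#'   applied to every sample (use for case-like or other-syndrome samples).
#' @param noise_precision Beta-noise precision.
#' @param probes Optional character vector restricting output to these probes.
#' @param prefix Sample-id prefix.
#' @return A list with `beta` (probe x sample) and `W` (true compositions).
#' @export
simulate_samples <- function(reference, n, seed, alpha = NULL,
                             compositions = NULL, planted = NULL,
                             noise_precision = 100, probes = NULL,
                             prefix = "s") {
  stopifnot(inherits(reference, "celltype_reference"), n >= 1)
  if (missing(seed)) stop("seed is required")
  set.seed(as.integer(seed))
  k <- length(reference$celltype_names)
  W <- if (!is.null(compositions)) {
    stopifnot(nrow(compositions) == n, ncol(compositions) == k)
    compositions
  } else {
    .rdirichlet(n, alpha %||% .default_alpha(k))
  }
  prof <- reference$profiles
  if (!is.null(probes)) {
    miss <- setdiff(probes, rownames(prof))
    if (length(miss)) stop("unknown probes: ", paste(utils::head(miss), collapse = ", "))
    prof <- prof[probes, , drop = FALSE]
  }
  mu <- prof %*% t(W)
  if (!is.null(planted) && nrow(planted) > 0) {
    hit <- planted$probe_id %in% rownames(mu)
    if (any(hit))
      mu[planted$probe_id[hit], ] <- mu[planted$probe_id[hit], ] + planted$delta[hit]
  }
  mu <- pmin(pmax(mu, 1e-4), 1 - 1e-4)
  beta <- .beta_noise(mu, noise_precision)
  dimnames(beta) <- list(rownames(prof), sprintf("%s_%03d", prefix, seq_len(n)))
  rownames(W) <- colnames(beta)
  list(beta = beta, W = W)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
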