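#' Signed per-probe z-scores from two-sided p-values
#'
#' z = sign(delta_beta) * qnorm(1 - p/2). Zero p-values are clipped to the
#' smallest positive double; p = 1 maps to z = 0.
#'
#' @param p Two-sided p-values.
#' @param delta Signed effect sizes (only the sign is used).
#' @return Signed z-scores.
#' @export
probe_z <- function(p, delta) {
  stopifnot(length(p) == length(delta))
  p <- pmax(p, .Machine$double.xmin)
  sign(delta) * stats::qnorm(p / 2, lower.tail = FALSE)
}

#' Gaussian kernel smoothing of probe statistics along the genome
#'
#' Per chromosome, smooths signed z-scores with a Gaussian kernel of
#' bandwidth sigma = `lambda_bp` / `C` over genomic distance, normalising by
#' the root sum of squared weights so the smoothed statistic keeps unit
#' variance under an independent N(0,1) null:
#' z_smooth_i = sum_j K_ij z_j / sqrt(sum_j K_ij^2). An isolated probe (no
#' neighbour within the kernel window) is returned unchanged. Weights beyond
#' 5 sigma are treated as zero.
#'
#' @param z Signed probe z-scores.
#' @param positions Genomic positions (bp), sorted non-decreasingly within
#'   each chromosome (error otherwise).
#' @param chrom Chromosome label per probe (single chromosome assumed if
#'   omitted).
#' @param lambda_bp Kernel scale in bp (default 1000).
#' @param C Bandwidth divisor, sigma = lambda_bp / C (default 2).
#' @return Smoothed z-scores, same length/order as `z`.
#' @export
kernel_smooth <- function(z, positions, chrom = NULL, lambda_bp = 1000, C = 2) {
  n <- length(z)
  stopifnot(length(positions) == n)
  if (is.null(chrom)) chrom <- rep("1", n)
  sigma <- lambda_bp / C
  window <- 5 * sigma
  out <- numeric(n)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    pos <- positions[idx]
    if (is.unsorted(pos)) stop("positions must be sorted within chromosome ", ch)
    zc <- z[idx]
    m <- length(idx)
    sm <- numeric(m)
    lo <- 1L
    hi <- 1L
    for (i in seq_len(m)) {
      while (pos[i] - pos[lo] > window) lo <- lo + 1L
      while (hi < m && pos[hi + 1L] - pos[i] <= window) hi <- hi + 1L
      w <- exp(-((pos[lo:hi] - pos[i])^2) / (2 * sigma^2))
      sm[i] <- sum(w * zc[lo:hi]) / sqrt(sum(w^2))
    }
    out[idx] <- sm
  }
  out
}

#' Call differentially methylated regions
#'
#' Seeds are probe-level significant CpGs (q < `q_seed`, or smoothed-z
#' significance when `seed_from = "smoothed"`). Seeds on the same chromosome
#' with consecutive gaps of at most `max_gap` bp form candidate regions;
#' candidates with at least `min_probes` members get a Stouffer-combined
#' statistic Z = sum(z_i) / sqrt(n) from the unsmoothed probe z-scores, a
#' two-sided normal p-value, and a BH FDR across candidates. Reported
#' regions additionally require FDR < `fdr_max` and an absolute mean
#' beta-scale difference above `delta_min`. The Stouffer combination assumes
#' independent probes and is anti-conservative under spatial correlation —
#' the structural gap/probe-count rules are what keep calls regional.
#'
#' @param dmp A `dmp_result` or DMP table (`probe_id`, `delta_beta`, `p`,
#'   `q`).
#' @param manifest Probe manifest (`probe_id`, `chrom`, `pos`).
#' @param max_gap Maximum gap between consecutive member probes (default
#'   1000 bp).
#' @param min_probes Minimum probes per region (default 3).
#' @param delta_min Minimum |mean regional delta beta| (default 0.10).
#' @param fdr_max Stouffer FDR threshold (default 0.01).
#' @param q_seed Probe-level FDR defining seed probes (default 0.01).
#' @param seed_from `"probe"` (default) seeds from probe-level q;
#'   `"smoothed"` seeds from BH-adjusted two-sided p-values of the
#'   kernel-smoothed statistic.
#' @param lambda_bp,C Kernel parameters for the smoothed diagnostic /
#'   smoothed seeding.
#' @return data.frame of class `dmr_table`: `chrom`, `start`, `end`
#'   (1-based inclusive), `n_probes`, `mean_delta`, `stouffer_z`, `p`,
#'   `fdr`, `direction`, `mean_smoothed_z`, `probe_ids`
#'   (semicolon-collapsed).
#' @export
call_regions <- function(dmp, manifest, max_gap = 1000, min_probes = 3,
                         delta_min = 0.10, fdr_max = 0.01, q_seed = 0.01,
                         seed_from = c("probe", "smoothed"),
                         lambda_bp = 1000, C = 2) {
  seed_from <- match.arg(seed_from)
  tab <- if (inherits(dmp, "dmp_result")) dmp$table else dmp
  mi <- match(tab$probe_id, manifest$probe_id)
  if (anyNA(mi)) stop("DMP probes absent from manifest")
  d <- data.frame(probe_id = tab$probe_id, chrom = manifest$chrom[mi],
                  pos = manifest$pos[mi], delta = tab$delta_beta,
                  p = tab$p, q = tab$q, stringsAsFactors = FALSE)
  d <- d[order(d$chrom, d$pos), ]
  d$z <- probe_z(d$p, d$delta)
  d$sz <- kernel_smooth(d$z, d$pos, d$chrom, lambda_bp, C)

  seed <- if (seed_from == "probe") d$q < q_seed
          else bh_adjust(2 * stats::pnorm(-abs(d$sz))) < q_seed
  s <- d[seed, , drop = FALSE]
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      n_probes = integer(), mean_delta = numeric(),
                      stouffer_z = numeric(), p = numeric(), fdr = numeric(),
                      direction = character(), mean_smoothed_z = numeric(),
                      probe_ids = character(), stringsAsFactors = FALSE)
  if (nrow(s) == 0) return(structure(empty, class = c("dmr_table", "data.frame")))

  new_block <- c(TRUE, s$chrom[-1] != s$chrom[-nrow(s)] |
                       diff(s$pos) > max_gap)
  block <- cumsum(new_block)
  keep_blocks <- names(which(table(block) >= min_probes))
  if (length(keep_blocks) == 0)
    return(structure(empty, class = c("dmr_table", "data.frame")))

  regions <- do.call(rbind, lapply(keep_blocks, function(b) {
    r <- s[block == as.integer(b), , drop = FALSE]
    data.frame(chrom = r$chrom[1], start = min(r$pos), end = max(r$pos),
               n_probes = nrow(r), mean_delta = mean(r$delta),
               stouffer_z = sum(r$z) / sqrt(nrow(r)),
               mean_smoothed_z = mean(r$sz),
               probe_ids = paste(r$probe_id, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  regions$p <- 2 * stats::pnorm(-abs(regions$stouffer_z))
  regions$fdr <- bh_adjust(regions$p)
  regions$direction <- ifelse(regions$mean_delta < 0, "hypo", "hyper")
  out <- regions[regions$fdr < fdr_max & abs(regions$mean_delta) > delta_min, ,
                 drop = FALSE]
  out <- out[order(out$chrom, out$start),
             c("chrom", "start", "end", "n_probes", "mean_delta",
               "stouffer_z", "p", "fdr", "direction", "mean_smoothed_z",
               "probe_ids")]
  rownames(out) <- NULL
  structure(out, class = c("dmr_table", "data.frame"))
}

#' Map regions to overlapping genes
#'
#' Reports every gene whose annotation interval overlaps a region by at
#' least 1 bp. Coordinates are 1-based inclusive on both sides.
#'
#' @param dmr A `dmr_table` (or data.frame with `chrom`, `start`, `end`).
#' @param genes Gene annotation data.frame: `gene`, `chrom`, `start`, `end`.
#' @return data.frame `region_index`, `chrom`, `start`, `end`, `gene`; one
#'   row per overlapping region-gene pair.
#' @export
map_regions_to_genes <- function(dmr, genes) {
  if (nrow(dmr) == 0)
    return(data.frame(region_index = integer(), chrom = character(),
                      start = integer(), end = integer(), gene = character(),
                      stringsAsFactors = FALSE))
  unmatched <- setdiff(unique(dmr$chrom), unique(genes$chrom))
  if (length(unmatched))
    stop("region chromosomes absent from gene annotation: ",
         paste(unmatched, collapse = ", "))
  hits <- lapply(seq_len(nrow(dmr)), function(i) {
    ov <- genes$chrom == dmr$chrom[i] &
      genes$start <= dmr$end[i] & genes$end >= dmr$start[i]
    if (!any(ov)) return(NULL)
    data.frame(region_index = i, chrom = dmr$chrom[i], start = dmr$start[i],
               end = dmr$end[i], gene = genes$gene[ov],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(region_index = integer(), chrom = character(),
                      start = integer(), end = integer(), gene = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read gene sets in GMT format
#'
#' Each tab-separated line is: set name, description, member genes.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(strsplit(lines, "\t"), `[`, "", 1L)
  sets
}

#' Hypergeometric over-representation test for gene sets
#'
#' One-sided hypergeometric tail per set: the probability of drawing at
#' least the observed number of set members in a query of the given size
#' from the universe, BH-adjusted across sets. Query genes outside the
#' universe are dropped with a warning.
#'
#' @param genes Character vector of query genes (e.g. DMR-overlapping
#'   genes).
#' @param sets Named list of gene sets (e.g. from [read_gmt()]).
#' @param universe Character vector of all assayable genes.
#' @return data.frame `set`, `set_size`, `overlap`, `p`, `q`, sorted by p.
#' @export
enrichment_test <- function(genes, sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty gene universe")
  genes <- unique(genes)
  outside <- setdiff(genes, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    genes <- intersect(genes, universe)
  }
  res <- lapply(names(sets), function(nm) {
    set <- intersect(unique(sets[[nm]]), universe)
    k <- length(intersect(genes, set))
    p <- stats::phyper(k - 1, length(set), length(universe) - length(set),
                       length(genes), lower.tail = FALSE)
    data.frame(set = nm, set_size = length(set), overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p)
  out[order(out$p), ]
}
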