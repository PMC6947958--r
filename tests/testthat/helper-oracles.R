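# Independent oracles used to validate the package's implementations.

# literal Benjamini-Hochberg step-up: q_(i) = min_{j >= i} p_(j) * m / j
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(p[o][i:m] * m / (i:m)))
  }, 0)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# brute-force O(n^3) Ward agglomeration; returns the merge heights.
# Ward cluster distance: d(A,B) = sqrt( 2|A||B|/(|A|+|B|) * ||c_A - c_B||^2 )
ward_oracle_heights <- function(x) {
  clusters <- lapply(seq_len(nrow(x)), identity)
  heights <- numeric(0)
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      a <- clusters[[i]]; b <- clusters[[j]]
      ca <- colMeans(x[a, , drop = FALSE])
      cb <- colMeans(x[b, , drop = FALSE])
      d <- sqrt(2 * length(a) * length(b) / (length(a) + length(b)) *
                sum((ca - cb)^2))
      if (d < best[1]) best <- c(d, i, j)
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

# fraction of truth regions recovered by called regions with >= 50%
# reciprocal overlap
region_recovery <- function(truth, called) {
  if (nrow(truth) == 0) return(NA_real_)
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    ov <- which(called$chrom == truth$chrom[i] &
                called$start <= truth$end[i] & called$end >= truth$start[i])
    any(vapply(ov, function(j) {
      inter <- min(called$end[j], truth$end[i]) -
               max(called$start[j], truth$start[i]) + 1
      inter >= 0.5 * (truth$end[i] - truth$start[i] + 1) &&
        inter >= 0.5 * (called$end[j] - called$start[j] + 1)
    }, TRUE))
  }, TRUE)
  mean(hit)
}

# small shared simulation fixtures
make_test_reference <- function(n_probes = 5000, k = 6, seed = 11)
  simulate_reference(n_probes, k, seed = seed)

make_test_cohort <- function(reference, seed = 1, ...) {
  args <- list(n_probes = nrow(reference$profiles), n_controls = 40L,
               n_signature_probes = 200L, n_dmr_blocks = 20L,
               effect_size_range = c(0.15, 0.15), seed = seed)
  cfg <- do.call(sim_config, utils::modifyList(args, list(...)))
  simulate_cohort(cfg, reference)
}
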