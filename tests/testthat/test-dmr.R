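test_that("signed probe z-scores follow the normal quantile transform", {
  expect_equal(probe_z(0.0455, -1), -1.9991, tolerance = 1e-3)
  expect_equal(probe_z(0.0455, 1), 1.9991, tolerance = 1e-3)
  expect_equal(probe_z(1, -1), 0)
  expect_true(is.finite(probe_z(0, 1)))   # p = 0 clipped, not infinite
})

test_that("kernel smoothing preserves isolated probes and pools neighbours", {
  # isolated probes: no neighbour within the window, returned unchanged
  z <- c(1.3, -0.7, 2.1)
  pos <- c(1e5, 2e5, 3e5)
  expect_equal(kernel_smooth(z, pos), z)

  # three co-located probes with z = 2: smoothed z = 2 * sqrt(3)
  expect_equal(kernel_smooth(c(2, 2, 2), c(500, 500, 500)),
               rep(2 * sqrt(3), 3))
  expect_equal(kernel_smooth(rep(0, 5), 1:5 * 100), rep(0, 5))
  expect_error(kernel_smooth(1:3, c(300, 100, 200)), "sorted")

  # chromosomes are smoothed independently
  sm <- kernel_smooth(c(2, 2), c(1000, 1000), chrom = c("1", "2"))
  expect_equal(sm, c(2, 2))

  # unit variance under an independent standard-normal null
  set.seed(61)
  zn <- rnorm(5000)
  sm <- kernel_smooth(zn, cumsum(sample(100:400, 5000, TRUE)))
  expect_equal(var(sm), 1, tolerance = 0.1)
})

make_dmp_table <- function(probe_id, chrom, pos, delta, p, q = p) {
  manifest <- data.frame(probe_id = probe_id, chrom = chrom, pos = pos,
                         stringsAsFactors = FALSE)
  tab <- data.frame(probe_id = probe_id, delta_beta = delta, p = p, q = q,
                    stringsAsFactors = FALSE)
  list(tab = tab, manifest = manifest)
}

test_that("region grouping follows the gap and probe-count rules", {
  # gaps 500 and 900: one region of 3 probes
  fx <- make_dmp_table(paste0("cg", 1:3), "1", c(1000, 1500, 2400),
                       rep(-0.15, 3), rep(1e-6, 3))
  dmr <- call_regions(fx$tab, fx$manifest)
  expect_equal(nrow(dmr), 1)
  expect_equal(dmr$n_probes, 3)
  expect_equal(dmr$start, 1000)
  expect_equal(dmr$end, 2400)

  # gap 1100 splits into fragments below the probe minimum: nothing called
  fx2 <- make_dmp_table(paste0("cg", 1:2), "1", c(1000, 2100),
                        rep(-0.15, 2), rep(1e-6, 2))
  expect_equal(nrow(call_regions(fx2$tab, fx2$manifest)), 0)
})

test_that("the Stouffer statistic and region p match direct evaluation", {
  p3 <- 2 * pnorm(-3)
  fx <- make_dmp_table(paste0("cg", 1:3), "7", c(100, 300, 500),
                       rep(-0.15, 3), rep(p3, 3))
  dmr <- call_regions(fx$tab, fx$manifest)
  expect_equal(nrow(dmr), 1)
  expect_equal(dmr$stouffer_z, -3 * sqrt(3), tolerance = 1e-6)
  expect_equal(dmr$p, 2 * pnorm(-3 * sqrt(3)), tolerance = 1e-9)
  expect_equal(dmr$direction, "hypo")
  expect_equal(dmr$mean_delta, -0.15)

  # the delta filter vetoes otherwise significant regions
  fx2 <- make_dmp_table(paste0("cg", 1:3), "7", c(100, 300, 500),
                        rep(-0.05, 3), rep(p3, 3))
  expect_equal(nrow(call_regions(fx2$tab, fx2$manifest)), 0)
})

test_that("smoothed-statistic seeding is available behind the switch", {
  p3 <- 2 * pnorm(-3)
  fx <- make_dmp_table(paste0("cg", 1:4), "2", c(100, 300, 500, 9e5),
                       c(rep(-0.15, 3), -0.2), c(rep(p3, 3), 0.5),
                       q = c(rep(p3, 3), 0.5))
  dmr <- call_regions(fx$tab, fx$manifest, seed_from = "smoothed")
  expect_equal(nrow(dmr), 1)
  expect_equal(dmr$n_probes, 3)
})

test_that("regions map to overlapping genes with 1-based inclusive logic", {
  dmr <- data.frame(chrom = c("1", "1"), start = c(100, 5000),
                    end = c(200, 6000), stringsAsFactors = FALSE)
  genes <- data.frame(gene = c("A", "B", "C", "D"),
                      chrom = "1",
                      start = c(150, 201, 5500, 5900),
                      end = c(300, 400, 5600, 7000),
                      stringsAsFactors = FALSE)
  hits <- map_regions_to_genes(dmr, genes)
  expect_setequal(hits$gene[hits$region_index == 1], "A")  # B starts at 201
  expect_setequal(hits$gene[hits$region_index == 2], c("C", "D"))
  dmr_bad <- data.frame(chrom = "chr9", start = 1, end = 2)
  expect_error(map_regions_to_genes(dmr_bad, genes), "chr9")
})

test_that("over-representation test matches the exact hypergeometric tail", {
  universe <- paste0("g", 1:100)
  sets <- list(hit_set = paste0("g", 1:10), other = paste0("g", 51:60))
  query <- c(paste0("g", 1:5), paste0("g", 90:94))
  res <- enrichment_test(query, sets, universe)
  row <- res[res$set == "hit_set", ]
  expect_equal(row$overlap, 5)
  expect_equal(row$p, phyper(4, 10, 90, 10, lower.tail = FALSE))
  expect_equal(row$p, 1.622087e-4, tolerance = 1e-3)

  # disjoint query and whole-universe set are both uninformative (p = 1)
  res2 <- enrichment_test(paste0("g", 90:99), sets, universe)
  expect_equal(res2$p[res2$set == "other"], 1)
  res_u <- enrichment_test(query, list(all = universe), universe)
  expect_equal(res_u$p, 1)

  expect_warning(enrichment_test(c("g1", "zz"), sets, universe), "dropped")
  expect_error(enrichment_test("g1", sets, character(0)), "empty")
})

test_that("GMT files round-trip", {
  path <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg4"), path)
  sets <- read_gmt(path)
  expect_equal(sets, list(setA = c("g1", "g2", "g3"), setB = "g4"))
})
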