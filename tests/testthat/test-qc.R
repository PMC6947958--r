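test_that("beta computation follows the signal-ratio definition", {
  expect_equal(compute_beta(300, 100), 0.75)
  expect_equal(compute_beta(100, 300), 0.25)
  expect_true(is.na(compute_beta(0, 0)))
  expect_error(compute_beta(-1, 5), "non-negative")
  m <- matrix(c(300, 0, 100, 0), 2, 2)
  u <- matrix(c(100, 0, 300, 0), 2, 2)
  expect_equal(compute_beta(m, u)[1, ], c(0.75, 0.25))
  expect_true(all(is.na(compute_beta(m, u)[2, ])))
})

make_qc_fixture <- function() {
  probes <- sprintf("cg%03d", 1:6)
  beta <- matrix(0.5, 6, 3, dimnames = list(probes, c("s1", "s2", "s3")))
  detp <- matrix(0.001, 6, 3, dimnames = dimnames(beta))
  detp["cg002", "s2"] <- 0.02          # fails detection in one sample
  manifest <- data.frame(
    probe_id = probes,
    chrom = c("1", "2", "X", "Y", "3", "4"),
    pos = 1:6 * 100L,
    is_snp = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    is_crossreactive = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    on_450k = TRUE, on_epic = TRUE, stringsAsFactors = FALSE)
  list(beta = beta, detp = detp, manifest = manifest)
}

test_that("probe filtering applies every exclusion rule and reports counts", {
  fx <- make_qc_fixture()
  qc <- filter_probes(fx$beta, fx$detp, fx$manifest)
  expect_setequal(rownames(qc$beta), "cg001")
  expect_equal(qc$removed$detection, "cg002")
  expect_setequal(qc$removed$sex_chromosome, c("cg003", "cg004"))
  expect_equal(qc$removed$snp, "cg005")
  expect_equal(qc$removed$cross_reactive, "cg006")
  expect_equal(unname(qc$counts["total_removed"]), 5L)
  expect_equal(unname(qc$counts["retained"]), 1L)
  # per-reason sets union to the removed set (set algebra exact)
  expect_setequal(unique(unlist(qc$removed)),
                  setdiff(rownames(fx$beta), rownames(qc$beta)))
})

test_that("probe filtering is idempotent and rejects unmapped probes", {
  fx <- make_qc_fixture()
  once <- filter_probes(fx$beta, fx$detp, fx$manifest)
  twice <- filter_probes(once$beta, fx$detp[rownames(once$beta), , drop = FALSE],
                         fx$manifest)
  expect_identical(once$beta, twice$beta)
  rownames(fx$beta)[1] <- "cg999"
  expect_error(filter_probes(fx$beta, NULL, fx$manifest), "absent")
})

test_that("failed arrays are dropped above (not at) the 5% failure rate", {
  detp <- matrix(0.001, 100, 3,
                 dimnames = list(NULL, c("bad", "edge", "good")))
  detp[1:6, "bad"] <- 0.02     # 6% failing
  detp[1:5, "edge"] <- 0.02    # exactly 5% -> retained
  res <- filter_failed_arrays(detp)
  expect_equal(res$dropped, "bad")
  expect_setequal(res$retained, c("edge", "good"))
})

test_that("sex prediction recovers simulated sex and flags mislabels", {
  ref <- make_test_reference(n_probes = 3000, seed = 21)
  co <- make_test_cohort(ref, seed = 22, n_probes = 3000L,
                         n_signature_probes = 0L, n_dmr_blocks = 0L,
                         n_controls = 30L)
  ps <- predict_sex(co$meth, co$unmeth, co$manifest, co$sheet)
  expect_equal(ps$prediction$predicted_sex,
               co$sheet$sex[match(ps$prediction$sample_id, co$sheet$sample_id)])
  expect_length(ps$discordant, 0)

  sheet_bad <- co$sheet
  flip <- sheet_bad$sample_id[1]
  sheet_bad$sex[1] <- setdiff(c("M", "F"), sheet_bad$sex[1])
  ps2 <- predict_sex(co$meth, co$unmeth, co$manifest, sheet_bad)
  expect_equal(ps2$discordant, flip)

  # single-sex cohort: clustering collapses, fixed-threshold fallback warns
  fem <- co$sheet$sample_id[co$sheet$sex == "F"]
  expect_warning(
    ps3 <- predict_sex(co$meth[, fem], co$unmeth[, fem], co$manifest),
    "separated")
  expect_true(all(ps3$prediction$predicted_sex == "F"))

  expect_error(predict_sex(co$meth[co$manifest$chrom == "1", ],
                           co$unmeth[co$manifest$chrom == "1", ],
                           co$manifest), "chromosome X/Y")
})

test_that("bimodality check passes clean arrays and fails flat ones", {
  ref <- make_test_reference(n_probes = 2000, seed = 23)
  co <- make_test_cohort(ref, seed = 24, n_probes = 2000L,
                         n_signature_probes = 0L, n_dmr_blocks = 0L,
                         n_controls = 10L)
  expect_true(all(bimodality_check(co$beta)$pass))

  set.seed(1)
  uni <- matrix(runif(2000 * 2), 2000, 2, dimnames = list(NULL, c("u1", "u2")))
  chk <- bimodality_check(uni)
  expect_false(any(chk$pass))
  expect_equal(chk$mid_fraction, c(0.4, 0.4), tolerance = 0.05)

  extreme <- matrix(rep(c(0, 1), 1000), 2000, 2,
                    dimnames = list(NULL, c("e1", "e2")))
  expect_true(all(bimodality_check(extreme)$pass))
  expect_error(bimodality_check(uni[1:500, , drop = FALSE]), "1000")
})

test_that("PCA outlier flagging is quiet on homogeneous cohorts and catches shifts", {
  # homogeneous null: flags are rare (robust-scale false positives only)
  set.seed(42)
  flags <- replicate(60, {
    b <- matrix(rbeta(2000 * 20, 2, 2), 2000, 20,
                dimnames = list(NULL, paste0("s", 1:20)))
    length(pca_outliers(b))
  })
  expect_gt(mean(flags == 0), 0.85)
  expect_lt(mean(flags) / 20, 0.02)

  # a globally shifted sample is always flagged
  set.seed(43)
  b <- matrix(rbeta(2000 * 20, 2, 2), 2000, 20,
              dimnames = list(NULL, paste0("s", 1:20)))
  b[, 7] <- pmin(b[, 7] + 0.3, 1)
  expect_true("s7" %in% pca_outliers(b))

  # degenerate threshold flags everything (even n: no sample sits on the median)
  expect_length(pca_outliers(b, k_sd = 0), 20)
  expect_error(pca_outliers(b[, 1:2]), "3 samples")
})
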