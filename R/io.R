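#' Write a simulated cohort to plain-text files
#'
#' Emits the standard file set: beta TSV (probes as rows, sample-id header),
#' methylated/unmethylated signal TSVs, detection-p TSV, manifest CSV,
#' sample sheet CSV and a truth JSON.
#'
#' @param cohort An `episim_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "episim_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(beta = file.path(dir, "beta.tsv"),
             meth = file.path(dir, "meth.tsv"),
             unmeth = file.path(dir, "unmeth.tsv"),
             detp = file.path(dir, "detp.tsv"),
             manifest = file.path(dir, "manifest.csv"),
             sheet = file.path(dir, "sample_sheet.csv"),
             truth = file.path(dir, "truth.json"))
  for (nm in c("beta", "meth", "unmeth", "detp"))
    .write_matrix_tsv(cohort[[nm]], paths[[nm]])
  data.table::fwrite(cohort$manifest, paths[["manifest"]])
  data.table::fwrite(cohort$sheet, paths[["sheet"]])
  truth <- cohort$truth
  truth$W <- as.data.frame(truth$W)
  truth$W$sample_id <- rownames(cohort$truth$W)
  jsonlite::write_json(truth, paths[["truth"]], digits = NA, dataframe = "columns")
  invisible(paths)
}

.write_matrix_tsv <- function(m, path) {
  dt <- data.table::as.data.table(m, keep.rownames = "probe_id")
  data.table::fwrite(dt, path, sep = "\t")
}

#' Read a probe x sample matrix from TSV
#'
#' Expects a `probe_id` first column (as written by [write_cohort()]) and
#' sample ids in the header.
#'
#' @param path TSV file path.
#' @return Numeric matrix with probe rownames and sample colnames.
#' @export
read_beta_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt[[1]]
  m
}

#' Read a probe manifest CSV
#' @param path CSV path with columns `probe_id`, `chrom`, `pos`, `is_snp`,
#'   `is_crossreactive`, `on_450k`, `on_epic`.
#' @return data.frame.
#' @export
read_manifest <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  need <- c("probe_id", "chrom", "pos", "is_snp", "is_crossreactive",
            "on_450k", "on_epic")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("manifest lacks columns: ", paste(miss, collapse = ", "))
  df$chrom <- as.character(df$chrom)
  df
}

#' Read a sample sheet CSV
#' @param path CSV path with columns `sample_id`, `group`, `age_years`,
#'   `sex`, `batch`, `array_type`.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  miss <- setdiff(c("sample_id", "sex", "age_years"), names(df))
  if (length(miss)) stop("sample sheet lacks columns: ",
                         paste(miss, collapse = ", "))
  df
}

#' Export a DMR table as BED6
#'
#' Converts the 1-based inclusive region coordinates to BED's 0-based
#' half-open convention. Scores are the Stouffer Z magnitudes.
#'
#' @param dmr A `dmr_table`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_dmr_bed <- function(dmr, path) {
  bed <- data.frame(chrom = dmr$chrom, start = dmr$start - 1L, end = dmr$end,
                    name = sprintf("DMR_%03d", seq_len(nrow(dmr))),
                    score = round(abs(dmr$stouffer_z), 3),
                    strand = ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
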