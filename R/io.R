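#' Read a beta-value matrix with its pairing manifest
#'
#' @param beta_tsv TSV with probe ids in the first column and one column
#'   per sample.
#' @param pairs_csv CSV with columns `sample_id`, `model_id`, `tissue`.
#' @return A [beta_matrix].
#' @export
read_beta_matrix <- function(beta_tsv, pairs_csv) {
  df <- read.delim(beta_tsv, check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  rownames(vals) <- df[[1L]]
  beta_matrix(vals, read.csv(pairs_csv, stringsAsFactors = FALSE))
}

#' Write a beta matrix and its pairing manifest
#' @param bm A [beta_matrix].
#' @param beta_tsv,pairs_csv Output paths.
#' @export
write_beta_matrix <- function(bm, beta_tsv, pairs_csv) {
  df <- data.frame(probe_id = rownames(bm$values), bm$values,
                   check.names = FALSE)
  write.table(df, beta_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  write.csv(bm$pairing, pairs_csv, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' Read a variant pair table
#' @param path TSV with the `VariantPair` columns (`model_id`, `chrom`,
#'   `pos`, `ref`, `alt`, `gene`, `effect_class`, `maf_primary`,
#'   `maf_xeno`, `depth_primary`, `depth_xeno`).
#' @return Data frame.
#' @export
read_variants <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(chrom = "character"))
}

#' Read a signal track TSV
#' @param path TSV with columns `probe_id`, `chrom`, `pos`, `total_signal`,
#'   `gc`, `probe_type`.
#' @return A [signal_track].
#' @export
read_signal_track <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(chrom = "character"))
  signal_track(df$probe_id, df$chrom, df$pos, df$total_signal, df$gc,
               df$probe_type)
}

#' Write a state-called segment profile as BED-like TSV
#'
#' Intervals are written 0-based half-open over probe indices (stated in
#' the header comment).
#' @param profile A state-called `segment_profile`.
#' @param path Output path.
#' @export
write_segments <- function(profile, path) {
  con <- file(path, "w")
  writeLines("# probe-index intervals, 0-based half-open", con)
  df <- data.frame(chrom = profile$chrom, start = profile$start - 1L,
                   end = profile$end, mean = profile$mean,
                   state = if (is.null(profile$state)) NA else
                     as.character(profile$state))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(NULL)
}

#' Read growth curves for response analysis
#'
#' @param path CSV with columns `model_id`, `arm`, `mouse_id`, `day`, and
#'   either `volume_cm3` or `diameter_mm` (converted via
#'   [volume_from_diameter()]).
#' @return Data frame with `model_id`, `arm`, `mouse_id`, `day`, `volume`.
#' @export
read_growth <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if ("volume_cm3" %in% names(df)) {
    df$volume <- df$volume_cm3
  } else if ("diameter_mm" %in% names(df)) {
    df$volume <- volume_from_diameter(df$diameter_mm / 10)
  } else {
    stop("growth file needs a volume_cm3 or diameter_mm column")
  }
  df[, c("model_id", "arm", "mouse_id", "day", "volume")]
}

#' Read an expression matrix with pairing
#' @param fpkm_tsv TSV of raw FPKM values, gene ids in the first column.
#' @param pairs_csv CSV with `sample_id`, `model_id`, `tissue`.
#' @return An [expression_matrix] (transformed and filtered).
#' @export
read_expression <- function(fpkm_tsv, pairs_csv) {
  df <- read.delim(fpkm_tsv, check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  rownames(vals) <- df[[1L]]
  transform_filter(vals, read.csv(pairs_csv, stringsAsFactors = FALSE))
}

#' Read gene sets in GMT format
#' @param path GMT file (set name, description, member genes, tab-separated).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t")[[1L]]
    f[-(1:2)]
  })
  names(out) <- vapply(lines, function(l) strsplit(l, "\t")[[1L]][1L], "")
  out
}
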