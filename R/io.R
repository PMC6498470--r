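#' Write and read the tabular interchange files
#'
#' Beta matrices travel as TSV with probes as rows, samples as columns and
#' `NA` for missing values, alongside a sample sheet (`sample`,
#' `condition`, `timepoint_days`, `replicate`). Manifests, Cq tables and
#' reports are plain TSV with a header row.
#'
#' @param betas A [beta_matrix()].
#' @param beta_path,samples_path Output paths.
#' @return Paths, invisibly.
#' @rdname epimem-io
#' @export
write_beta_tsv <- function(betas, beta_path, samples_path) {
  stopifnot(inherits(betas, "beta_matrix"))
  df <- data.frame(probe = rownames(betas$beta), betas$beta,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, beta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(betas$samples, samples_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(beta_path, samples_path))
}

#' @param beta_path,samples_path Paths written by [write_beta_tsv()].
#' @rdname epimem-io
#' @export
read_beta_tsv <- function(beta_path, samples_path) {
  df <- utils::read.table(beta_path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  samples <- utils::read.table(samples_path, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
  b <- as.matrix(df[, -1, drop = FALSE])
  rownames(b) <- df$probe
  beta_matrix(b, samples)
}

#' @param df Any data.frame (manifest, Cq table, report).
#' @param path Output path.
#' @rdname epimem-io
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname epimem-io
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
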