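#' Read and write the pipeline's tabular formats
#'
#' Plain-TSV readers/writers for expression matrices (features x samples,
#' first column = feature id), clinical tables, DE tables and TSS tables,
#' plus BED peak IO through `rtracklayer` and a GMT gene-set reader. All
#' writers round-trip losslessly through the matching reader.
#'
#' @param x object to write (matrix or data.frame as appropriate).
#' @param path file path.
#' @name pipeline-io
NULL

#' @rdname pipeline-io
#' @export
writeExpressionTSV <- function(x, path) {
  df <- data.frame(feature = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline-io
#' @export
readExpressionTSV <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname pipeline-io
#' @export
writeTableTSV <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline-io
#' @export
readDETable <- function(path) {
  de <- utils::read.delim(path)
  assertDETable(de, what = basename(path))
  de
}

#' @rdname pipeline-io
#' @export
readClinicalTSV <- function(path) {
  utils::read.delim(path)
}

#' @rdname pipeline-io
#' @export
readTssTSV <- function(path) {
  tss <- utils::read.delim(path)
  need <- c("gene", "chrom", "strand", "tss")
  missing <- setdiff(need, colnames(tss))
  if (length(missing))
    stop("TSS table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(tss$tss < 1))
    stop("TSS positions are 1-based and must be >= 1", call. = FALSE)
  tss
}

#' @rdname pipeline-io
#' @export
writePeaksBED <- function(x, path) {
  stopifnot(is(x, "GRanges"))
  rtracklayer::export(x, path, format = "BED")
  invisible(path)
}

#' @rdname pipeline-io
#' @export
readPeaksBED <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' @rdname pipeline-io
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(f) f[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t"), `[[`, character(1), 1L)
  sets
}

#' @rdname pipeline-io
#' @export
writeGMT <- function(x, path) {
  stopifnot(is.list(x), !is.null(names(x)))
  lines <- vapply(names(x), function(nm)
    paste(c(nm, "synthetic", x[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a simulation config (YAML or JSON) into generator specs
#'
#' The config file mirrors the spec constructors: top-level blocks
#' `cohort`, `de`, `cistrome` and `genesets`, each holding the arguments
#' of [cohortSpec()], [deExperimentSpec()], [cistromeSpec()] and
#' [simulateGeneSets()] respectively. Gene-id shorthand `"1:50"` is
#' expanded against the block's gene universe.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON config file.
#' @return named list of config blocks (plain lists).
#' @export
readSimulationConfig <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::read_json(path, simplifyVector = TRUE)
  cfg
}

#' Expand `"a:b"` index shorthand into gene ids
#'
#' Simulation configs may give planted gene subsets as an index range
#' string (e.g. `"1:50"`), expanded against the block's gene universe.
#' Anything else is returned unchanged.
#'
#' @param x shorthand string or a character vector of ids.
#' @param nGenes universe size of the config block.
#' @return character vector of gene ids.
#' @export
expandGeneRange <- function(x, nGenes) {
  if (is.character(x) && length(x) == 1L && grepl("^[0-9]+:[0-9]+$", x)) {
    idx <- as.integer(strsplit(x, ":")[[1]])
    return(geneIds(nGenes)[idx[1]:idx[2]])
  }
  x
}
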