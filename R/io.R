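#' @importFrom utils read.delim write.table head combn packageVersion
NULL

#' Write a folded joint SFS in the .obs text dialect
#'
#' Writes the fastsimcoal-style observed-SFS text layout: a first line
#' "1 observations", a tab-separated header of column labels
#' \code{d0_0..d0_n2} and one labelled row \code{d1_i} per row of the
#' matrix (rows = population 1).
#'
#' @param jsfs a \linkS4class{JointFoldedSFS}.
#' @param path output file.
#' @export
writeJointSFSObs <- function(jsfs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("1 observations", con)
  writeLines(paste(c("", paste0("d0_", 0:jsfs@n2)), collapse = "\t"), con)
  for (i in 0:jsfs@n1)
    writeLines(paste(c(paste0("d1_", i),
                       format(jsfs@mat[i + 1, ], trim = TRUE,
                              scientific = FALSE)), collapse = "\t"), con)
  invisible(path)
}

#' Read a folded joint SFS from the .obs text dialect
#'
#' @param path .obs file written by \code{\link{writeJointSFSObs}} (or by
#'   compatible tools: one header line, a labelled column row, labelled
#'   matrix rows).
#' @param popNames optional character(2) population labels.
#' @return a \linkS4class{JointFoldedSFS}.
#' @export
readJointSFSObs <- function(path, popNames = c("pop1", "pop2")) {
  lines <- readLines(path)
  if (!grepl("observation", lines[1]))
    stop("not an .obs file: missing observations header")
  body <- strsplit(lines[-(1:2)], "\t")
  mat <- do.call(rbind, lapply(body, function(x) as.numeric(x[-1])))
  n1 <- nrow(mat) - 1L
  n2 <- ncol(mat) - 1L
  new("JointFoldedSFS", mat = mat, n1 = n1, n2 = n2, popNames = popNames)
}

#' Read / write long allele-count tables
#'
#' TSV with columns chrom, pos (1-based), gene_id (optional), pop, count
#' (same-allele count) and n (sampled alleles).
#'
#' @param path file path.
#' @return data.frame (validated).
#' @export
readAlleleCounts <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  validateAlleleCounts(x)
  x
}

#' @rdname readAlleleCounts
#' @param counts allele-count table.
#' @export
writeAlleleCounts <- function(counts, path) {
  validateAlleleCounts(counts)
  write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene x sample count matrix and its sample sheet
#'
#' \code{readCountsMatrix}: TSV of integer counts, first column gene ids,
#' header row of sample ids. \code{readSampleSheet}: TSV with columns
#' sample, pair, ecotype.
#'
#' @param path file path.
#' @return matrix / data.frame.
#' @export
readCountsMatrix <- function(path) {
  x <- read.delim(path, row.names = 1, check.names = FALSE)
  as.matrix(x)
}

#' @rdname readCountsMatrix
#' @export
readSampleSheet <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "pair", "ecotype") %in% colnames(x)))
  x
}

#' Read / write gene-set collections as TSV
#'
#' Sets as a two-column TSV (set_name, gene_id); the background universe as
#' a one-column list.
#'
#' @param setsPath two-column TSV path.
#' @param backgroundPath one-gene-per-line file.
#' @return a \linkS4class{GeneSetCollection}.
#' @export
readGeneSets <- function(setsPath, backgroundPath) {
  x <- read.delim(setsPath, stringsAsFactors = FALSE)
  stopifnot(all(c("set_name", "gene_id") %in% colnames(x)))
  bg <- readLines(backgroundPath)
  geneSetCollection(split(x$gene_id, x$set_name), bg)
}

#' @rdname readGeneSets
#' @param collection a \linkS4class{GeneSetCollection}.
#' @export
writeGeneSets <- function(collection, setsPath, backgroundPath) {
  sets <- geneSets(collection)
  df <- data.frame(
    set_name = rep(names(sets), vapply(sets, length, integer(1))),
    gene_id = unlist(sets, use.names = FALSE))
  write.table(df, setsPath, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(background(collection), backgroundPath)
  invisible(setsPath)
}
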