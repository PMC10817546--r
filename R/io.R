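#' Read a FASTQ file (Phred+33)
#'
#' Strict four-line-record parser; sequence characters outside A/C/G/T/N
#' are rejected with the offending line number, as are malformed headers
#' and length mismatches.
#'
#' @param path FASTQ file.
#' @return Data frame: id, sequence, qualities.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ: line count not a multiple of 4 in ", path)
  n <- length(lines) %/% 4L
  ids <- character(n); seqs <- character(n); quals <- character(n)
  for (i in seq_len(n)) {
    off <- (i - 1L) * 4L
    if (!startsWith(lines[off + 1L], "@"))
      stop("malformed FASTQ record at line ", off + 1L, ": missing '@'")
    bad <- regexpr("[^ACGTN]", lines[off + 2L])
    if (bad > 0)
      stop("non-ACGTN character at line ", off + 2L, ", position ", bad)
    if (lines[off + 3L] != "+" && !startsWith(lines[off + 3L], "+"))
      stop("malformed FASTQ record at line ", off + 3L)
    if (nchar(lines[off + 2L]) != nchar(lines[off + 4L]))
      stop("sequence/quality length mismatch at line ", off + 4L)
    ids[i] <- sub("^@", "", strsplit(lines[off + 1L], " ")[[1]][1])
    seqs[i] <- lines[off + 2L]
    quals[i] <- lines[off + 4L]
  }
  data.frame(id = ids, sequence = seqs, qualities = quals,
             stringsAsFactors = FALSE)
}

#' Write a FASTQ file (Phred+33)
#'
#' @param ids,seqs,quals Parallel vectors of record fields.
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_fastq <- function(ids, seqs, quals, path) {
  stopifnot(length(ids) == length(seqs), length(seqs) == length(quals))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(ids))
    writeLines(paste0("@", ids, "\n", seqs, "\n+\n", quals), con, sep = "\n")
  invisible(path)
}

#' Read/write FASTA
#'
#' Thin wrappers over Biostrings; sequences are uppercased and U mapped to
#' T on input.
#'
#' @param path File path.
#' @return `read_fasta`: named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(x))
  out <- gsub("U", "T", out, fixed = TRUE)
  stats::setNames(out, names(x))
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read/write Newick trees (supports kept as internal node labels)
#'
#' @param path File path.
#' @return `read_newick`: an `ape::phylo`.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' @rdname read_newick
#' @param tree An `ape::phylo`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, path)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
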