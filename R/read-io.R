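#' Read a FASTQ file into a DataFrame of reads
#'
#' Parses plain or gzip-compressed 4-line FASTQ (Sanger/offset-33 qualities,
#' the encoding emitted by nanopore basecallers; no offset auto-detection).
#' Bases are uppercase-normalised on input; quality strings are untouched.
#'
#' @param path path to a \code{.fastq} or \code{.fastq.gz} file.
#' @return \link[S4Vectors]{DataFrame} with columns \code{read_id} (header
#'   token up to the first whitespace, without the leading \code{@}),
#'   \code{seq} (uppercase, alphabet ACGTN) and \code{qual} (offset-33 Phred
#'   string, same length as \code{seq}). An empty file yields zero rows.
#' @details Malformed records are hard errors naming the 1-based record
#'   number: a header not starting with \code{@}, a separator line not
#'   starting with \code{+}, a base outside ACGTN, or a quality string whose
#'   length differs from the sequence.
#' @examples
#' fq <- file.path(tempdir(), "ex.fastq")
#' writeLines(c("@r1", "ACGT", "+", "!!!!"), fq)
#' readFastq(fq)
#' @export
readFastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  n <- length(lines)
  if (n == 0L)
    return(DataFrame(read_id = character(), seq = character(),
                     qual = character()))
  if (n %% 4L != 0L)
    stop("truncated FASTQ: ", n, " lines is not a multiple of 4")
  hd <- lines[seq(1L, n, by = 4L)]
  sq <- toupper(lines[seq(2L, n, by = 4L)])
  pl <- lines[seq(3L, n, by = 4L)]
  ql <- lines[seq(4L, n, by = 4L)]

  bad <- which(!startsWith(hd, "@"))
  if (length(bad))
    stop("FASTQ record ", bad[1L], ": header does not start with '@'")
  bad <- which(!startsWith(pl, "+"))
  if (length(bad))
    stop("FASTQ record ", bad[1L], ": missing '+' separator line")
  bad <- which(nchar(sq) != nchar(ql))
  if (length(bad))
    stop("FASTQ record ", bad[1L],
         ": sequence and quality lengths differ (",
         nchar(sq[bad[1L]]), " vs ", nchar(ql[bad[1L]]), ")")
  bad <- which(grepl("[^ACGTN]", sq))
  if (length(bad))
    stop("FASTQ record ", bad[1L], ": sequence contains non-ACGTN characters")

  id <- sub("^@", "", hd)
  id <- sub("[ \t].*$", "", id)
  DataFrame(read_id = id, seq = sq, qual = ql)
}

#' Write reads to a FASTQ file
#'
#' @param x DataFrame or data.frame with columns \code{read_id}, \code{seq},
#'   \code{qual} (as returned by \code{\link{readFastq}}).
#' @param path output path; a \code{.gz} suffix triggers gzip compression.
#' @return \code{path}, invisibly.
#' @export
writeFastq <- function(x, path) {
  stopifnot(all(c("read_id", "seq", "qual") %in% colnames(x)))
  if (any(nchar(x$seq) != nchar(x$qual)))
    stop("sequence and quality lengths differ")
  lines <- as.vector(rbind(paste0("@", x$read_id), x$seq, "+", x$qual))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Decode an offset-33 Phred quality string to integer scores
#'
#' @param qual a single quality string.
#' @return integer vector of Phred scores, one per character.
#' @examples
#' phredToInt("!?I")  # 0, 30, 40
#' @export
phredToInt <- function(qual) {
  stopifnot(length(qual) == 1L)
  if (nchar(qual) == 0L) return(integer())
  q <- as.integer(charToRaw(qual)) - 33L
  if (any(q < 0L | q > 93L))
    stop("quality character outside the offset-33 Phred range [0, 93]")
  q
}

#' Encode integer Phred scores as an offset-33 quality string
#'
#' @param q integer vector of Phred scores in [0, 93].
#' @return a single quality string.
#' @export
intToPhred <- function(q) {
  q <- as.integer(q)
  if (length(q) && (any(q < 0L) || any(q > 93L)))
    stop("Phred scores must lie in [0, 93]")
  rawToChar(as.raw(q + 33L))
}

#' Reverse-complement DNA strings
#'
#' Standard complement (N maps to N), reversed. Characters outside the IUPAC
#' DNA alphabet are a hard error.
#'
#' @param x character vector of DNA strings over ACGTN.
#' @return character vector of reverse complements.
#' @examples
#' revComp(c("ACGT", "AAAC"))  # "ACGT" "GTTT"
#' @export
revComp <- function(x) {
  if (!length(x)) return(character())
  as.character(reverseComplement(DNAStringSet(x)))
}

# Reverse quality strings so they stay base-aligned after revComp().
reverseQual <- function(qual) {
  if (!length(qual)) return(character())
  as.character(reverse(BStringSet(qual)))
}
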