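#' Read sets
#'
#' A `read_set` is the package's lightweight container for sequencing reads:
#' parallel vectors of identifiers, uppercase DNA sequences over
#' \{A,C,G,T,N\}, and (optionally) per-base PHRED qualities kept in their
#' compact Phred+33 string encoding. Long reads typically carry no qualities;
#' short reads always do.
#'
#' @param id character vector of read identifiers.
#' @param seq character vector of DNA sequences (coerced to uppercase;
#'   `U` becomes `T`, other ambiguity codes become `N`).
#' @param qual optional character vector of Phred+33 quality strings, one per
#'   read and of matching length.
#' @return An object of class `read_set`.
#' @examples
#' rs <- read_set(c("r1", "r2"), c("ACGT", "GGGA"))
#' length(rs)
#' @export
read_set <- function(id, seq, qual = NULL) {
  id <- as.character(id)
  seq <- normalize_dna(seq)
  if (length(id) != length(seq))
    stop("id and seq must have equal length")
  if (anyDuplicated(id))
    stop("duplicate read identifiers: ", paste(head(id[duplicated(id)], 3), collapse = ", "))
  if (!is.null(qual)) {
    qual <- as.character(qual)
    if (length(qual) != length(seq))
      stop("qual must match seq in length")
    bad <- which(nchar(qual) != nchar(seq))
    if (length(bad))
      stop("quality string length does not match sequence length for read '",
           id[bad[1]], "'")
  }
  structure(list(id = id, seq = seq, qual = qual), class = "read_set")
}

normalize_dna <- function(x) {
  x <- toupper(as.character(x))
  x <- chartr("U", "T", x)
  # fold any remaining IUPAC ambiguity code into N
  gsub("[^ACGTN]", "N", x)
}

#' @export
length.read_set <- function(x) length(x$id)

#' @export
`[.read_set` <- function(x, i) {
  read_set(x$id[i], x$seq[i], if (!is.null(x$qual)) x$qual[i])
}

#' @export
print.read_set <- function(x, ...) {
  n <- length(x)
  cat("read_set with", n, "read(s)",
      if (!is.null(x$qual)) "(with qualities)" else "(no qualities)", "\n")
  if (n > 0) {
    show <- head(seq_len(n), 5)
    for (i in show)
      cat(sprintf("  %s  [%d bp]\n", x$id[i], nchar(x$seq[i])))
    if (n > 5) cat("  ...\n")
  }
  invisible(x)
}

#' @export
as.data.frame.read_set <- function(x, ...) {
  data.frame(id = x$id, seq = x$seq,
             qual = if (is.null(x$qual)) NA_character_ else x$qual,
             stringsAsFactors = FALSE)
}

#' Decode and encode PHRED qualities (Phred+33)
#'
#' @param qstr character vector of Phred+33 strings.
#' @return `phred_decode`: a list of integer vectors of per-base qualities.
#' @examples
#' phred_decode("II!")[[1]]   # 40 40 0
#' phred_encode(c(40, 0))
#' @export
phred_decode <- function(qstr) {
  lapply(qstr, function(s) {
    if (is.na(s) || !nzchar(s)) return(integer(0))
    utf8ToInt(s) - 33L
  })
}

#' @rdname phred_decode
#' @param q integer vector of PHRED scores in \[0, 93\].
#' @return `phred_encode`: a single Phred+33 string.
#' @export
phred_encode <- function(q) {
  q <- as.integer(q)
  if (any(q < 0L | q > 93L)) stop("PHRED scores must lie in [0, 93]")
  if (!length(q)) return("")
  intToUtf8(q + 33L)
}

sniff_format <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) return("empty")
    if (nzchar(trimws(line))) break
  }
  c1 <- substr(trimws(line), 1, 1)
  if (c1 == ">") "fasta" else if (c1 == "@") "fastq" else
    stop("cannot determine sequence format of ", path)
}

# Locate and report the first malformed FASTQ record (called on parse failure).
diagnose_fastq <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  i <- 1L
  while (i <= n) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    if (substr(lines[i], 1, 1) != "@")
      stop("malformed FASTQ in ", path, ": expected '@' at line ", i)
    if (i + 3L > n)
      stop("malformed FASTQ in ", path, ": truncated record at line ", i)
    id <- sub("\\s.*", "", sub("^@", "", lines[i]))
    sq <- lines[i + 1L]
    qu <- lines[i + 3L]
    if (substr(lines[i + 2L], 1, 1) != "+")
      stop("malformed FASTQ in ", path, ": record '", id,
           "' missing '+' separator at line ", i + 2L)
    if (nchar(sq) != nchar(qu))
      stop("malformed FASTQ in ", path, ": record '", id, "' at line ", i,
           " has sequence length ", nchar(sq), " but quality length ",
           nchar(qu))
    i <- i + 4L
  }
  invisible(TRUE)
}

#' Read sequences from FASTQ or FASTA
#'
#' `read_fastq()` sniffs the format: FASTQ records come back with Phred+33
#' qualities decoded on demand; FASTA records carry none. Sequences are
#' uppercased and `U` is converted to `T`. A FASTQ record whose quality string
#' does not match its sequence length is a hard error naming the record and
#' line.
#'
#' @param path path to a FASTQ or FASTA file.
#' @return A [read_set].
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  fmt <- sniff_format(path)
  if (fmt == "empty") return(read_set(character(0), character(0)))
  if (fmt == "fasta") {
    x <- Biostrings::readBStringSet(path, format = "fasta")
    return(read_set(sub("\\s.*", "", names(x)), as.character(x)))
  }
  parsed <- tryCatch({
    x <- Biostrings::readBStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
    list(seq = as.character(x),
         qual = as.character(S4Vectors::mcols(x)$qualities),
         id = sub("\\s.*", "", names(x)))
  }, error = function(e) {
    diagnose_fastq(path)  # raises a precise error if it finds the defect
    stop("failed to parse FASTQ ", path, ": ", conditionMessage(e))
  })
  seqs <- parsed$seq
  qual <- parsed$qual
  ids <- parsed$id
  bad <- which(nchar(qual) != nchar(seqs))
  if (length(bad)) {
    stop("malformed FASTQ in ", path, ": record '", ids[bad[1]],
         "' at line ", 4L * (bad[1] - 1L) + 1L,
         " has mismatched sequence/quality lengths")
  }
  read_set(ids, seqs, qual)
}

#' @rdname read_fastq
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readBStringSet(path, format = "fasta")
  read_set(sub("\\s.*", "", names(x)), as.character(x))
}

#' Write reads to FASTQ or FASTA
#'
#' Reads without stored qualities are written to FASTQ with a constant
#' placeholder quality (Q40). Output round-trips through [read_fastq()].
#'
#' @param reads a [read_set].
#' @param path output path.
#' @param format `"fastq"` or `"fasta"`.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  stopifnot(inherits(reads, "read_set"))
  n <- length(reads)
  if (n == 0L) {
    file.create(path)
    return(invisible(path))
  }
  x <- Biostrings::BStringSet(reads$seq)
  names(x) <- reads$id
  if (format == "fasta") {
    Biostrings::writeXStringSet(x, path, format = "fasta", width = 70L)
  } else {
    qual <- reads$qual
    if (is.null(qual)) qual <- strrep("I", nchar(reads$seq))
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(qual))
  }
  invisible(path)
}

#' @rdname write_fastq
#' @export
write_fasta <- function(reads, path) write_fastq(reads, path, format = "fasta")

#' Read short-read-to-long-read alignments from SAM
#'
#' Loads primary alignments of short reads against long reads. Unmapped
#' (0x4), secondary (0x100) and supplementary (0x800) records are skipped so
#' that each short read votes at most once per site; records referencing an
#' unknown long read are skipped with a warning; records without a CIGAR are
#' skipped. SAM's 1-based POS becomes the package's 0-based `start`.
#' Reverse-strand SEQ/QUAL are kept as stored in the SAM, i.e. already in
#' long-read orientation. Each record's alignment identity (exact matches
#' over short-read length) is computed on load.
#'
#' @param path path to a SAM file.
#' @param long_reads a [read_set] of the long reads the SAM refers to.
#' @return A `data.table` with columns `qname`, `rname`, `start` (0-based),
#'   `strand`, `cigar`, `seq`, `qual`, `identity`.
#' @export
read_sam <- function(path, long_reads) {
  if (!file.exists(path)) stop("no such file: ", path)
  stopifnot(inherits(long_reads, "read_set"))
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "cigar", "seq", "qual"))
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  dt <- data.table(
    qname = res$qname,
    flag = res$flag,
    rname = as.character(res$rname),
    strand = as.character(res$strand),
    start = res$pos - 1L,
    cigar = res$cigar,
    seq = as.character(res$seq),
    qual = as.character(res$qual))
  dt <- dt[bitwAnd(flag, 0x4L) == 0L & bitwAnd(flag, 0x100L) == 0L &
             bitwAnd(flag, 0x800L) == 0L & !is.na(cigar) & cigar != "*"]
  unknown <- setdiff(unique(dt$rname), long_reads$id)
  if (length(unknown)) {
    warning("skipping alignments to unknown long read(s): ",
            paste(head(unknown, 5), collapse = ", "))
    dt <- dt[!rname %in% unknown]
  }
  if (nrow(dt) == 0L) return(empty_alignments())
  llen <- setNames(nchar(long_reads$seq), long_reads$id)
  refw <- vapply(dt$cigar, cigar_ref_width_cpp, integer(1), USE.NAMES = FALSE)
  over <- dt$start + refw > llen[dt$rname]
  if (any(over))
    stop("alignment overruns long read bounds (first offender: ",
         dt$qname[which(over)[1]], ")")
  lseq <- setNames(long_reads$seq, long_reads$id)
  dt[, seq := normalize_dna(seq)]
  dt[, identity := mapply(aln_identity_cpp, start, cigar, seq, lseq[rname],
                          USE.NAMES = FALSE)]
  dt[, flag := NULL]
  setcolorder(dt, c("qname", "rname", "start", "strand", "cigar", "seq",
                    "qual", "identity"))
  dt[]
}

empty_alignments <- function() {
  data.table(qname = character(0), rname = character(0), start = integer(0),
             strand = character(0), cigar = character(0), seq = character(0),
             qual = character(0), identity = numeric(0))
}

#' Write alignments to SAM
#'
#' Emits a minimal valid SAM file (with `@SQ` header lines for the long
#' reads) from an alignment table as produced by [read_sam()] or the built-in
#' aligner. Reverse-strand records get flag 16; SEQ/QUAL are written as
#' stored, i.e. in long-read orientation.
#'
#' @param alignments alignment `data.table`.
#' @param long_reads a [read_set] of long reads (for the header).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, long_reads, path) {
  stopifnot(inherits(long_reads, "read_set"))
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", long_reads$id, nchar(long_reads$seq)))
  if (nrow(alignments)) {
    qual <- alignments$qual
    qual[is.na(qual) | !nzchar(qual)] <- "*"
    rec <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
                   alignments$qname,
                   ifelse(alignments$strand == "-", 16L, 0L),
                   alignments$rname,
                   alignments$start + 1L,
                   alignments$cigar,
                   alignments$seq,
                   qual)
  } else rec <- character(0)
  writeLines(c(hdr, rec), path)
  invisible(path)
}
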