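#' @noRd
kmer_set <- function(seqs, k, canonical = FALSE) {
  if (inherits(seqs, "read_set")) seqs <- seqs$seq
  k <- as.integer(k)
  stopifnot(k >= 1L)
  seqs <- seqs[nchar(seqs) >= k]
  if (!length(seqs)) return(character(0))
  km <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    substring(s, 1:(n - k + 1L), k:n)
  }), use.names = FALSE)
  km <- unique(km)
  km <- km[!grepl("N", km, fixed = TRUE)]  # windows containing N are skipped
  if (canonical && length(km)) {
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(km)))
    km <- unique(pmin(km, rc))
  }
  km
}

#' Count distinct k-mers in a read set
#'
#' The number of distinct length-`k` substrings across all reads. Windows
#' containing `N` are skipped. Errors inflate this count (each error creates
#' up to `k` novel k-mers), so for a fixed underlying genome a *smaller*
#' unique-k-mer count indicates better-corrected reads; the iterative loop
#' uses the relative drop in this count as its termination signal.
#'
#' @param reads a [read_set] or character vector of sequences.
#' @param k k-mer length (default 21).
#' @param canonical if `TRUE`, fold each k-mer with its reverse complement
#'   and count canonical k-mers instead.
#' @return Integer count.
#' @examples
#' unique_kmers("ACGTACGT", k = 3)  # 4
#' @export
unique_kmers <- function(reads, k = 21L, canonical = FALSE) {
  length(kmer_set(reads, k, canonical))
}

#' Count valid k-mers shared between long and short reads
#'
#' The size of the intersection between the distinct k-mers of the long
#' reads and those of the (accurate) short reads. A long-read k-mer also
#' seen in the short reads is very likely error-free, so a *larger* valid
#' count indicates better-corrected long reads.
#'
#' @param long_reads,short_reads [read_set]s or character vectors.
#' @inheritParams unique_kmers
#' @return Integer count.
#' @examples
#' valid_kmers("ACGT", "CGTA", k = 3)  # 1 ("CGT")
#' @export
valid_kmers <- function(long_reads, short_reads, k = 21L, canonical = FALSE) {
  length(intersect(kmer_set(long_reads, k, canonical),
                   kmer_set(short_reads, k, canonical)))
}

#' Truth-based alignment metrics on synthetic data
#'
#' Globally aligns each (corrected) long read against the reference interval
#' it was simulated from and reports percent identity (matches over
#' alignment length, including gap columns) and the matched-base fraction
#' (matches over read length). Only meaningful when the truth mapping is
#' known, i.e. on simulated reads.
#'
#' @param reads a [read_set] of (corrected) long reads.
#' @param truth_map `data.table`/data.frame with columns `id`, `ref_start`
#'   (0-based), `ref_end` (exclusive) as produced by
#'   [simulate_hybrid_data()].
#' @param reference reference sequence (character scalar).
#' @return A list with `per_read` (data.frame: `id`, `pi`, `matched`,
#'   `length`), `mean_pi` and `mean_matched`, percentages in \[0, 100\].
#' @export
truth_metrics <- function(reads, truth_map, reference) {
  stopifnot(inherits(reads, "read_set"))
  tm <- as.data.frame(truth_map)
  missing_ids <- setdiff(reads$id, tm$id)
  if (length(missing_ids))
    stop("no truth mapping for read(s): ",
         paste(head(missing_ids, 3), collapse = ", "))
  idx <- match(reads$id, tm$id)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
  pis <- numeric(length(reads))
  matched <- numeric(length(reads))
  for (i in seq_along(reads$id)) {
    truth <- substring(reference, tm$ref_start[idx[i]] + 1L,
                       tm$ref_end[idx[i]])
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(reads$seq[i]), Biostrings::DNAString(truth),
      type = "global", substitutionMatrix = mat,
      gapOpening = 2, gapExtension = 2)
    nm <- Biostrings::nmatch(aln)
    pis[i] <- 100 * nm / Biostrings::nchar(aln)
    matched[i] <- 100 * nm / nchar(reads$seq[i])
  }
  list(per_read = data.frame(id = reads$id, pi = pis, matched = matched,
                             length = nchar(reads$seq),
                             stringsAsFactors = FALSE),
       mean_pi = mean(pis), mean_matched = mean(matched))
}
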