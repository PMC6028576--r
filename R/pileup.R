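#' Alignment identity of one short read against a long read
#'
#' The similarity weight underlying optimization-based correction: the number
#' of exactly matching aligned bases divided by the full short-read length.
#' Soft-clipped bases therefore lower identity (they count in the denominator
#' but can never match), and `N` in either sequence never matches.
#'
#' @param start 0-based alignment start on the long read.
#' @param cigar CIGAR string (ops in `M=XIDSHN`).
#' @param short_seq short-read sequence as aligned (long-read orientation).
#' @param long_seq long-read sequence.
#' @return A fraction in \[0, 1\].
#' @examples
#' alignment_identity(0, "4=", "ACGT", "ACGTA")      # 1.0
#' alignment_identity(0, "2=1X1S", "ACGA", "ACTTT")  # 0.5
#' @export
alignment_identity <- function(start, cigar, short_seq, long_seq) {
  start <- as.integer(start)
  if (is.na(start) || start < 0L) stop("start must be a nonnegative integer")
  w <- cigar_ref_width_cpp(cigar)
  if (is.na(w)) stop("malformed CIGAR string: '", cigar, "'")
  if (start + w > nchar(long_seq))
    stop("alignment overruns long read bounds")
  aln_identity_cpp(start, cigar, normalize_dna(short_seq),
                   normalize_dna(long_seq))
}

#' Build a per-position evidence pileup over long reads
#'
#' Walks every primary alignment's CIGAR and records, for each long-read
#' position touched, the aligned short-read base with its PHRED quality.
#' Positions where at least one short read disagrees with the long read
#' (mismatch, or an insertion/deletion relative to it) are marked
#' *questionable*; agreeing reads at those positions are retained too so that
#' consensus fractions can be computed against the full covering depth.
#'
#' Edit semantics: a short-read insertion (CIGAR `I`) proposes an `INS` of
#' the extra bases at the inter-base locus before long-read position `pos`;
#' a short-read deletion (CIGAR `D`) proposes a `DEL` of the long-read base.
#' A `DEL` vote's quality is the floored mean PHRED of the two flanking
#' short-read bases; an `INS` vote's quality is the floored mean of the
#' inserted bases. `N` bases never vote.
#'
#' @param alignments alignment `data.table` from [read_sam()] or
#'   [align_short_reads()].
#' @param long_reads a [read_set] of long reads.
#' @return An object of class `pileup`: a list with
#'   \describe{
#'     \item{votes}{`data.table` of candidate votes at questionable sites
#'       (`rname`, `pos`, `is_ins`, `qname`, `type` in `SUB/DEL/INS`, `edit`,
#'       `q`, `identity`, `agree`, `coverage`, `long_base`).}
#'     \item{sites}{`data.table` of questionable sites with coverage and vote
#'       counts, sorted by read and position.}
#'     \item{coverage}{list of per-position integer coverage vectors, one per
#'       long read.}
#'   }
#' @export
build_pileup <- function(alignments, long_reads) {
  stopifnot(inherits(long_reads, "read_set"))
  lseq <- setNames(long_reads$seq, long_reads$id)
  llen <- nchar(lseq)
  cov <- lapply(llen, function(n) integer(n))
  covj <- lapply(llen, function(n) integer(n))  # inter-base (junction) depth
  votes_list <- list()
  if (nrow(alignments)) {
    alignments <- as.data.table(alignments)
    for (rn in unique(alignments$rname)) {
      sub <- alignments[rname == rn]
      L <- llen[[rn]]
      refw <- vapply(sub$cigar, cigar_ref_width_cpp, integer(1),
                     USE.NAMES = FALSE)
      # positional coverage via difference trick
      d <- integer(L + 1L)
      s <- pmin(sub$start, L - 1L) + 1L
      e <- pmin(sub$start + refw, L) + 1L
      for (i in seq_along(s)) {
        d[s[i]] <- d[s[i]] + 1L
        d[e[i]] <- d[e[i]] - 1L
      }
      cov[[rn]] <- cumsum(d[seq_len(L)])
      # junction coverage: alignments spanning positions j-1 and j
      dj <- integer(L + 1L)
      sj <- sub$start + 2L            # first spanned junction is start+1
      ej <- sub$start + refw          # last spanned junction is start+refw-1
      keep <- ej >= sj
      for (i in which(keep)) {
        dj[sj[i]] <- dj[sj[i]] + 1L
        dj[ej[i] + 1L] <- dj[ej[i] + 1L] - 1L
      }
      covj[[rn]] <- cumsum(dj[seq_len(L)])
      qual <- sub$qual
      qual[is.na(qual)] <- ""
      w <- pileup_walk_cpp(sub$start, sub$cigar, sub$seq, qual, lseq[[rn]])
      if (length(w$rec)) {
        v <- as.data.table(w)
        v[, rname := rn]
        v[, qname := sub$qname[rec]]
        v[, identity := sub$identity[rec]]
        votes_list[[rn]] <- v
      }
    }
  }
  if (length(votes_list)) {
    votes <- rbindlist(votes_list)
    votes[, rec := NULL]
    votes[, type := c("SUB", "DEL", "INS")[type + 1L]]
    votes[, agree := agree == 1L]
    # keep only questionable sites (>= 1 disagreeing vote)
    votes[, questionable := any(!agree), by = .(rname, pos, is_ins)]
    votes <- votes[questionable == TRUE][, questionable := NULL]
    if (nrow(votes)) {
      votes[, coverage := {
        cv <- if (is_ins[1] == 1L) covj[[rname[1]]] else cov[[rname[1]]]
        cv[pos + 1L]
      }, by = .(rname, is_ins)]
      votes[, long_base := ifelse(is_ins == 1L, "",
                                  substring(lseq[rname], pos + 1L, pos + 1L))]
      setorder(votes, rname, pos, is_ins)
    }
  } else {
    votes <- data.table(pos = integer(0), is_ins = integer(0),
                        type = character(0), edit = character(0),
                        q = integer(0), agree = logical(0),
                        rname = character(0), qname = character(0),
                        identity = numeric(0), coverage = integer(0),
                        long_base = character(0))
  }
  sites <- if (nrow(votes)) {
    votes[, .(long_base = long_base[1], coverage = coverage[1],
              n_votes = .N, n_disagree = sum(!agree)),
          by = .(rname, pos, is_ins)]
  } else {
    data.table(rname = character(0), pos = integer(0), is_ins = integer(0),
               long_base = character(0), coverage = integer(0),
               n_votes = integer(0), n_disagree = integer(0))
  }
  setorder(sites, rname, pos, is_ins)
  structure(list(votes = votes, sites = sites, coverage = cov),
            class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat("pileup:", nrow(x$sites), "questionable site(s) over",
      length(x$coverage), "long read(s)\n")
  invisible(x)
}

#' Extract a single questionable site from a pileup
#'
#' Returns one site's evidence in the per-site form consumed by
#' [quick_correct()] and [select_optimal()].
#'
#' @param pileup a [build_pileup()] result.
#' @param rname long-read identifier.
#' @param pos 0-based position on the long read.
#' @param is_ins `TRUE` for the inter-base insertion locus before `pos`.
#' @return A list with `long_read_id`, `position`, `is_insert`, `long_base`,
#'   `coverage` and a `votes` data.frame (`short_read_id`, `type`, `edit`,
#'   `q`, `identity`, `agree`), or `NULL` when the site is not questionable.
#' @export
site_evidence <- function(pileup, rname, pos, is_ins = FALSE) {
  stopifnot(inherits(pileup, "pileup"))
  ii <- as.integer(is_ins)
  rn <- rname
  pp <- as.integer(pos)
  v <- pileup$votes[rname == rn & pos == pp & is_ins == ii]
  if (!nrow(v)) return(NULL)
  list(long_read_id = rn, position = pp, is_insert = ii == 1L,
       long_base = v$long_base[1], coverage = v$coverage[1],
       votes = data.frame(short_read_id = v$qname, type = v$type,
                          edit = v$edit, q = v$q, identity = v$identity,
                          agree = v$agree, stringsAsFactors = FALSE))
}
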