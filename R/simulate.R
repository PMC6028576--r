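#' Simulation configuration
#'
#' Parameters of the synthetic hybrid-sequencing data generator. The
#' defaults describe the package's reference study conditions: a 50 kb
#' random reference, ~20 long reads of 5-10 kb carrying 15% uniformly
#' distributed errors split evenly between substitutions, insertions and
#' deletions, and 100 bp short reads at 50x coverage with 1% substitution
#' error and informative per-base qualities (correct bases around Q35,
#' erroneous bases around Q15).
#'
#' @param reference_length reference length in bp.
#' @param n_long number of long reads.
#' @param long_length length range `c(min, max)` of long reads.
#' @param long_error per-base error rate of long reads in \[0, 1\].
#' @param error_mix length-3 nonnegative vector (substitution, insertion,
#'   deletion fractions); normalised to sum to 1.
#' @param short_length short-read length in bp.
#' @param coverage target short-read coverage of the reference (x).
#' @param short_error per-base substitution error rate of short reads.
#' @param qual_mean,qual_sd PHRED quality model for correct short-read bases
#'   (normal, clamped to \[2, 41\]).
#' @param err_qual_mean,err_qual_sd quality model for erroneous bases.
#' @param seed RNG seed; the same configuration always yields byte-identical
#'   output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(reference_length = 50000L, n_long = 20L,
                       long_length = c(5000L, 10000L), long_error = 0.15,
                       error_mix = c(sub = 1, ins = 1, del = 1) / 3,
                       short_length = 100L, coverage = 50,
                       short_error = 0.01,
                       qual_mean = 35, qual_sd = 3,
                       err_qual_mean = 15, err_qual_sd = 4,
                       seed = 1L) {
  stopifnot(reference_length >= 1, n_long >= 1, length(long_length) == 2L,
            long_length[1] <= long_length[2],
            long_error >= 0, long_error <= 1,
            length(error_mix) == 3L, all(error_mix >= 0), sum(error_mix) > 0,
            short_length >= 1, coverage > 0,
            short_error >= 0, short_error <= 1)
  if (long_length[2] > reference_length)
    stop("long reads cannot be longer than the reference")
  if (short_length > reference_length)
    stop("short reads cannot be longer than the reference")
  structure(list(reference_length = as.integer(reference_length),
                 n_long = as.integer(n_long),
                 long_length = as.integer(long_length),
                 long_error = long_error,
                 error_mix = unname(error_mix / sum(error_mix)),
                 short_length = as.integer(short_length),
                 coverage = coverage, short_error = short_error,
                 qual_mean = qual_mean, qual_sd = qual_sd,
                 err_qual_mean = err_qual_mean, err_qual_sd = err_qual_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

BASES <- c("A", "C", "G", "T")

rand_other_base <- function(b) {
  # one uniform draw per base, excluding the current base
  alt <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G"),
                nrow = 3)
  alt[cbind(sample.int(3L, length(b), replace = TRUE), match(b, BASES))]
}

clamp_qual <- function(x) pmin(41L, pmax(2L, as.integer(round(x))))

#' Generate a synthetic hybrid-sequencing data set
#'
#' Produces a random reference, long reads sampled from it with uniformly
#' distributed substitution/insertion/deletion errors, short reads at the
#' configured coverage with per-base qualities, truth alignments of the
#' short reads against the *erroneous* long reads (obtained by lifting
#' reference coordinates through each long read's edit script, so no
#' aligner is involved), and the truth map needed by [truth_metrics()].
#' Every injected long-read error is recorded for later bookkeeping.
#'
#' @param config a [sim_config()].
#' @param dir optional directory; when given, the five outputs are also
#'   written as `reference.fasta`, `long_reads.fastq`, `short_reads.fastq`,
#'   `truth.sam` and `truth_map.tsv`.
#' @return A list with `reference` (character), `long_reads` and
#'   `short_reads` ([read_set]s), `alignments` (truth alignment
#'   `data.table`), `truth_map` (`data.table`: `id`, `ref_start`, `ref_end`,
#'   `strand`, `edit_script`), `injected` (`data.table` of injected
#'   long-read errors: `rname`, `pos` on the erroneous long read, `type`,
#'   `ref_base`, `alt`, `coverage_pos` flag), `config`, and (with `dir`)
#'   `files`.
#' @export
simulate_hybrid_data <- function(config = sim_config(), dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  Lref <- config$reference_length
  ref_chars <- sample(BASES, Lref, replace = TRUE)
  reference <- paste(ref_chars, collapse = "")

  # --- long reads with injected errors ------------------------------------
  long_ids <- sprintf("long_%03d", seq_len(config$n_long))
  long_seqs <- character(config$n_long)
  truth_map <- vector("list", config$n_long)
  injected <- vector("list", config$n_long)
  ref_maps <- vector("list", config$n_long)  # ref offset -> long pos (0-based)
  for (i in seq_len(config$n_long)) {
    len <- sample(config$long_length[1]:config$long_length[2], 1L)
    a <- sample(0:(Lref - len), 1L)
    slice <- ref_chars[(a + 1):(a + len)]
    chars <- slice
    is_err <- runif(len) < config$long_error
    etype <- character(len)
    alt <- character(len)
    idx <- which(is_err)
    if (length(idx)) {
      etype[idx] <- sample(c("sub", "ins", "del"), length(idx),
                           replace = TRUE, prob = config$error_mix)
      subs <- idx[etype[idx] == "sub"]
      if (length(subs)) {
        alt[subs] <- rand_other_base(slice[subs])
        chars[subs] <- alt[subs]
      }
      dels <- idx[etype[idx] == "del"]
      if (length(dels)) chars[dels] <- ""
      inss <- idx[etype[idx] == "ins"]
      if (length(inss)) {
        alt[inss] <- sample(BASES, length(inss), replace = TRUE)
        chars[inss] <- paste0(chars[inss], alt[inss])  # insert after the base
      }
    }
    widths <- nchar(chars)
    starts0 <- cumsum(widths) - widths           # 0-based start of each slot
    mp <- ifelse(widths == 0L, NA_integer_, as.integer(starts0))
    long_seqs[i] <- paste(chars, collapse = "")
    ref_maps[[i]] <- mp
    script <- if (length(idx)) {
      paste(sprintf("%d:%s:%s", idx - 1L, etype[idx], alt[idx]),
            collapse = ";")
    } else ""
    truth_map[[i]] <- data.table(id = long_ids[i], ref_start = a,
                                 ref_end = a + len, strand = "+",
                                 edit_script = script)
    if (length(idx)) {
      ipos <- integer(length(idx))
      for (jj in seq_along(idx)) {
        o <- idx[jj]
        ipos[jj] <- switch(etype[o],
          sub = mp[o],
          ins = mp[o] + 1L,          # the inserted base follows ref base o
          del = NA_integer_)
      }
      injected[[i]] <- data.table(rname = long_ids[i], ref_offset = idx - 1L,
                                  pos = ipos, type = etype[idx],
                                  ref_base = slice[idx], alt = alt[idx])
    }
  }
  long_reads <- read_set(long_ids, long_seqs)
  truth_map <- rbindlist(truth_map)
  injected <- if (length(Filter(Negate(is.null), injected)))
    rbindlist(Filter(Negate(is.null), injected))
  else data.table(rname = character(0), ref_offset = integer(0),
                  pos = integer(0), type = character(0),
                  ref_base = character(0), alt = character(0))

  # --- short reads ---------------------------------------------------------
  slen <- config$short_length
  n_short <- as.integer(ceiling(config$coverage * Lref / slen))
  spos <- sample(0:(Lref - slen), n_short, replace = TRUE)
  sstrand <- sample(c("+", "-"), n_short, replace = TRUE)
  short_ids <- sprintf("short_%06d", seq_len(n_short))
  ref_seq_m <- vapply(spos, function(p)
    paste(ref_chars[(p + 1):(p + slen)], collapse = ""), character(1))
  err_mask <- matrix(runif(n_short * slen) < config$short_error,
                     nrow = n_short)
  quals <- matrix(clamp_qual(rnorm(n_short * slen, config$qual_mean,
                                   config$qual_sd)),
                  nrow = n_short)
  ref_ori_seq <- ref_seq_m
  if (any(err_mask)) {
    where <- which(err_mask, arr.ind = TRUE)
    # substitute erroneous bases and give them error-typical qualities
    for (r in unique(where[, 1])) {
      cols <- where[where[, 1] == r, 2]
      ch <- strsplit(ref_ori_seq[r], "", fixed = TRUE)[[1]]
      ch[cols] <- rand_other_base(ch[cols])
      ref_ori_seq[r] <- paste(ch, collapse = "")
    }
    quals[err_mask] <- clamp_qual(rnorm(sum(err_mask), config$err_qual_mean,
                                        config$err_qual_sd))
  }
  ref_ori_qual <- apply(quals, 1L, phred_encode)
  # as-sequenced orientation for FASTQ output
  neg <- sstrand == "-"
  fastq_seq <- ref_ori_seq
  fastq_qual <- ref_ori_qual
  if (any(neg)) {
    fastq_seq[neg] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(ref_ori_seq[neg])))
    fastq_qual[neg] <- vapply(ref_ori_qual[neg], function(s)
      intToUtf8(rev(utf8ToInt(s))), character(1), USE.NAMES = FALSE)
  }
  short_reads <- read_set(short_ids, fastq_seq, fastq_qual)

  # --- truth alignments by coordinate lifting ------------------------------
  aln_list <- list()
  tm_start <- truth_map$ref_start
  tm_end <- truth_map$ref_end
  for (i in seq_len(config$n_long)) {
    inside <- which(spos >= tm_start[i] & spos + slen <= tm_end[i])
    if (!length(inside)) next
    mp <- ref_maps[[i]]
    st <- integer(length(inside))
    cg <- character(length(inside))
    for (u in seq_along(inside)) {
      j <- inside[u]
      o <- (spos[j] - tm_start[i] + 1L):(spos[j] - tm_start[i] + slen)
      lifted <- lift_cigar_cpp(mp[o])
      st[u] <- if (is.na(lifted$start)) NA_integer_ else lifted$start
      cg[u] <- if (is.na(lifted$start)) NA_character_ else lifted$cigar
    }
    ok <- !is.na(st)
    if (any(ok))
      aln_list[[long_ids[i]]] <- data.table(
        qname = short_ids[inside[ok]], rname = long_ids[i], start = st[ok],
        strand = sstrand[inside[ok]], cigar = cg[ok],
        seq = ref_ori_seq[inside[ok]], qual = ref_ori_qual[inside[ok]])
  }
  alignments <- if (length(aln_list)) rbindlist(aln_list)
  else empty_alignments()[, !"identity"]
  if (nrow(alignments)) {
    lseq <- setNames(long_seqs, long_ids)
    alignments[, identity := mapply(aln_identity_cpp, start, cigar, seq,
                                    lseq[rname], USE.NAMES = FALSE)]
  } else alignments[, identity := numeric(0)]

  out <- list(reference = reference, long_reads = long_reads,
              short_reads = short_reads, alignments = alignments,
              truth_map = truth_map, injected = injected, config = config)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(reference = file.path(dir, "reference.fasta"),
               long_reads = file.path(dir, "long_reads.fastq"),
               short_reads = file.path(dir, "short_reads.fastq"),
               truth_sam = file.path(dir, "truth.sam"),
               truth_map = file.path(dir, "truth_map.tsv"))
    write_fasta(read_set("reference", reference), files[["reference"]])
    write_fastq(long_reads, files[["long_reads"]])
    write_fastq(short_reads, files[["short_reads"]])
    write_sam(alignments, long_reads, files[["truth_sam"]])
    write.table(truth_map, files[["truth_map"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
    out$files <- files
  }
  out
}

#' Randomly down-sample a short-read set
#'
#' Uniform subsampling without replacement to the stated fraction of reads
#' (rounded to the nearest integer count), preserving input order.
#'
#' @param short_reads a [read_set].
#' @param fraction fraction in (0, 1].
#' @param seed optional RNG seed for reproducible subsets.
#' @return A [read_set] with `round(fraction * n)` reads.
#' @export
downsample_short_reads <- function(short_reads, fraction, seed = NULL) {
  stopifnot(inherits(short_reads, "read_set"),
            fraction > 0, fraction <= 1)
  n <- length(short_reads)
  if (n == 0L) return(short_reads)
  if (!is.null(seed)) set.seed(seed)
  keep <- sort(sample.int(n, round(fraction * n)))
  short_reads[keep]
}
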