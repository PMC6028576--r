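#' Correction configuration
#'
#' Bundles the tunable parameters of the corrector. Defaults follow the
#' settings the method is normally run with: a strong-consensus threshold of
#' 90%, a 95th-percentile confidence cut-off, a 2% relative k-mer improvement
#' floor, at most five iterations, k = 21 for the k-mer metrics, and a
#' minimum covering depth of 2 before a site is considered correctable.
#'
#' @param eta consensus threshold in (0, 1]: a questionable site is
#'   quick-corrected when at least this fraction of covering reads propose
#'   the same edit.
#' @param alpha percentile in (0, 100) used for the per-iteration
#'   high-confidence cut-off over optimal costs.
#' @param epsilon relative-improvement threshold in (0, 1) for the k-mer
#'   termination test.
#' @param max_iter maximum number of iterations (>= 1).
#' @param k k-mer length for the termination metric.
#' @param min_coverage minimum covering depth (>= 1) for a site to be
#'   correctable.
#' @return An object of class `hybridec_config`.
#' @export
correction_config <- function(eta = 0.9, alpha = 95, epsilon = 0.02,
                              max_iter = 5L, k = 21L, min_coverage = 2L) {
  stopifnot(is.numeric(eta), length(eta) == 1L, eta > 0, eta <= 1)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 100)
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L,
            epsilon > 0, epsilon < 1)
  max_iter <- as.integer(max_iter)
  k <- as.integer(k)
  min_coverage <- as.integer(min_coverage)
  stopifnot(max_iter >= 1L, k >= 1L, min_coverage >= 1L)
  structure(list(eta = eta, alpha = alpha, epsilon = epsilon,
                 max_iter = max_iter, k = k, min_coverage = min_coverage),
            class = "hybridec_config")
}

#' @export
print.hybridec_config <- function(x, ...) {
  cat(sprintf(paste0("hybridec_config: eta=%.3g alpha=%.3g epsilon=%.3g ",
                     "max_iter=%d k=%d min_coverage=%d\n"),
              x$eta, x$alpha, x$epsilon, x$max_iter, x$k, x$min_coverage))
  invisible(x)
}

#' Normalised quality weights
#'
#' Per-site normalisation of PHRED qualities: each voting read's quality is
#' divided by the maximum quality among the reads aligned to the site, so
#' the best read gets weight exactly 1. If every quality is zero all weights
#' are defined as zero (the cost then decides on alignment identity alone).
#'
#' @param q integer vector of PHRED qualities (>= 0) of the reads at a site.
#' @return Numeric vector of weights in \[0, 1\].
#' @examples
#' normalize_quality_weights(c(30, 40, 20))  # 0.75 1.00 0.50
#' @export
normalize_quality_weights <- function(q) {
  q <- as.numeric(q)
  if (!length(q)) stop("need at least one quality")
  if (any(q < 0)) stop("qualities must be nonnegative")
  m <- max(q)
  if (m == 0) return(rep(0, length(q)))
  q / m
}

#' Correction cost of one candidate read
#'
#' The convex combination, with equal weights, of a read's normalised
#' quality weight and its alignment identity:
#' `J = (w_q + w_s) / 2`. Monotone in both arguments and bounded in \[0, 1\].
#'
#' @param w_q normalised quality weight in \[0, 1\].
#' @param w_s alignment-identity weight in \[0, 1\].
#' @return Cost value(s) in \[0, 1\].
#' @examples
#' correction_cost(0.8, 0.6)  # 0.7
#' @export
correction_cost <- function(w_q, w_s) {
  if (any(w_q < 0 | w_q > 1, na.rm = TRUE) ||
      any(w_s < 0 | w_s > 1, na.rm = TRUE))
    stop("weights must lie in [0, 1]")
  (w_q + w_s) / 2
}

# Kernel: strong-consensus resolution of a site.
# Returns an edit decision, the marker list(keep = TRUE) when >= eta of the
# covering reads agree with the long read as-is (site resolved, optimization
# skipped), or NULL when no proposal reaches consensus.
# votes: vectors type, edit, q, qname, agree; coverage: covering depth.
# Reads covering the site without a vote (e.g. spanning an insertion locus
# without inserting, or carrying N) implicitly support keeping the read as-is.
.quick_kernel <- function(type, edit, q, qname, agree, coverage, eta) {
  dis <- !agree
  n_keep <- coverage - sum(dis)
  if (any(dis)) {
    key <- paste(type[dis], edit[dis], sep = "\r")
    cnt <- tapply(rep(1L, sum(dis)), key, sum)
    qsum <- tapply(q[dis], key, sum)
    ord <- order(-cnt, -qsum, names(cnt))
    topk <- names(cnt)[ord[1]]
    if (cnt[[topk]] / coverage >= eta) {
      sel <- dis & key_of(type, edit) == topk
      w <- which(sel)
      w <- w[order(-q[w], qname[w])][1]
      parts <- strsplit(topk, "\r", fixed = TRUE)[[1]]
      return(list(type = parts[1],
                  edit = if (length(parts) > 1) parts[2] else "",
                  origin = "QUICK", J = NA_real_, winner = qname[w],
                  q = q[w]))
    }
  }
  if (n_keep / coverage >= eta) return(list(keep = TRUE))
  NULL
}

key_of <- function(type, edit) paste(type, edit, sep = "\r")

# Kernel: optimization-based winner over ALL reads aligned to the site.
# Quality weights are normalised over the N aligned reads; agreeing reads are
# candidates too, and an agreeing winner resolves the site without an edit
# (returned as list(keep = TRUE, ...)).
.optimal_kernel <- function(type, edit, q, qname, identity, agree) {
  if (!length(q)) return(NULL)
  wq <- normalize_quality_weights(q)
  J <- correction_cost(wq, identity)
  o <- order(-J, -q, qname)[1]
  if (agree[o])
    return(list(keep = TRUE, J = J[o], winner = qname[o]))
  list(type = type[o], edit = edit[o], origin = "OPTIMIZED", J = J[o],
       winner = qname[o], q = q[o])
}

#' Quick correction of a questionable site by strong consensus
#'
#' If one proposed edit (differing from the long read's current state) is
#' supported by at least a fraction `eta` of the reads covering the site, it
#' is accepted outright without evaluating the optimization cost. (In the
#' full pipeline the symmetric case — at least `eta` of covering reads
#' agreeing with the long read — likewise resolves the site without an
#' edit, shrinking the optimization search space; this function returns
#' `NULL` in both no-edit cases.)
#'
#' @param site a site as returned by [site_evidence()].
#' @param eta consensus threshold in (0, 1].
#' @param min_coverage minimum covering depth for the site to be considered.
#' @return A correction decision (list with `type`, `edit`, `origin =
#'   "QUICK"`, `winner`, plus the site's coordinates), or `NULL` when
#'   consensus is not reached.
#' @export
quick_correct <- function(site, eta = 0.9, min_coverage = 1L) {
  if (is.null(site)) return(NULL)
  if (site$coverage < min_coverage) return(NULL)
  v <- site$votes
  d <- .quick_kernel(v$type, v$edit, v$q, v$short_read_id, v$agree,
                     site$coverage, eta)
  if (is.null(d) || isTRUE(d$keep)) return(NULL)
  c(list(long_read_id = site$long_read_id, position = site$position,
         is_insert = site$is_insert), d)
}

#' Optimization-based correction of a questionable site
#'
#' Over all `N` reads aligned to the site — agreeing reads included —
#' selects the one maximising the cost `J = (w_q + w_s)/2`, where `w_q` is
#' the per-site normalised PHRED weight and `w_s` the alignment identity.
#' Ties on `J` are broken by highest raw quality, then by lexicographically
#' smallest short-read identifier. When the winner agrees with the long
#' read, the questionable base is kept as-is (no edit); this is what keeps
#' a lone low-quality disagreeing read from overruling high-quality
#' agreeing coverage.
#'
#' @param site a site as returned by [site_evidence()].
#' @return A correction decision (list with `type`, `edit`, `origin =
#'   "OPTIMIZED"`, optimal cost `J`, `winner`, site coordinates), a keep
#'   resolution (list with `keep = TRUE`, `J`, `winner`) when an agreeing
#'   read wins, or `NULL` when the site has no votes.
#' @export
select_optimal <- function(site) {
  if (is.null(site)) return(NULL)
  v <- site$votes
  d <- .optimal_kernel(v$type, v$edit, v$q, v$short_read_id, v$identity,
                       v$agree)
  if (is.null(d)) return(NULL)
  c(list(long_read_id = site$long_read_id, position = site$position,
         is_insert = site$is_insert), d)
}

#' Decide corrections for every questionable site of a pileup
#'
#' Applies quick correction first and falls back to optimization-based
#' correction at sites without strong consensus. Sites with covering depth
#' below `min_coverage`, and sites at locked coordinates, are skipped.
#'
#' @param pileup a [build_pileup()] result.
#' @param config a [correction_config()].
#' @param locked optional `data.table` of locked coordinates (`rname`,
#'   `pos`, `is_ins`) that must not be re-decided.
#' @return A `data.table` of decisions: `rname`, `pos`, `is_ins`, `type`,
#'   `edit`, `origin` (`QUICK`/`OPTIMIZED`), `J` (NA for quick), `winner`,
#'   `q`.
#' @export
decide_sites <- function(pileup, config = correction_config(),
                         locked = NULL) {
  stopifnot(inherits(pileup, "pileup"))
  v <- pileup$votes[coverage >= config$min_coverage]
  if (!is.null(locked) && nrow(locked)) {
    lk <- unique(as.data.table(locked)[, .(rname, pos, is_ins)])
    v <- v[!lk, on = c("rname", "pos", "is_ins")]
  }
  if (!nrow(v)) return(empty_decisions())
  eta <- config$eta
  dec <- v[, {
    d <- .quick_kernel(type, edit, q, qname, agree, coverage[1], eta)
    if (is.null(d))
      d <- .optimal_kernel(type, edit, q, qname, identity, agree)
    if (is.null(d) || isTRUE(d$keep))
      list(type = character(0), edit = character(0), origin = character(0),
           J = numeric(0), winner = character(0), q = integer(0))
    else
      list(type = d$type, edit = d$edit, origin = d$origin, J = d$J,
           winner = d$winner, q = as.integer(d$q))
  }, by = .(rname, pos, is_ins)]
  setorder(dec, rname, pos, is_ins)
  dec[]
}

empty_decisions <- function() {
  data.table(rname = character(0), pos = integer(0), is_ins = integer(0),
             type = character(0), edit = character(0), origin = character(0),
             J = numeric(0), winner = character(0), q = integer(0))
}

#' Apply correction decisions to one long read
#'
#' Applies the selected edits to the sequence. Substitutions and deletions
#' act on the base at `pos`; insertions add bases immediately before `pos`.
#' Edits are applied so that every decision's original coordinate stays
#' valid, and positions without a decision are never modified. At most one
#' decision per locus is expected (the site decision step guarantees this).
#'
#' @param seq long-read sequence (character scalar).
#' @param decisions `data.table`/data.frame of decisions for this read
#'   (columns `pos`, `is_ins`, `type`, `edit`).
#' @return A list with
#'   \describe{
#'     \item{seq}{the corrected sequence,}
#'     \item{pos_map}{integer vector mapping each original 0-based position
#'       to its 0-based position in the corrected sequence (`NA` when the
#'       base was deleted),}
#'     \item{new_locks}{`data.table` of the applied edits' coordinates in
#'       the *corrected* sequence (`pos`, `is_ins`).}
#'   }
#' @export
correct_read <- function(seq, decisions) {
  L <- nchar(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (is.null(decisions) || nrow(decisions) == 0L) {
    return(list(seq = seq, pos_map = seq_len(L) - 1L,
                new_locks = data.table(pos = integer(0), is_ins = integer(0),
                                       base = character(0))))
  }
  decisions <- as.data.table(decisions)
  if (any(decisions$pos < 0L | decisions$pos >= L))
    stop("decision position out of read bounds")
  if (anyDuplicated(decisions[, .(pos, is_ins)]))
    stop("multiple decisions at one locus")
  deleted <- logical(L)
  # base edits first (replace the character), then insertions (prepend),
  # so an insertion before a substituted/deleted base composes correctly
  base_ed <- decisions[is_ins == 0L]
  for (i in seq_len(nrow(base_ed))) {
    j <- base_ed$pos[i] + 1L
    if (base_ed$type[i] == "SUB") chars[j] <- base_ed$edit[i]
    else if (base_ed$type[i] == "DEL") { chars[j] <- ""; deleted[j] <- TRUE }
    else stop("invalid base edit type: ", base_ed$type[i])
  }
  ins_ed <- decisions[is_ins == 1L]
  for (i in seq_len(nrow(ins_ed))) {
    j <- ins_ed$pos[i] + 1L
    chars[j] <- paste0(ins_ed$edit[i], chars[j])
  }
  widths <- nchar(chars)
  ends <- cumsum(widths)              # 1-based end of each original slot
  pos_map <- ifelse(deleted, NA_integer_, as.integer(ends - 1L)) # 0-based
  # locks in corrected coordinates
  locks <- list()
  if (nrow(base_ed)) {
    sub_i <- base_ed$type == "SUB"
    if (any(sub_i))
      locks$sub <- data.table(pos = pos_map[base_ed$pos[sub_i] + 1L],
                              is_ins = 0L, base = base_ed$edit[sub_i])
    del_i <- base_ed$type == "DEL"
    if (any(del_i)) {
      # lock the junction left behind so the base cannot be re-inserted
      nxt <- vapply(base_ed$pos[del_i] + 1L, function(j) {
        k <- j + 1L
        while (k <= L && deleted[k]) k <- k + 1L
        if (k <= L) pos_map[k] else NA_integer_
      }, integer(1))
      ok <- !is.na(nxt) & nxt > 0L
      if (any(ok)) locks$del <- data.table(pos = nxt[ok], is_ins = 1L,
                                           base = NA_character_)
    }
  }
  if (nrow(ins_ed)) {
    # lock every inserted base
    ins_locks <- lapply(seq_len(nrow(ins_ed)), function(i) {
      j <- ins_ed$pos[i] + 1L
      len <- nchar(ins_ed$edit[i])
      end0 <- ends[j] - 1L                      # 0-based end of slot j
      first0 <- end0 - widths[j] + 1L           # 0-based start of slot j
      data.table(pos = as.integer(seq.int(first0, length.out = len)),
                 is_ins = 0L,
                 base = strsplit(ins_ed$edit[i], "", fixed = TRUE)[[1]])
    })
    if (length(ins_locks)) locks$ins <- rbindlist(ins_locks)
  }
  new_locks <- if (length(locks)) rbindlist(locks) else
    data.table(pos = integer(0), is_ins = integer(0), base = character(0))
  list(seq = paste(chars, collapse = ""), pos_map = pos_map,
       new_locks = unique(new_locks))
}

# Apply a set of decisions across reads; remap and extend the lock set.
# locked: data.table(rname, pos, is_ins). Returns list(reads, locked,
# pos_maps) where pos_maps maps each read's pre-application coordinates to
# post-application ones.
apply_decisions <- function(reads, decisions, locked = NULL) {
  seqs <- setNames(reads$seq, reads$id)
  pos_maps <- lapply(setNames(nchar(seqs), names(seqs)),
                     function(n) seq_len(n) - 1L)
  lock_out <- list()
  dec_by_read <- if (nrow(decisions)) split(decisions, by = "rname") else list()
  locked <- if (is.null(locked))
    data.table(rname = character(0), pos = integer(0), is_ins = integer(0),
               base = character(0))
  else as.data.table(locked)
  if (!"base" %in% names(locked)) locked[, base := NA_character_]
  for (rn in names(seqs)) {
    dd <- dec_by_read[[rn]]
    res <- correct_read(seqs[[rn]], dd)
    pm <- res$pos_map
    seqs[[rn]] <- res$seq
    pos_maps[[rn]] <- pm
    old <- locked[rname == rn]
    remapped <- if (nrow(old)) {
      L <- length(pm)
      newpos <- integer(nrow(old))
      for (i in seq_len(nrow(old))) {
        p <- old$pos[i]
        if (old$is_ins[i] == 0L) {
          newpos[i] <- if (p + 1L <= L) pm[p + 1L] else NA_integer_
        } else {
          # junction before base p: anchor to first surviving base >= p
          k <- p + 1L
          while (k <= L && is.na(pm[k])) k <- k + 1L
          newpos[i] <- if (k <= L) pm[k] else NA_integer_
        }
      }
      data.table(pos = newpos, is_ins = old$is_ins,
                 base = old$base)[!is.na(pos)]
    } else data.table(pos = integer(0), is_ins = integer(0),
                      base = character(0))
    nl <- rbind(remapped, res$new_locks)
    if (nrow(nl)) {
      nl[, rname := rn]
      lock_out[[rn]] <- unique(nl)
    }
  }
  new_locked <- if (length(lock_out)) rbindlist(lock_out, use.names = TRUE)
  else data.table(pos = integer(0), is_ins = integer(0),
                  base = character(0), rname = character(0))
  setcolorder(new_locked, c("rname", "pos", "is_ins", "base"))
  list(reads = read_set(names(seqs), unname(seqs)),
       locked = new_locked, pos_maps = pos_maps)
}
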