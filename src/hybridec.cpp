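#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstring>
#include <climits>

using namespace Rcpp;

// Parse a CIGAR string into (length, op) runs. Returns false on malformed input.
static bool parse_cigar(const char *cig, std::vector<int> &lens,
                        std::vector<char> &ops) {
  lens.clear();
  ops.clear();
  if (cig == NULL || cig[0] == '\0' || std::strcmp(cig, "*") == 0) return false;
  const char *p = cig;
  while (*p) {
    long n = 0;
    if (*p < '0' || *p > '9') return false;
    while (*p >= '0' && *p <= '9') {
      n = n * 10 + (*p - '0');
      ++p;
    }
    char op = *p;
    if (op == '\0') return false;
    switch (op) {
    case 'M': case '=': case 'X': case 'I': case 'D':
    case 'S': case 'H': case 'N': case 'P':
      break;
    default:
      return false;
    }
    lens.push_back((int)n);
    ops.push_back(op);
    ++p;
  }
  return !ops.empty();
}

static inline bool consumes_query(char op) {
  return op == 'M' || op == '=' || op == 'X' || op == 'I' || op == 'S';
}
static inline bool consumes_ref(char op) {
  return op == 'M' || op == '=' || op == 'X' || op == 'D' || op == 'N';
}

// Reference-consuming width of a CIGAR.
// [[Rcpp::export]]
int cigar_ref_width_cpp(std::string cigar) {
  std::vector<int> lens;
  std::vector<char> ops;
  if (!parse_cigar(cigar.c_str(), lens, ops)) return NA_INTEGER;
  int w = 0;
  for (size_t i = 0; i < ops.size(); ++i)
    if (consumes_ref(ops[i])) w += lens[i];
  return w;
}

// Alignment identity: exact matches over aligned columns divided by the
// short-read length (soft-clipped bases count in the denominator, never as
// matches; 'N' in either sequence never matches).
// [[Rcpp::export]]
double aln_identity_cpp(int start, std::string cigar, std::string sseq,
                        std::string lseq) {
  std::vector<int> lens;
  std::vector<char> ops;
  if (!parse_cigar(cigar.c_str(), lens, ops))
    stop("malformed CIGAR string: '%s'", cigar.c_str());
  int spos = 0, lpos = start, matches = 0;
  int slen = (int)sseq.size(), llen = (int)lseq.size();
  for (size_t i = 0; i < ops.size(); ++i) {
    char op = ops[i];
    int n = lens[i];
    if (op == 'M' || op == '=' || op == 'X') {
      if (spos + n > slen || lpos + n > llen)
        stop("CIGAR overruns sequence (start=%d, cigar=%s)", start,
             cigar.c_str());
      for (int t = 0; t < n; ++t) {
        char sb = sseq[spos + t], lb = lseq[lpos + t];
        if (sb != 'N' && lb != 'N' && sb == lb) ++matches;
      }
      spos += n;
      lpos += n;
    } else {
      // S and I consume query; D and N consume reference; H/P consume nothing
      if (consumes_query(op)) spos += n;
      if (consumes_ref(op)) lpos += n;
    }
  }
  if (slen == 0) return 0.0;
  return (double)matches / (double)slen;
}

// Walk CIGARs of all alignments against one long read and emit per-position
// candidate votes: substitutions/agreements at aligned columns, DELETE votes
// at long-read bases absent from the short read, INSERT votes at inter-base
// loci where the short read carries extra bases. Positions are 0-based on the
// long read; an INSERT at pos j proposes bases before base j.
// type codes: 0 = SUB, 1 = DEL, 2 = INS.
// [[Rcpp::export]]
List pileup_walk_cpp(IntegerVector start, CharacterVector cigar,
                     CharacterVector seq, CharacterVector qual,
                     std::string lseq) {
  int nrec = start.size();
  std::vector<int> o_rec, o_pos, o_ins, o_type, o_q, o_agree;
  std::vector<std::string> o_edit;
  size_t cap = 0;
  for (int r = 0; r < nrec; ++r) cap += LENGTH(STRING_ELT(seq, r));
  o_rec.reserve(cap); o_pos.reserve(cap); o_ins.reserve(cap);
  o_type.reserve(cap); o_q.reserve(cap); o_agree.reserve(cap);
  o_edit.reserve(cap);

  std::vector<int> lens;
  std::vector<char> ops;
  int llen = (int)lseq.size();

  for (int r = 0; r < nrec; ++r) {
    const char *cg = CHAR(STRING_ELT(cigar, r));
    if (!parse_cigar(cg, lens, ops)) continue;
    const char *sq = CHAR(STRING_ELT(seq, r));
    int slen = (int)std::strlen(sq);
    const char *ql = CHAR(STRING_ELT(qual, r));
    bool have_q = ((int)std::strlen(ql) == slen);
    int spos = 0, lpos = start[r];
    // last op index that consumes reference (to reject unanchored inserts)
    int last_ref_op = -1, first_ref_op = -1;
    for (size_t i = 0; i < ops.size(); ++i) {
      if (consumes_ref(ops[i])) {
        if (first_ref_op < 0) first_ref_op = (int)i;
        last_ref_op = (int)i;
      }
    }
    for (size_t i = 0; i < ops.size(); ++i) {
      char op = ops[i];
      int n = lens[i];
      if (op == 'M' || op == '=' || op == 'X') {
        if (spos + n > slen || lpos + n > llen)
          stop("CIGAR overruns sequence for record %d", r + 1);
        for (int t = 0; t < n; ++t) {
          char sb = sq[spos + t], lb = lseq[lpos + t];
          if (sb == 'N' || lb == 'N') continue;
          o_rec.push_back(r + 1);
          o_pos.push_back(lpos + t);
          o_ins.push_back(0);
          o_type.push_back(0);
          o_edit.push_back(std::string(1, sb));
          o_q.push_back(have_q ? (ql[spos + t] - 33) : 20);
          o_agree.push_back(sb == lb ? 1 : 0);
        }
        spos += n;
        lpos += n;
      } else if (op == 'I') {
        bool anchored = ((int)i > first_ref_op) && ((int)i < last_ref_op) &&
                        lpos > 0 && lpos < llen;
        if (anchored && spos + n <= slen) {
          std::string ins(sq + spos, sq + spos + n);
          if (ins.find('N') == std::string::npos) {
            long qs = 0;
            for (int t = 0; t < n; ++t)
              qs += have_q ? (ql[spos + t] - 33) : 20;
            o_rec.push_back(r + 1);
            o_pos.push_back(lpos);
            o_ins.push_back(1);
            o_type.push_back(2);
            o_edit.push_back(ins);
            o_q.push_back((int)(qs / n));
            o_agree.push_back(0);
          }
        }
        spos += n;
      } else if (op == 'D') {
        for (int t = 0; t < n; ++t) {
          int qleft = (spos > 0 && have_q) ? (ql[spos - 1] - 33) : -1;
          int qright = (spos < slen && have_q) ? (ql[spos] - 33) : -1;
          int qv;
          if (qleft >= 0 && qright >= 0) qv = (qleft + qright) / 2;
          else if (qleft >= 0) qv = qleft;
          else if (qright >= 0) qv = qright;
          else qv = 20;
          o_rec.push_back(r + 1);
          o_pos.push_back(lpos + t);
          o_ins.push_back(0);
          o_type.push_back(1);
          o_edit.push_back("");
          o_q.push_back(qv);
          o_agree.push_back(0);
        }
        lpos += n;
      } else if (op == 'S') {
        spos += n;
      } else if (op == 'N') {
        lpos += n;
      }
      // H, P: consume nothing stored
    }
  }
  return List::create(_["rec"] = wrap(o_rec), _["pos"] = wrap(o_pos),
                      _["is_ins"] = wrap(o_ins), _["type"] = wrap(o_type),
                      _["edit"] = wrap(o_edit), _["q"] = wrap(o_q),
                      _["agree"] = wrap(o_agree));
}

// Banded glocal alignment: the short read is aligned end-to-end against a
// window of the long read; the window's leading and trailing overhangs are
// free. The expected diagonal runs through column i + band for short-read row
// i; cells further than `band` from it are not computed.
// Scoring: match +1, mismatch -2, gap -2 (linear).
// Returns, per pair: 0-based start of the alignment within the window, a
// CIGAR over {=,X,I,D} (I = extra short-read base), match count and score.
// [[Rcpp::export]]
List banded_glocal_cpp(CharacterVector sseq, CharacterVector wseq, int band) {
  const int MATCH = 1, MISMATCH = -2, GAP = -2;
  const int NEG = INT_MIN / 4;
  int npair = sseq.size();
  IntegerVector out_start(npair), out_matches(npair), out_score(npair);
  CharacterVector out_cigar(npair);

  std::vector<int> score;
  std::vector<unsigned char> dir; // 0 none, 1 diag, 2 up(I), 3 left(D)

  for (int p = 0; p < npair; ++p) {
    const char *S = CHAR(STRING_ELT(sseq, p));
    const char *W = CHAR(STRING_ELT(wseq, p));
    int m = (int)std::strlen(S), n = (int)std::strlen(W);
    if (m == 0 || n == 0) {
      out_start[p] = NA_INTEGER;
      out_cigar[p] = NA_STRING;
      out_matches[p] = 0;
      out_score[p] = NEG;
      continue;
    }
    size_t sz = (size_t)(m + 1) * (size_t)(n + 1);
    score.assign(sz, NEG);
    dir.assign(sz, 0);
#define IX(i, j) ((size_t)(i) * (size_t)(n + 1) + (size_t)(j))
    // free leading window gap: row 0 all zero within reach
    int j0max = std::min(n, 2 * band);
    for (int j = 0; j <= j0max; ++j) score[IX(0, j)] = 0;
    for (int i = 1; i <= m; ++i) {
      // expected col for row i is i + band, so the band spans [i, i + 2*band]
      int jlo = std::max(1, i), jhi = std::min(n, i + 2 * band);
      for (int j = jlo; j <= jhi; ++j) {
        int best = NEG;
        unsigned char d = 0;
        int sd = score[IX(i - 1, j - 1)];
        if (sd > NEG) {
          char a = S[i - 1], b = W[j - 1];
          int v = sd + ((a != 'N' && b != 'N' && a == b) ? MATCH : MISMATCH);
          if (v > best) { best = v; d = 1; }
        }
        int su = score[IX(i - 1, j)];
        if (su > NEG && su + GAP > best) { best = su + GAP; d = 2; }
        int sl = score[IX(i, j - 1)];
        if (sl > NEG && sl + GAP > best) { best = sl + GAP; d = 3; }
        if (d) { score[IX(i, j)] = best; dir[IX(i, j)] = d; }
      }
    }
    // free trailing window gap: best over last row
    int bestj = -1, bestv = NEG;
    for (int j = std::min(n, m + 2 * band); j >= std::max(0, m); --j) {
      int v = score[IX(m, j)];
      if (v > bestv) { bestv = v; bestj = j; }
    }
    if (bestj < 0) {
      // fully banded-out (shouldn't happen); report failure
      out_start[p] = NA_INTEGER;
      out_cigar[p] = NA_STRING;
      out_matches[p] = 0;
      out_score[p] = NEG;
      continue;
    }
    // traceback
    std::string rev;
    rev.reserve(m + n);
    int matches = 0;
    int i = m, j = bestj;
    while (i > 0) {
      unsigned char d = dir[IX(i, j)];
      if (d == 1) {
        char a = S[i - 1], b = W[j - 1];
        bool mt = (a != 'N' && b != 'N' && a == b);
        rev.push_back(mt ? '=' : 'X');
        if (mt) ++matches;
        --i; --j;
      } else if (d == 2) {
        rev.push_back('I');
        --i;
      } else if (d == 3) {
        rev.push_back('D');
        --j;
      } else {
        break; // hit row-0 free zone
      }
    }
    int astart = j; // 0-based start within window
    // run-length encode reversed op string (reading backwards = forward order)
    std::string cig;
    cig.reserve(rev.size());
    for (int t = (int)rev.size() - 1; t >= 0;) {
      char op = rev[t];
      int run = 0;
      while (t >= 0 && rev[t] == op) { ++run; --t; }
      cig += std::to_string(run);
      cig.push_back(op);
    }
    out_start[p] = astart;
    out_cigar[p] = cig;
    out_matches[p] = matches;
    out_score[p] = bestv;
#undef IX
  }
  return List::create(_["start"] = out_start, _["cigar"] = out_cigar,
                      _["matches"] = out_matches, _["score"] = out_score);
}

// Build a CIGAR for a short read whose reference bases map to long-read
// positions mp (0-based; NA = the ref base is deleted in the long read).
// Emits M for mapped bases, I for deleted ones, and D runs for long-read
// insertions falling between consecutive mapped bases.
// [[Rcpp::export]]
List lift_cigar_cpp(IntegerVector mp) {
  int n = mp.size();
  std::string ops;
  ops.reserve(2 * n);
  int last = -1, start = -1;
  for (int t = 0; t < n; ++t) {
    if (mp[t] == NA_INTEGER) {
      ops.push_back('I');
      continue;
    }
    if (start < 0) start = mp[t];
    if (last >= 0) {
      int g = mp[t] - last - 1;
      for (int u = 0; u < g; ++u) ops.push_back('D');
    }
    ops.push_back('M');
    last = mp[t];
  }
  if (start < 0)
    return List::create(_["start"] = NA_INTEGER, _["cigar"] = NA_STRING);
  std::string cig;
  for (size_t t = 0; t < ops.size();) {
    char op = ops[t];
    size_t run = 0;
    while (t < ops.size() && ops[t] == op) { ++run; ++t; }
    cig += std::to_string(run);
    cig.push_back(op);
  }
  return List::create(_["start"] = start, _["cigar"] = cig);
}
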