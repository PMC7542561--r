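// Per-read hot loops: seed-and-extend read placement, alignment scoring,
// codon pileup accumulation, correlation-profile accumulation and
// recombination-event application. All randomness stays on the R side;
// these routines are deterministic transforms.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

// mean Phred score (+33 encoding) per quality string
// [[Rcpp::export]]
NumericVector cpp_mean_phred(CharacterVector quals) {
  int n = quals.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const char *q = CHAR(STRING_ELT(quals, i));
    long sum = 0;
    int len = 0;
    for (; q[len]; ++len) sum += q[len] - 33;
    out[i] = len ? (double)sum / len : NA_REAL;
  }
  return out;
}

// cumulative masked-column count: cum[i] = masked columns in ref[0, i)
static std::vector<int> mask_cum(int L, const IntegerVector &ms,
                                 const IntegerVector &me) {
  std::vector<char> m(L, 0);
  for (int k = 0; k < ms.size(); ++k)
    for (int p = ms[k]; p < me[k] && p < L; ++p)
      if (p >= 0) m[p] = 1;
  std::vector<int> cum(L + 1, 0);
  for (int i = 0; i < L; ++i) cum[i + 1] = cum[i] + m[i];
  return cum;
}

// score projected alignment strings against the reference; masked columns
// are excluded from both matches and aligned length
// [[Rcpp::export]]
List cpp_score_alignments(CharacterVector aln_seq, IntegerVector ref_start,
                          std::string ref, IntegerVector mask_start,
                          IntegerVector mask_end) {
  int n = aln_seq.size();
  int L = ref.size();
  std::vector<int> cum = mask_cum(L, mask_start, mask_end);
  IntegerVector alen(n), matches(n);
  for (int i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(aln_seq, i));
    int start = ref_start[i];
    int len = LENGTH(STRING_ELT(aln_seq, i));
    int a = 0, m = 0;
    for (int j = 0; j < len; ++j) {
      int p = start + j;
      if (p < 0 || p >= L) continue;
      if (cum[p + 1] - cum[p]) continue;  // masked column
      ++a;
      if (s[j] == ref[p]) ++m;
    }
    alen[i] = a;
    matches[i] = m;
  }
  return List::create(_["aligned_len"] = alen, _["matches"] = matches);
}

// Seed-and-extend ungapped placement of reads on a reference.
// Exact k-mer seeds at regular read offsets vote for candidate diagonal
// placements; the top candidates are scored by full-length Hamming
// comparison (masked columns excluded). Best = most matches, ties broken by
// leftmost reference start. Reads whose aligned span overlaps masked
// regions by more than mask_drop_frac, or with no seed hit, are dropped.
// [[Rcpp::export]]
DataFrame cpp_align_reads(CharacterVector reads, std::string ref, int k,
                          int step, IntegerVector mask_start,
                          IntegerVector mask_end, double mask_drop_frac) {
  int L = ref.size();
  std::vector<int> refc(L);
  for (int i = 0; i < L; ++i) refc[i] = base_code(ref[i]);
  std::vector<int> cum = mask_cum(L, mask_start, mask_end);

  // k-mer index of the reference (2-bit encoding; k <= 31)
  std::unordered_map<uint64_t, std::vector<int> > index;
  index.reserve(L);
  uint64_t h = 0, msk = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  int run = 0;
  for (int i = 0; i < L; ++i) {
    int c = refc[i];
    if (c < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)c) & msk;
    if (++run >= k) index[h].push_back(i - k + 1);
  }

  int n = reads.size();
  std::vector<int> out_idx, out_start, out_alen, out_match;
  out_idx.reserve(n);
  std::unordered_map<int, int> votes;
  for (int r = 0; r < n; ++r) {
    const char *s = CHAR(STRING_ELT(reads, r));
    int rl = LENGTH(STRING_ELT(reads, r));
    if (rl < k || rl > L) continue;
    votes.clear();
    for (int off = 0; off + k <= rl; off += step) {
      uint64_t hh = 0;
      bool ok = true;
      for (int j = 0; j < k; ++j) {
        int c = base_code(s[off + j]);
        if (c < 0) { ok = false; break; }
        hh = (hh << 2) | (uint64_t)c;
      }
      if (!ok) continue;
      std::unordered_map<uint64_t, std::vector<int> >::iterator it = index.find(hh);
      if (it == index.end()) continue;
      if ((int)it->second.size() > 64) continue;  // uninformative repeat seed
      for (size_t t = 0; t < it->second.size(); ++t) {
        int cand = it->second[t] - off;
        if (cand >= 0 && cand + rl <= L) ++votes[cand];
      }
    }
    if (votes.empty()) continue;
    // order candidates by votes desc, then leftmost
    std::vector<std::pair<int, int> > cands(votes.begin(), votes.end());
    std::sort(cands.begin(), cands.end(),
              [](const std::pair<int, int> &a, const std::pair<int, int> &b) {
                if (a.second != b.second) return a.second > b.second;
                return a.first < b.first;
              });
    int ncand = std::min((int)cands.size(), 8);
    int best_m = -1, best_a = 0, best_s = -1, best_maskov = 0;
    for (int ci = 0; ci < ncand; ++ci) {
      int st = cands[ci].first;
      int a = 0, m = 0, maskov = cum[st + rl] - cum[st];
      for (int j = 0; j < rl; ++j) {
        int p = st + j;
        if (cum[p + 1] - cum[p]) continue;
        ++a;
        if (s[j] == ref[p]) ++m;
      }
      if (m > best_m || (m == best_m && st < best_s)) {
        best_m = m; best_a = a; best_s = st; best_maskov = maskov;
      }
    }
    if (best_m < 0) continue;
    if ((double)best_maskov > mask_drop_frac * rl) continue;
    out_idx.push_back(r + 1);
    out_start.push_back(best_s);
    out_alen.push_back(best_a);
    out_match.push_back(best_m);
  }
  return DataFrame::create(_["read_idx"] = out_idx, _["ref_start"] = out_start,
                           _["aligned_len"] = out_alen,
                           _["matches"] = out_match);
}

// Codon pileup accumulation. codon_first[p] holds the global codon id when
// genome position p (0-based) is the first base of a codon slot, else -1.
// Only reads spanning all three codon bases contribute; columns with gaps
// or N skip that codon for that read.
// [[Rcpp::export]]
List cpp_codon_pileup(IntegerVector ref_start, CharacterVector aln_seq,
                      IntegerVector codon_first) {
  int L = codon_first.size();
  std::unordered_map<int64_t, int> acc;
  int n = aln_seq.size();
  for (int i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(aln_seq, i));
    int len = LENGTH(STRING_ELT(aln_seq, i));
    int st = ref_start[i];
    int lo = std::max(0, st), hi = std::min(L, st + len - 2);
    for (int p = lo; p < hi; ++p) {
      int cid = codon_first[p];
      if (cid < 0) continue;
      if (p < st || p + 3 > st + len) continue;
      int c1 = base_code(s[p - st]);
      int c2 = base_code(s[p - st + 1]);
      int c3 = base_code(s[p - st + 2]);
      if (c1 < 0 || c2 < 0 || c3 < 0) continue;
      int64_t key = (int64_t)cid * 64 + (c1 * 16 + c2 * 4 + c3);
      ++acc[key];
    }
  }
  int m = acc.size();
  IntegerVector cid(m), code(m), count(m);
  int j = 0;
  for (std::unordered_map<int64_t, int>::iterator it = acc.begin();
       it != acc.end(); ++it, ++j) {
    cid[j] = (int)(it->first / 64);
    code[j] = (int)(it->first % 64);
    count[j] = it->second;
  }
  return List::create(_["codon_id"] = cid, _["codon_code"] = code,
                      _["count"] = count);
}

// Correlation-profile accumulation over masked (synonymous) sites.
// For every read and every masked-site pair (i, i+l) covered by that read,
// accumulate the product of mismatch indicators against the reference.
// Columns where the read base is not ACGT are skipped.
// [[Rcpp::export]]
List cpp_corr_profile(IntegerVector ref_start, CharacterVector aln_seq,
                      std::string ref, IntegerVector mask_pos, int max_l) {
  int n = aln_seq.size();
  std::vector<double> pair_sum(max_l + 1, 0.0);
  std::vector<double> pair_n(max_l + 1, 0.0);
  double site_n = 0.0, site_mm = 0.0;
  std::vector<int> pos_buf;
  std::vector<char> x_buf;
  int M = mask_pos.size();
  for (int i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(aln_seq, i));
    int len = LENGTH(STRING_ELT(aln_seq, i));
    int st = ref_start[i];
    // masked sites inside [st, st+len)
    int lo = std::lower_bound(mask_pos.begin(), mask_pos.end(), st) -
      mask_pos.begin();
    pos_buf.clear();
    x_buf.clear();
    for (int t = lo; t < M && mask_pos[t] < st + len; ++t) {
      int p = mask_pos[t];
      char rc = s[p - st];
      if (base_code(rc) < 0) continue;
      char x = (rc != ref[p]) ? 1 : 0;
      pos_buf.push_back(p);
      x_buf.push_back(x);
      site_n += 1.0;
      site_mm += x;
    }
    int m = pos_buf.size();
    for (int a = 0; a < m; ++a) {
      for (int b = a + 1; b < m; ++b) {
        int l = pos_buf[b] - pos_buf[a];
        if (l > max_l) break;
        pair_n[l] += 1.0;
        pair_sum[l] += (double)(x_buf[a] & x_buf[b]);
      }
    }
  }
  return List::create(_["pair_sum"] = NumericVector(pair_sum.begin(), pair_sum.end()),
                      _["pair_n"] = NumericVector(pair_n.begin(), pair_n.end()),
                      _["site_n"] = site_n, _["site_mm"] = site_mm);
}

// Apply pre-drawn recombination events sequentially: copy [start, end]
// (1-based, inclusive) of the donor's current haplotype into the recipient.
// [[Rcpp::export]]
IntegerMatrix cpp_apply_recomb(IntegerMatrix hap, IntegerVector donor,
                               IntegerVector recipient, IntegerVector start,
                               IntegerVector end) {
  IntegerMatrix out = clone(hap);
  int m = donor.size();
  for (int e = 0; e < m; ++e) {
    int d = donor[e] - 1, r = recipient[e] - 1;
    for (int p = start[e] - 1; p < end[e]; ++p) out(p, r) = out(p, d);
  }
  return out;
}

// Apply pre-drawn pool-recombination events sequentially: reset
// [start, end] (1-based, inclusive) of the recipient to the reference,
// then apply that event's fresh substitutions. mut_event must be sorted
// ascending; mut_pos is 1-based.
// [[Rcpp::export]]
IntegerMatrix cpp_apply_pool_recomb(IntegerMatrix hap, IntegerVector recipient,
                                    IntegerVector start, IntegerVector end,
                                    IntegerVector mut_event,
                                    IntegerVector mut_pos,
                                    IntegerVector mut_base,
                                    IntegerVector ref) {
  IntegerMatrix out = clone(hap);
  int m = recipient.size();
  int nm = mut_event.size();
  int j = 0;
  for (int e = 0; e < m; ++e) {
    int r = recipient[e] - 1;
    for (int p = start[e] - 1; p < end[e]; ++p) out(p, r) = ref[p];
    while (j < nm && mut_event[j] == e + 1) {
      out(mut_pos[j] - 1, r) = mut_base[j];
      ++j;
    }
  }
  return out;
}

// Hamming mismatches of each sequence to the reference and pairwise.
// [[Rcpp::export]]
List cpp_pairwise_mismatch(CharacterVector seqs, std::string ref) {
  int n = seqs.size();
  NumericVector to_ref(n);
  NumericMatrix pw(n, n);
  std::vector<const char *> ptr(n);
  std::vector<int> len(n);
  for (int i = 0; i < n; ++i) {
    ptr[i] = CHAR(STRING_ELT(seqs, i));
    len[i] = LENGTH(STRING_ELT(seqs, i));
  }
  int L = ref.size();
  for (int i = 0; i < n; ++i) {
    int m = 0, li = std::min(L, len[i]);
    for (int p = 0; p < li; ++p)
      if (ptr[i][p] != ref[p]) ++m;
    to_ref[i] = m;
    for (int j = i + 1; j < n; ++j) {
      int lm = std::min(len[i], len[j]);
      int mm = 0;
      for (int p = 0; p < lm; ++p)
        if (ptr[i][p] != ptr[j][p]) ++mm;
      pw(i, j) = mm;
      pw(j, i) = mm;
    }
  }
  return List::create(_["to_ref"] = to_ref, _["pairwise"] = pw);
}
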