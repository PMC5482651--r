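#include <Rcpp.h>
#include <array>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps (Gotoh). A gap of
// length L costs gap_open + L * gap_ext. Scores are integers.

struct PairAln {
  int score = 0;
  int a_start = 0, a_end = -1;  // 0-based inclusive on a (read)
  int b_start = 0, b_end = -1;  // 0-based inclusive on b (ref)
  int n_match = 0, n_mismatch = 0, n_gap = 0;
  std::string cigar;            // M/I/D w.r.t. a
};

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static PairAln sw_pair(const std::string &a, const std::string &b,
                       int match, int mismatch, int gap_open, int gap_ext,
                       bool traceback) {
  const int n = (int)a.size(), m = (int)b.size();
  PairAln best;
  if (n == 0 || m == 0) return best;
  const int NEG = -1000000000;
  const int go = gap_open + gap_ext;  // cost of opening (first gapped base)
  std::vector<int> Hprev(m + 1, 0), Hcur(m + 1, 0), Eprev(m + 1, NEG),
      Ecur(m + 1, NEG), Fcur(m + 1, NEG), Fprev(m + 1, NEG);
  // traceback: 2 bits per state per cell
  std::vector<uint8_t> tbH, tbE, tbF;
  if (traceback) {
    tbH.assign((size_t)(n + 1) * (m + 1), 0);
    tbE.assign((size_t)(n + 1) * (m + 1), 0);
    tbF.assign((size_t)(n + 1) * (m + 1), 0);
  }
  int bi = 0, bj = 0, bscore = 0;
  for (int i = 1; i <= n; ++i) {
    Hcur[0] = 0; Ecur[0] = NEG; Fcur[0] = NEG;
    const int ai = base_code(a[i - 1]);
    for (int j = 1; j <= m; ++j) {
      // E: gap consuming b (deletion from read)
      int e_open = Hcur[j - 1] - go, e_ext = Ecur[j - 1] - gap_ext;
      int e = std::max(e_open, e_ext);
      // F: gap consuming a (insertion in read)
      int f_open = Hprev[j] - go, f_ext = Fprev[j] - gap_ext;
      int f = std::max(f_open, f_ext);
      const int bj_ = base_code(b[j - 1]);
      int sub = (ai >= 0 && ai == bj_) ? match : mismatch;
      int diag = Hprev[j - 1] + sub;
      int h = std::max(std::max(0, diag), std::max(e, f));
      Ecur[j] = e; Fcur[j] = f; Hcur[j] = h;
      if (traceback) {
        size_t idx = (size_t)i * (m + 1) + j;
        tbE[idx] = (e == e_open) ? 0 : 1;
        tbF[idx] = (f == f_open) ? 0 : 1;
        uint8_t th = 0;  // stop
        if (h > 0) {
          if (h == diag) th = 1;
          else if (h == e) th = 2;
          else th = 3;
        }
        tbH[idx] = th;
      }
      if (h > bscore) { bscore = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
    std::swap(Fprev, Fcur);
  }
  best.score = bscore;
  if (bscore == 0) return best;
  best.a_end = bi - 1; best.b_end = bj - 1;
  if (!traceback) { best.a_start = 0; best.b_start = 0; return best; }
  // walk back from (bi, bj) in state H
  std::string ops;
  int i = bi, j = bj, state = 0;  // 0=H,1=E,2=F
  while (i > 0 && j > 0) {
    size_t idx = (size_t)i * (m + 1) + j;
    if (state == 0) {
      uint8_t th = tbH[idx];
      if (th == 0) break;
      if (th == 1) {
        ops.push_back('M');
        if (base_code(a[i - 1]) >= 0 && base_code(a[i - 1]) == base_code(b[j - 1]))
          best.n_match++;
        else
          best.n_mismatch++;
        --i; --j;
      } else if (th == 2) state = 1;
      else state = 2;
    } else if (state == 1) {  // E: consumed b
      ops.push_back('D');
      best.n_gap++;
      uint8_t te = tbE[idx];
      --j;
      if (te == 0) state = 0;
    } else {  // F: consumed a
      ops.push_back('I');
      best.n_gap++;
      uint8_t tf = tbF[idx];
      --i;
      if (tf == 0) state = 0;
    }
  }
  best.a_start = i; best.b_start = j;
  std::reverse(ops.begin(), ops.end());
  // run-length encode
  std::string cig;
  for (size_t p = 0; p < ops.size();) {
    size_t q = p;
    while (q < ops.size() && ops[q] == ops[p]) ++q;
    cig += std::to_string(q - p);
    cig.push_back(ops[p]);
    p = q;
  }
  best.cigar = cig;
  return best;
}

// [[Rcpp::export]]
List sw_align_pair_cpp(std::string a, std::string b, int match, int mismatch,
                       int gap_open, int gap_ext) {
  PairAln r = sw_pair(a, b, match, mismatch, gap_open, gap_ext, true);
  return List::create(
      _["score"] = r.score,
      _["a_start"] = r.a_start + 1, _["a_end"] = r.a_end + 1,
      _["b_start"] = r.b_start + 1, _["b_end"] = r.b_end + 1,
      _["n_match"] = r.n_match, _["n_mismatch"] = r.n_mismatch,
      _["n_gap"] = r.n_gap, _["cigar"] = r.cigar);
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) {
    switch (c) {
      case 'A': case 'a': c = 'T'; break;
      case 'C': case 'c': c = 'G'; break;
      case 'G': case 'g': c = 'C'; break;
      case 'T': case 't': c = 'A'; break;
      default: c = 'N';
    }
  }
  return r;
}

struct KmerIndex {
  int k;
  // per reference: map from 2-bit kmer to sorted positions (0-based)
  std::vector<std::unordered_map<uint64_t, std::vector<int>>> maps;
};

static bool encode_kmer(const std::string &s, int pos, int k, uint64_t &out) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int c = base_code(s[pos + i]);
    if (c < 0) return false;
    v = (v << 2) | (uint64_t)c;
  }
  out = v;
  return true;
}

static KmerIndex build_index(const std::vector<std::string> &refs, int k) {
  KmerIndex idx;
  idx.k = k;
  idx.maps.resize(refs.size());
  for (size_t r = 0; r < refs.size(); ++r) {
    const std::string &s = refs[r];
    if ((int)s.size() < k) continue;
    for (int p = 0; p + k <= (int)s.size(); ++p) {
      uint64_t v;
      if (encode_kmer(s, p, k, v)) idx.maps[r][v].push_back(p);
    }
  }
  return idx;
}

struct Candidate {
  int ref, strand;  // strand 0 = forward, 1 = reverse-complement of read
  int win_start, win_end;  // 0-based half-open window on ref
};

// collect candidate windows for one oriented read against one reference
static void collect_windows(const std::string &read, const KmerIndex &idx,
                            int ref, int strand, int ref_len,
                            std::vector<Candidate> &out) {
  const int k = idx.k;
  const int L = (int)read.size();
  if (L < k) return;
  int step = std::max(1, (L - k) / 16);
  std::vector<long long> diags;
  const auto &map = idx.maps[ref];
  for (int p = 0; p + k <= L; p += step) {
    uint64_t v;
    if (!encode_kmer(read, p, k, v)) continue;
    auto it = map.find(v);
    if (it == map.end()) continue;
    if (it->second.size() > 50) continue;  // highly repetitive seed
    for (int rp : it->second) diags.push_back((long long)rp - p);
  }
  if (diags.empty()) return;
  std::sort(diags.begin(), diags.end());
  const int pad = 40;
  size_t i = 0;
  while (i < diags.size()) {
    size_t j = i;
    while (j + 1 < diags.size() && diags[j + 1] - diags[j] <= 30) ++j;
    long long d0 = diags[i], d1 = diags[j];
    Candidate c;
    c.ref = ref; c.strand = strand;
    c.win_start = (int)std::max(0LL, d0 - pad);
    c.win_end = (int)std::min((long long)ref_len, d1 + L + pad);
    if (c.win_end > c.win_start) out.push_back(c);
    i = j + 1;
  }
}

// Batch seeded local alignment of reads against a reference set. For each
// read the best-scoring window alignment is reported together with the
// best score at a distinct locus (for ambiguity filtering). Coordinates on
// the read refer to its aligned orientation (reverse-complemented when
// strand == "-").
// [[Rcpp::export]]
DataFrame align_reads_cpp(CharacterVector read_names, CharacterVector reads,
                          CharacterVector ref_names, CharacterVector refs,
                          int k, int min_score, int match, int mismatch,
                          int gap_open, int gap_ext, bool both_strands) {
  std::vector<std::string> R(refs.size());
  for (int i = 0; i < refs.size(); ++i) R[i] = as<std::string>(refs[i]);
  KmerIndex idx = build_index(R, k);

  int N = reads.size();
  CharacterVector o_read(N), o_ref(N), o_strand(N), o_cigar(N);
  IntegerVector o_score(N), o_rstart(N), o_rend(N), o_qstart(N), o_qend(N),
      o_nmatch(N), o_nmm(N), o_ngap(N), o_second(N);
  LogicalVector o_found(N);

  for (int q = 0; q < N; ++q) {
    std::string fwd = as<std::string>(reads[q]);
    std::string rev = both_strands ? revcomp(fwd) : std::string();
    std::vector<Candidate> cands;
    for (size_t r = 0; r < R.size(); ++r) {
      collect_windows(fwd, idx, (int)r, 0, (int)R[r].size(), cands);
      if (both_strands)
        collect_windows(rev, idx, (int)r, 1, (int)R[r].size(), cands);
    }
    // evaluate candidates; best + best-at-distinct-locus
    int best_score = 0, second_score = 0;
    int best_ref = -1, best_strand = 0, best_ws = 0;
    PairAln best_aln;
    std::vector<std::pair<int, std::array<int, 3>>> scored;  // score, (ref,strand,refstart)
    for (const Candidate &c : cands) {
      const std::string &rd = c.strand == 0 ? fwd : rev;
      std::string window = R[c.ref].substr(c.win_start,
                                           c.win_end - c.win_start);
      PairAln a = sw_pair(rd, window, match, mismatch, gap_open, gap_ext,
                          false);
      if (a.score < min_score) continue;
      int abs_end = c.win_start + a.b_end;  // end is valid without traceback
      scored.push_back({a.score, {c.ref, c.strand, abs_end}});
      if (a.score > best_score) {
        best_score = a.score;
        best_ref = c.ref; best_strand = c.strand; best_ws = c.win_start;
      }
    }
    if (best_ref >= 0) {
      // re-align best window with traceback for exact coordinates
      const Candidate *bc = nullptr;
      for (const Candidate &c : cands)
        if (c.ref == best_ref && c.strand == best_strand &&
            c.win_start == best_ws) { bc = &c; break; }
      const std::string &rd = best_strand == 0 ? fwd : rev;
      std::string window = R[best_ref].substr(bc->win_start,
                                              bc->win_end - bc->win_start);
      best_aln = sw_pair(rd, window, match, mismatch, gap_open, gap_ext,
                         true);
      int babs_end = bc->win_start + best_aln.b_end;
      for (auto &sc : scored) {
        bool same_locus = sc.second[0] == best_ref &&
                          sc.second[1] == best_strand &&
                          std::abs(sc.second[2] - babs_end) <= 30;
        if (!same_locus && sc.first > second_score) second_score = sc.first;
      }
      o_found[q] = true;
      o_ref[q] = ref_names[best_ref];
      o_strand[q] = best_strand == 0 ? "+" : "-";
      o_score[q] = best_aln.score;
      o_rstart[q] = bc->win_start + best_aln.b_start + 1;
      o_rend[q] = bc->win_start + best_aln.b_end + 1;
      o_qstart[q] = best_aln.a_start + 1;
      o_qend[q] = best_aln.a_end + 1;
      o_nmatch[q] = best_aln.n_match;
      o_nmm[q] = best_aln.n_mismatch;
      o_ngap[q] = best_aln.n_gap;
      o_cigar[q] = best_aln.cigar;
      o_second[q] = second_score;
    } else {
      o_found[q] = false;
      o_ref[q] = NA_STRING; o_strand[q] = NA_STRING; o_cigar[q] = NA_STRING;
      o_score[q] = 0; o_rstart[q] = NA_INTEGER; o_rend[q] = NA_INTEGER;
      o_qstart[q] = NA_INTEGER; o_qend[q] = NA_INTEGER;
      o_nmatch[q] = 0; o_nmm[q] = 0; o_ngap[q] = 0; o_second[q] = 0;
    }
    o_read[q] = read_names[q];
  }
  return DataFrame::create(
      _["read_id"] = o_read, _["found"] = o_found, _["ref"] = o_ref,
      _["strand"] = o_strand, _["score"] = o_score,
      _["ref_start"] = o_rstart, _["ref_end"] = o_rend,
      _["read_start"] = o_qstart, _["read_end"] = o_qend,
      _["n_match"] = o_nmatch, _["n_mismatch"] = o_nmm, _["n_gap"] = o_ngap,
      _["cigar"] = o_cigar, _["second_score"] = o_second,
      _["stringsAsFactors"] = false);
}
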