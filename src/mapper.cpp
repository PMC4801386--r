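#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Seed-and-extend read-to-CDS assignment.
//
// Alignment space (shared contract with the R reference aligner used in the
// test suite): a candidate alignment places the *entire* read (forward or
// reverse-complemented) inside one CDS, either ungapped on a diagonal that
// carries at least one exact word_size match ("seeded" diagonal), or with
// exactly one gap of length 1..max_gap_len (in the read or in the reference)
// where at least one of the two ungapped segments lies on a seeded diagonal.
// Identity = matching columns / alignment columns (gap columns count against
// identity). Score = match*m + mismatch*mm - (gap_open + gap_extend*g) for a
// length-g gap. Per (read, CDS, strand) the best admissible (identity >=
// min_identity) alignment is kept; per read only assignments tied at the
// maximal score survive, capped at max_hits by ascending CDS identifier.

static inline int enc(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default:            return 4;  // N or anything else: never matches
  }
}

static std::vector<int8_t> encode(const std::string& s) {
  std::vector<int8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = (int8_t) enc(s[i]);
  return v;
}

static std::vector<int8_t> revcomp(const std::vector<int8_t>& v) {
  std::vector<int8_t> r(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    int8_t b = v[v.size() - 1 - i];
    r[i] = (b < 4) ? (int8_t)(3 - b) : (int8_t)4;
  }
  return r;
}

struct Hit { int cds; double score; double identity; int gap_len; char strand; };

// Best alignment of read (encoded, strand already applied) against ref,
// restricted to the given seeded diagonals. Returns true if an admissible
// alignment exists, filling score/identity/gap_len.
static bool best_alignment(const std::vector<int8_t>& rd,
                           const std::vector<int8_t>& ref,
                           const std::vector<int>& diags,
                           int max_gap_len, double min_identity,
                           int match, int mismatch, int gap_open, int gap_extend,
                           double& best_score, double& best_identity, int& best_gap) {
  const int n = (int) rd.size();
  const int L = (int) ref.size();
  bool found = false;
  best_score = -1e18;

  // match counts along a diagonal: pref[i] = matches of rd[0..i) vs ref[d..d+i)
  std::vector<int> prefA(n + 1), prefB(n + 1);
  auto fill_pref = [&](int d, std::vector<int>& pref) {
    pref[0] = 0;
    for (int i = 0; i < n; ++i) {
      int p = d + i;
      int m = (p >= 0 && p < L && rd[i] < 4 && rd[i] == ref[p]) ? 1 : 0;
      pref[i + 1] = pref[i] + m;
    }
  };

  auto consider = [&](int m, int aligned_pairs, int cols, int g) {
    int mm = aligned_pairs - m;
    double score = (double) match * m + (double) mismatch * mm;
    if (g > 0) score -= (double) gap_open + (double) gap_extend * g;
    double identity = 100.0 * (double) m / (double) cols;
    if (identity + 1e-9 < min_identity) return;
    if (score > best_score + 1e-9) {
      best_score = score; best_identity = identity; best_gap = g; found = true;
    } else if (found && score > best_score - 1e-9 && identity > best_identity + 1e-9) {
      best_identity = identity; best_gap = g;  // same score, report best identity
    }
  };

  for (size_t di = 0; di < diags.size(); ++di) {
    int d = diags[di];

    // ungapped, full read at offset d
    if (d >= 0 && d + n <= L) {
      fill_pref(d, prefA);
      consider(prefA[n], n, n, 0);
    }

    for (int g = 1; g <= max_gap_len; ++g) {
      // gap in the read row (reference has g extra bases): left segment on
      // diagonal dl, right on dl + g; the seed may be either segment.
      int dl_opts[2] = { d, d - g };
      for (int t = 0; t < 2; ++t) {
        int dl = dl_opts[t];
        int dr = dl + g;
        if (dl < 0 || dr + n > L) continue;
        fill_pref(dl, prefA);
        fill_pref(dr, prefB);
        int best_m = -1;
        for (int k = 1; k <= n - 1; ++k) {
          int m = prefA[k] + (prefB[n] - prefB[k]);
          if (m > best_m) best_m = m;
        }
        if (best_m >= 0) consider(best_m, n, n + g, g);
      }
      // gap in the reference row (g read bases unaligned): left segment on
      // dl, right segment on dr = dl - g.
      if (n - g - 1 < 1) continue;
      int dr_opts[2] = { d - g, d };  // dr = dl - g with dl in {d, d + g}
      for (int t = 0; t < 2; ++t) {
        int dr = dr_opts[t];
        int dl = dr + g;
        if (dr < 0 || dr + n > L) continue;
        fill_pref(dl, prefA);
        fill_pref(dr, prefB);
        int best_m = -1;
        for (int k = 1; k <= n - g - 1; ++k) {
          int m = prefA[k] + (prefB[n] - prefB[k + g]);
          if (m > best_m) best_m = m;
        }
        if (best_m >= 0) consider(best_m, n - g, n, g);
      }
    }
  }
  return found;
}

// [[Rcpp::export(name = ".map_reads_cpp")]]
List map_reads_cpp(CharacterVector read_seqs, CharacterVector ref_seqs,
                   CharacterVector ref_ids,
                   int word_size = 25, double min_identity = 95.0,
                   int max_gap_len = 3, int max_hits = 5,
                   int match = 2, int mismatch = -3,
                   int gap_open = 5, int gap_extend = 2) {
  const int n_ref = ref_seqs.size();
  std::vector<std::vector<int8_t> > refs(n_ref);
  std::vector<std::string> ids(n_ref);
  for (int j = 0; j < n_ref; ++j) {
    refs[j] = encode(std::string(ref_seqs[j]));
    ids[j] = std::string(ref_ids[j]);
  }

  // k-mer index over the reference (forward strand only; the read is
  // reverse-complemented instead). 2-bit encoding, k-mers with N skipped.
  if (word_size < 1 || word_size > 31) stop("word_size must be in 1..31");
  const uint64_t mask = (word_size == 31) ? ~0ULL >> 2 : ((1ULL << (2 * word_size)) - 1);
  std::unordered_map<uint64_t, std::vector<std::pair<int, int> > > index;
  for (int j = 0; j < n_ref; ++j) {
    const std::vector<int8_t>& s = refs[j];
    if ((int) s.size() < word_size) continue;
    uint64_t key = 0; int run = 0;
    for (int p = 0; p < (int) s.size(); ++p) {
      if (s[p] > 3) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t) s[p]) & mask;
      if (++run >= word_size) index[key].push_back(std::make_pair(j, p - word_size + 1));
    }
  }

  std::vector<int> out_read, out_cds, out_gap;
  std::vector<double> out_score, out_identity;
  std::vector<char> out_strand;

  const int n_reads = read_seqs.size();
  std::vector<Hit> hits;
  for (int r = 0; r < n_reads; ++r) {
    std::vector<int8_t> fwd = encode(std::string(read_seqs[r]));
    const int n = (int) fwd.size();
    hits.clear();
    if (n >= word_size && n_ref > 0) {
      for (int s = 0; s < 2; ++s) {
        std::vector<int8_t> rd = (s == 0) ? fwd : revcomp(fwd);
        // seeded diagonals per candidate CDS
        std::unordered_map<int, std::vector<int> > cand;
        uint64_t key = 0; int run = 0;
        for (int i = 0; i < n; ++i) {
          if (rd[i] > 3) { run = 0; key = 0; continue; }
          key = ((key << 2) | (uint64_t) rd[i]) & mask;
          if (++run >= word_size) {
            int rpos = i - word_size + 1;
            std::unordered_map<uint64_t, std::vector<std::pair<int, int> > >::const_iterator it = index.find(key);
            if (it != index.end()) {
              for (size_t h = 0; h < it->second.size(); ++h) {
                int cds = it->second[h].first;
                int diag = it->second[h].second - rpos;
                std::vector<int>& ds = cand[cds];
                if (std::find(ds.begin(), ds.end(), diag) == ds.end()) ds.push_back(diag);
              }
            }
          }
        }
        for (std::unordered_map<int, std::vector<int> >::iterator it = cand.begin(); it != cand.end(); ++it) {
          double sc, id; int gp;
          if (best_alignment(rd, refs[it->first], it->second, max_gap_len,
                             min_identity, match, mismatch, gap_open, gap_extend,
                             sc, id, gp)) {
            Hit h; h.cds = it->first; h.score = sc; h.identity = id;
            h.gap_len = gp; h.strand = (s == 0) ? '+' : '-';
            hits.push_back(h);
          }
        }
      }
    }
    if (hits.empty()) continue;

    // per CDS keep the better strand (ties prefer '+', i.e. first seen)
    std::unordered_map<int, size_t> best_by_cds;
    std::vector<Hit> uniq;
    for (size_t h = 0; h < hits.size(); ++h) {
      std::unordered_map<int, size_t>::iterator it = best_by_cds.find(hits[h].cds);
      if (it == best_by_cds.end()) {
        best_by_cds[hits[h].cds] = uniq.size();
        uniq.push_back(hits[h]);
      } else if (hits[h].score > uniq[it->second].score + 1e-9) {
        uniq[it->second] = hits[h];
      }
    }
    double top = -1e18;
    for (size_t h = 0; h < uniq.size(); ++h) top = std::max(top, uniq[h].score);
    std::vector<Hit> tied;
    for (size_t h = 0; h < uniq.size(); ++h)
      if (uniq[h].score > top - 1e-9) tied.push_back(uniq[h]);
    std::sort(tied.begin(), tied.end(),
              [&](const Hit& a, const Hit& b) { return ids[a.cds] < ids[b.cds]; });
    int keep = std::min((int) tied.size(), max_hits);
    for (int h = 0; h < keep; ++h) {
      out_read.push_back(r + 1);
      out_cds.push_back(tied[h].cds + 1);
      out_score.push_back(tied[h].score);
      out_identity.push_back(tied[h].identity);
      out_gap.push_back(tied[h].gap_len);
      out_strand.push_back(tied[h].strand);
    }
  }

  CharacterVector strand_out(out_strand.size());
  for (size_t i = 0; i < out_strand.size(); ++i)
    strand_out[i] = (out_strand[i] == '+') ? "+" : "-";
  return List::create(
    _["read_index"] = wrap(out_read),
    _["cds_index"] = wrap(out_cds),
    _["score"] = wrap(out_score),
    _["identity"] = wrap(out_identity),
    _["gap_len"] = wrap(out_gap),
    _["strand"] = strand_out);
}
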