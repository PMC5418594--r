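// Seeded, diagonal-chained, gap-free overlap scanner.
//
// Finds end-to-end / containment overlaps between two sequence sets by shared
// k-mer seeding and diagonal voting, then scores the best diagonal of each
// cluster by direct base comparison. Assumes substitution-style divergence
// (no alignment gaps); callers with gapped data supply external alignments.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <unordered_map>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

static inline int base2(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
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

struct Seed { uint32_t code, tgt, pos; };

// [[Rcpp::export]]
DataFrame overlap_scan_cpp(CharacterVector q_ids, CharacterVector q_seqs,
                           CharacterVector t_ids, CharacterVector t_seqs,
                           int k, int min_len, double min_identity,
                           int seed_step, int min_votes, int band,
                           int max_occ, bool skip_same_id) {
  if (k < 11 || k > 15) stop("k must be in [11, 15]");
  const int nq = q_seqs.size(), nt = t_seqs.size();
  std::vector<std::string> qs(nq), ts(nt);
  for (int i = 0; i < nq; ++i) qs[i] = as<std::string>(q_seqs[i]);
  for (int i = 0; i < nt; ++i) ts[i] = as<std::string>(t_seqs[i]);

  // --- index every k-mer of the target set ---
  std::vector<Seed> index;
  {
    size_t total = 0;
    for (const auto& s : ts) if (s.size() >= (size_t)k) total += s.size() - k + 1;
    index.reserve(total);
  }
  const uint32_t mask = (k == 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1u);
  for (int j = 0; j < nt; ++j) {
    const std::string& s = ts[j];
    uint32_t code = 0; int valid = 0;
    for (size_t p = 0; p < s.size(); ++p) {
      int b = base2(s[p]);
      if (b < 0) { valid = 0; code = 0; continue; }
      code = ((code << 2) | (uint32_t)b) & mask;
      if (++valid >= k) index.push_back({code, (uint32_t)j, (uint32_t)(p - k + 1)});
    }
  }
  std::sort(index.begin(), index.end(),
            [](const Seed& a, const Seed& b) { return a.code < b.code; });

  auto lower = [&](uint32_t code) {
    return std::lower_bound(index.begin(), index.end(), code,
                            [](const Seed& s, uint32_t c) { return s.code < c; });
  };

  std::vector<std::string> out_q, out_t, out_strand;
  std::vector<double> out_qs, out_qe, out_ql, out_ts, out_te, out_tl, out_m, out_al;

  for (int i = 0; i < nq; ++i) {
    const long qlen = (long)qs[i].size();
    if (qlen < k) continue;
    for (int strand = 0; strand < 2; ++strand) {
      std::string seq = strand == 0 ? qs[i] : revcomp(qs[i]);
      // vote per (target, exact diagonal)
      std::unordered_map<int64_t, int> votes;
      uint32_t code = 0; int valid = 0;
      for (long p = 0; p < qlen; ++p) {
        int b = base2(seq[p]);
        if (b < 0) { valid = 0; code = 0; continue; }
        code = ((code << 2) | (uint32_t)b) & mask;
        ++valid;
        long qpos = p - k + 1;
        if (valid < k || (qpos % seed_step) != 0) continue;
        auto it = lower(code);
        auto end = it;
        while (end != index.end() && end->code == code) ++end;
        if (end - it > max_occ) continue;
        for (; it != end; ++it) {
          if (skip_same_id && q_ids[i] == t_ids[it->tgt]) continue;
          int64_t diag = (int64_t)it->pos - qpos;
          votes[((int64_t)it->tgt << 32) | (uint32_t)(diag + qlen)]++;
        }
      }
      // cluster diagonals per target within +/- band, keep max-vote diagonal
      std::vector<std::pair<int64_t, int>> keys;
      keys.reserve(votes.size());
      for (auto& kv : votes)
        if (kv.second >= min_votes) keys.push_back(kv);
      std::sort(keys.begin(), keys.end());
      size_t a = 0;
      while (a < keys.size()) {
        size_t b2 = a;
        int64_t tgt = keys[a].first >> 32;
        while (b2 + 1 < keys.size() && (keys[b2 + 1].first >> 32) == tgt &&
               ((int64_t)(uint32_t)(keys[b2 + 1].first) -
                (int64_t)(uint32_t)(keys[b2].first)) <= band) {
          ++b2;
        }
        // evaluate the strongest exact diagonals of the cluster (several:
        // distinct homologous runs may sit on slightly shifted diagonals)
        std::vector<std::pair<int, int64_t>> dl;
        for (size_t c = a; c <= b2; ++c)
          dl.push_back({-keys[c].second,
                        (int64_t)(uint32_t)(keys[c].first) - qlen});
        std::sort(dl.begin(), dl.end());
        if (dl.size() > 64) dl.resize(64);
        for (auto& dv : dl) {
        int64_t best_diag = dv.second;
        const std::string& tseq = ts[(size_t)tgt];
        const long tlen = (long)tseq.size();
        long q0 = std::max((long)0, -best_diag);
        long q1 = std::min(qlen, tlen - best_diag);
        if (q1 - q0 >= min_len) {
          // trim to the best-matching segment along the diagonal (local
          // max-subarray), so internal overlaps are not diluted by
          // non-homologous flanks
          const long MIS = 4;
          long run = 0, best_sc = 0, best_s = q0, best_e = q0, cur_s = q0;
          for (long p = q0; p < q1; ++p) {
            char cq = seq[p], ct = tseq[p + best_diag];
            if (cq >= 'a') cq -= 32;
            if (ct >= 'a') ct -= 32;
            long sc = (cq == ct && cq != 'N') ? 1 : -MIS;
            if (run <= 0) { run = sc; cur_s = p; } else run += sc;
            if (run > best_sc) { best_sc = run; best_s = cur_s; best_e = p + 1; }
          }
          q0 = best_s; q1 = best_e;
          long span = q1 - q0;
          long matches = 0;
          for (long p = q0; p < q1; ++p) {
            char cq = seq[p], ct = tseq[p + best_diag];
            if (cq >= 'a') cq -= 32;
            if (ct >= 'a') ct -= 32;
            if (cq == ct && cq != 'N') ++matches;
          }
          if (span >= min_len && (double)matches / span >= min_identity) {
            long oqs = q0, oqe = q1;
            if (strand == 1) { oqs = qlen - q1; oqe = qlen - q0; }
            out_q.push_back(as<std::string>(q_ids[i]));
            out_t.push_back(as<std::string>(t_ids[(size_t)tgt]));
            out_strand.push_back(strand == 0 ? "+" : "-");
            out_qs.push_back((double)oqs); out_qe.push_back((double)oqe);
            out_ql.push_back((double)qlen);
            out_ts.push_back((double)(q0 + best_diag));
            out_te.push_back((double)(q1 + best_diag));
            out_tl.push_back((double)tlen);
            out_m.push_back((double)matches); out_al.push_back((double)span);
          }
        }
        }
        a = b2 + 1;
      }
    }
  }

  return DataFrame::create(
      _["query_id"] = out_q, _["target_id"] = out_t, _["strand"] = out_strand,
      _["q_start"] = out_qs, _["q_end"] = out_qe, _["q_len"] = out_ql,
      _["t_start"] = out_ts, _["t_end"] = out_te, _["t_len"] = out_tl,
      _["matches"] = out_m, _["aln_len"] = out_al,
      _["stringsAsFactors"] = false);
}
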