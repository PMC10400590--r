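#include <Rcpp.h>
#include <unordered_map>
using namespace Rcpp;

// Three-letter (bisulfite) seed-and-extend aligner for toy genomes.
//
// The reference is held twice per contig in C->T converted space: the forward
// strand and the reverse complement. A read is queried as-is (C->T converted)
// against both — hits are original-top (OT) or original-bottom (OB) — and as
// its reverse complement (again C->T converted), which handles the
// complementary-strand (PBAT-like) orientations CTOT and CTOB. Candidate loci
// come from exact k-mer seeds at the read start and mid-read; extension is a
// full-length mismatch count (the simulator emits no indels, so the edit band
// is substitution-only). Only a unique best hit — strictly better than the
// runner-up — with at most `max_edit` mismatches is reported.

static inline char comp_base(char b) {
  switch (b) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default: return 'N';
  }
}

static inline int base2bit(char b) {
  switch (b) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

static bool hash_kmer(const std::string& s, int pos, int k, uint64_t* out) {
  uint64_t h = 0;
  for (int i = 0; i < k; ++i) {
    const int b = base2bit(s[pos + i]);
    if (b < 0) return false;
    h = (h << 2) | (uint64_t)b;
  }
  *out = h;
  return true;
}

static std::string ct_convert(const std::string& s) {
  std::string out = s;
  for (size_t i = 0; i < out.size(); ++i)
    if (out[i] == 'C') out[i] = 'T';
  return out;
}

static std::string revcomp(const std::string& s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i)
    out[i] = comp_base(s[s.size() - 1 - i]);
  return out;
}

// [[Rcpp::export]]
DataFrame cpp_bs_align(CharacterVector reads,
                       CharacterVector conv_fwd,
                       CharacterVector conv_rev,
                       int k, int max_edit) {
  const int n_contig = conv_fwd.size();
  if (conv_rev.size() != n_contig)
    stop("conv_fwd and conv_rev must have the same length");
  // reference set: [0, n) forward-converted, [n, 2n) reverse-converted
  std::vector<std::string> refs(2 * n_contig);
  uint64_t max_len = 0;
  for (int c = 0; c < n_contig; ++c) {
    refs[c] = as<std::string>(conv_fwd[c]);
    refs[n_contig + c] = as<std::string>(conv_rev[c]);
    if (refs[c].size() != refs[n_contig + c].size())
      stop("converted strand lengths differ for contig %d", c + 1);
    max_len = std::max(max_len, (uint64_t)refs[c].size());
  }
  const uint64_t stride = max_len + 1;

  std::unordered_map<uint64_t, std::vector<uint64_t> > index;
  index.reserve((size_t)(2 * n_contig) * (size_t)max_len / 2);
  for (int r = 0; r < 2 * n_contig; ++r) {
    const std::string& ref = refs[r];
    if ((int)ref.size() < k) continue;  // contig shorter than the seed
    for (int p = 0; p + k <= (int)ref.size(); ++p) {
      uint64_t h;
      if (hash_kmer(ref, p, k, &h))
        index[h].push_back((uint64_t)r * stride + (uint64_t)p);
    }
  }

  const int n = reads.size();
  IntegerVector out_contig(n), out_start(n), out_end(n), out_mode(n),
      out_nm(n), out_status(n);

  std::vector<uint64_t> cand_keys;
  for (int i = 0; i < n; ++i) {
    const std::string raw = as<std::string>(reads[i]);
    const int l = (int)raw.size();
    out_contig[i] = NA_INTEGER; out_start[i] = NA_INTEGER;
    out_end[i] = NA_INTEGER; out_mode[i] = NA_INTEGER;
    out_nm[i] = NA_INTEGER; out_status[i] = 0;
    if (l < k) continue;

    const std::string q[2] = { ct_convert(raw), ct_convert(revcomp(raw)) };
    int best_nm = l + 1, second_nm = l + 1;
    uint64_t best_key = 0;
    int best_orient = -1;
    cand_keys.clear();

    for (int orient = 0; orient < 2; ++orient) {
      const std::string& query = q[orient];
      int offsets[2] = { 0, (l - k) / 2 };
      const int n_off = (offsets[1] == 0) ? 1 : 2;
      for (int oi = 0; oi < n_off; ++oi) {
        uint64_t h;
        if (!hash_kmer(query, offsets[oi], k, &h)) continue;
        auto it = index.find(h);
        if (it == index.end()) continue;
        for (uint64_t enc : it->second) {
          const int r = (int)(enc / stride);
          const long pos = (long)(enc % stride) - offsets[oi];
          if (pos < 0 || pos + l > (long)refs[r].size()) continue;
          const uint64_t key =
              ((uint64_t)r * stride + (uint64_t)pos) * 2u + (uint64_t)orient;
          bool seen = false;
          for (uint64_t ck : cand_keys) if (ck == key) { seen = true; break; }
          if (seen) continue;
          cand_keys.push_back(key);
          // extension: mismatch count with early abandon
          const std::string& ref = refs[r];
          const int cap = second_nm;  // beyond this the hit cannot matter
          int nm = 0;
          for (int j = 0; j < l; ++j) {
            if (query[j] != ref[pos + j] && ++nm > cap) break;
          }
          if (nm < best_nm) {
            second_nm = best_nm;
            best_nm = nm; best_key = key; best_orient = orient;
          } else if (nm < second_nm) {
            second_nm = nm;
          }
        }
      }
    }

    if (best_nm > max_edit) { out_status[i] = 0; continue; }       // unmapped
    if (best_nm >= second_nm) { out_status[i] = 2; continue; }     // ambiguous
    const uint64_t enc = best_key / 2u;
    const int r = (int)(enc / stride);
    const int pos = (int)(enc % stride);
    int contig, start, mode;
    if (r < n_contig) {
      contig = r; start = pos;
      mode = (best_orient == 0) ? 0 : 2;  // OT : CTOT
    } else {
      contig = r - n_contig;
      const int L = (int)refs[contig].size();
      start = L - pos - l;
      mode = (best_orient == 0) ? 1 : 3;  // OB : CTOB
    }
    out_contig[i] = contig + 1;  // 1-based contig index for R
    out_start[i] = start;
    out_end[i] = start + l;
    out_mode[i] = mode;
    out_nm[i] = best_nm;
    out_status[i] = 1;
  }

  return DataFrame::create(_["contig_idx"] = out_contig,
                           _["start"] = out_start, _["end"] = out_end,
                           _["mode_idx"] = out_mode, _["nm"] = out_nm,
                           _["status"] = out_status);
}
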