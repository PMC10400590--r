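#include <Rcpp.h>
using namespace Rcpp;

// Per-cytosine methylation observations from uniquely aligned reads.
//
// The orientation mode fixes the informative strand: OT/CTOT reads report the
// top-strand cytosines of the forward reference, OB/CTOB reads the
// bottom-strand cytosines. A retained C in the (orientation-restored) read at
// a reference cytosine is a methylated call, a T an unmethylated call; any
// other base (a sequencing error) is ignored rather than counted in coverage.
// Context is the reference trinucleotide on the cytosine's own strand; the
// site is CpG when the next base on that strand is G.

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
  default: return 0;  // out-of-range context padded with A
  }
}

// [[Rcpp::export]]
DataFrame cpp_call_meth(CharacterVector read_seqs,
                        IntegerVector contig_idx,   // 1-based
                        IntegerVector start0,
                        IntegerVector mode_idx,     // 0 OT, 1 OB, 2 CTOT, 3 CTOB
                        CharacterVector genome) {
  const int n_contig = genome.size();
  std::vector<std::string> contigs(n_contig);
  for (int c = 0; c < n_contig; ++c)
    contigs[c] = as<std::string>(genome[c]);

  std::vector<int> v_contig, v_pos, v_strand, v_ctx, v_meth;
  const int n = read_seqs.size();
  v_contig.reserve(n * 16);
  v_pos.reserve(n * 16);
  v_strand.reserve(n * 16);
  v_ctx.reserve(n * 16);
  v_meth.reserve(n * 16);

  std::string overlay;
  for (int i = 0; i < n; ++i) {
    const int c = contig_idx[i] - 1;
    const int s = start0[i];
    const int mode = mode_idx[i];
    const std::string& S = contigs[c];
    const int L = (int)S.size();
    std::string seq = as<std::string>(read_seqs[i]);
    const int l = (int)seq.size();
    if (s < 0 || s + l > L) stop("alignment outside contig bounds");

    // restore the read to template-strand orientation
    if (mode == 2 || mode == 3) {
      overlay.resize(l);
      for (int j = 0; j < l; ++j) overlay[j] = comp_base(seq[l - 1 - j]);
    } else {
      overlay = seq;
    }

    if (mode == 0 || mode == 2) {
      // top strand: overlay runs left-to-right over S[s, s+l)
      for (int j = 0; j < l; ++j) {
        const int pos = s + j;
        if (S[pos] != 'C') continue;
        const char b = overlay[j];
        int meth;
        if (b == 'C') meth = 1; else if (b == 'T') meth = 0; else continue;
        const char n1 = (pos + 1 < L) ? S[pos + 1] : 'N';
        const char n2 = (pos + 2 < L) ? S[pos + 2] : 'N';
        v_contig.push_back(c + 1);
        v_pos.push_back(pos);
        v_strand.push_back(0);
        v_ctx.push_back(base2bit(n1) * 4 + base2bit(n2) +
                        ((n1 == 'G') ? 64 : 0));
        v_meth.push_back(meth);
      }
    } else {
      // bottom strand: overlay[j] sits over forward position s + l - 1 - j,
      // a bottom-strand cytosine wherever the forward base is G
      for (int j = 0; j < l; ++j) {
        const int pos = s + l - 1 - j;
        if (S[pos] != 'G') continue;
        const char b = overlay[j];
        int meth;
        if (b == 'C') meth = 1; else if (b == 'T') meth = 0; else continue;
        const char n1 = (pos - 1 >= 0) ? comp_base(S[pos - 1]) : 'N';
        const char n2 = (pos - 2 >= 0) ? comp_base(S[pos - 2]) : 'N';
        v_contig.push_back(c + 1);
        v_pos.push_back(pos);
        v_strand.push_back(1);
        v_ctx.push_back(base2bit(n1) * 4 + base2bit(n2) +
                        ((n1 == 'G') ? 64 : 0));
        v_meth.push_back(meth);
      }
    }
  }

  return DataFrame::create(_["contig_idx"] = v_contig, _["pos0"] = v_pos,
                           _["strand_idx"] = v_strand, _["ctx_code"] = v_ctx,
                           _["meth"] = v_meth);
}
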