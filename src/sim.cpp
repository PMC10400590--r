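#include <Rcpp.h>
using namespace Rcpp;

static inline char comp_base(char b) {
  switch (b) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i)
    out[i] = comp_base(s[s.size() - 1 - i]);
  return out;
}

// Simulate bisulfite-converted fragments.
//
// For each fragment the template strand is read 5'->3'; every cytosine on the
// template draws its methylation state from the owning cell type's per-site
// probability, unmethylated cytosines are deaminated (read as T) with
// probability `conversion_rate`, and the two mates are cut from the converted
// template: R2 reads the template from its 5' end, R1 reads the random-primed
// complementary strand (so R1 carries the opposite-strand, G->A-looking
// pattern). Methylation probabilities are supplied per (type, contig) as a
// full-length vector indexed by forward-genome position; position i refers to
// the top-strand cytosine when the base is C and to the bottom-strand cytosine
// when the base is G.
//
// [[Rcpp::export]]
List cpp_simulate_fragments(CharacterVector contig_seqs,
                            IntegerVector frag_contig,
                            IntegerVector frag_start,
                            IntegerVector frag_len,
                            IntegerVector frag_strand,
                            IntegerVector frag_type,
                            List probs_full,   // probs_full[[type]][[contig]]
                            double conversion_rate,
                            int r1_len, int r2_len,
                            bool store_states) {
  RNGScope scope;
  const int n_frag = frag_contig.size();
  const int n_contig = contig_seqs.size();
  std::vector<std::string> contigs(n_contig);
  for (int c = 0; c < n_contig; ++c)
    contigs[c] = as<std::string>(contig_seqs[c]);

  const int n_types = probs_full.size();
  std::vector<std::vector<NumericVector> > P(n_types);
  for (int t = 0; t < n_types; ++t) {
    List per_contig = probs_full[t];
    if (per_contig.size() != n_contig)
      stop("probs_full[[%d]] must have one vector per contig", t + 1);
    for (int c = 0; c < n_contig; ++c)
      P[t].push_back(as<NumericVector>(per_contig[c]));
  }

  CharacterVector r1(n_frag), r2(n_frag);
  IntegerVector cg_m(n_frag), cg_t(n_frag), ch_m(n_frag), ch_t(n_frag);
  CharacterVector states(store_states ? n_frag : 0);

  std::string tmpl, st;
  for (int f = 0; f < n_frag; ++f) {
    const int c = frag_contig[f], s = frag_start[f], l = frag_len[f];
    const int ty = frag_type[f], strand = frag_strand[f];
    const std::string& S = contigs[c];
    const int L = (int)S.size();
    if (s < 0 || s + l > L) stop("fragment outside contig bounds");
    const NumericVector& pv = P[ty][c];

    tmpl.resize(l);
    if (strand == 0) {
      for (int j = 0; j < l; ++j) tmpl[j] = S[s + j];
    } else {
      for (int j = 0; j < l; ++j) tmpl[j] = comp_base(S[s + l - 1 - j]);
    }
    if (store_states) st.clear();
    int cgm = 0, cgt = 0, chm = 0, cht = 0;
    for (int j = 0; j < l; ++j) {
      if (tmpl[j] != 'C') continue;
      const int i = (strand == 0) ? s + j : s + l - 1 - j;
      const double p = pv[i];
      const bool meth = unif_rand() < p;
      if (!meth && unif_rand() < conversion_rate) tmpl[j] = 'T';
      // genomic CG/CH context on the template strand
      bool is_cg;
      if (strand == 0) {
        is_cg = (i + 1 < L) && S[i + 1] == 'G';
      } else {
        is_cg = (i - 1 >= 0) && S[i - 1] == 'C';
      }
      if (is_cg) { cgt++; if (meth) cgm++; }
      else       { cht++; if (meth) chm++; }
      if (store_states) st.push_back(meth ? 'M' : 'U');
    }
    cg_m[f] = cgm; cg_t[f] = cgt; ch_m[f] = chm; ch_t[f] = cht;
    if (store_states) states[f] = st;

    const int l2 = std::min(r2_len, l);
    r2[f] = tmpl.substr(0, l2);
    std::string rc = revcomp(tmpl);
    const int l1 = std::min(r1_len, l);
    r1[f] = rc.substr(0, l1);
  }

  List out = List::create(_["r1"] = r1, _["r2"] = r2,
                          _["cg_meth"] = cg_m, _["cg_total"] = cg_t,
                          _["ch_meth"] = ch_m, _["ch_total"] = ch_t);
  if (store_states) out["states"] = states;
  return out;
}

// Random fixed-length strings over an alphabet, one RNG draw per character.
// [[Rcpp::export]]
CharacterVector cpp_random_strings(int n, int len, CharacterVector alphabet,
                                   NumericVector weights) {
  RNGScope scope;
  const int a = alphabet.size();
  std::vector<char> letters(a);
  for (int i = 0; i < a; ++i) letters[i] = as<std::string>(alphabet[i])[0];
  std::vector<double> cum(a);
  double tot = 0;
  for (int i = 0; i < a; ++i) { tot += weights[i]; cum[i] = tot; }
  CharacterVector out(n);
  std::string s(len, 'A');
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < len; ++j) {
      const double u = unif_rand() * tot;
      int b = 0;
      while (b < a - 1 && u > cum[b]) ++b;
      s[j] = letters[b];
    }
    out[i] = s;
  }
  return out;
}

// Uniform substitution sequencing errors applied in place over a character
// vector of reads; returns the mutated copy. Uses the R RNG.
// [[Rcpp::export]]
CharacterVector cpp_apply_seq_error(CharacterVector reads, double error_rate) {
  RNGScope scope;
  const char bases[4] = {'A', 'C', 'G', 'T'};
  CharacterVector out(reads.size());
  for (int i = 0; i < reads.size(); ++i) {
    std::string s = as<std::string>(reads[i]);
    const int n_err = (int)R::rbinom((double)s.size(), error_rate);
    for (int e = 0; e < n_err; ++e) {
      const int pos = (int)(unif_rand() * s.size());
      char nb = bases[(int)(unif_rand() * 4)];
      while (nb == s[pos]) nb = bases[(int)(unif_rand() * 4)];
      s[pos] = nb;
    }
    out[i] = s;
  }
  out.attr("names") = reads.attr("names");
  return out;
}
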