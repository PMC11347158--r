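#include <Rcpp.h>
using namespace Rcpp;

// Leftmost position at which a prefix of the adapter matches the read
// suffix with at most floor(mismatch_rate * overlap) mismatches.
// Returns, per read, the number of bases kept (0 = adapter at read start,
// -1 = no adapter found).
// [[Rcpp::export(name = ".find_adapter_cpp")]]
IntegerVector find_adapter_cpp(CharacterVector reads, std::string adapter,
                               int min_overlap, double mismatch_rate) {
  const int n = reads.size();
  const int alen = adapter.size();
  IntegerVector cut(n);
  for (int i = 0; i < n; ++i) {
    const char *r = CHAR(STRING_ELT(reads, i));
    const int len = LENGTH(STRING_ELT(reads, i));
    int found = -1;
    for (int j = 0; j <= len - min_overlap; ++j) {
      const int k = std::min(alen, len - j);
      const int allowed = (int)std::floor(mismatch_rate * k);
      int mm = 0;
      for (int b = 0; b < k && mm <= allowed; ++b)
        if (r[j + b] != adapter[b]) ++mm;
      if (mm <= allowed) { found = j; break; }
    }
    cut[i] = found;
  }
  return cut;
}

// Ungapped conversion-aware assignment of inserts to templates.
//
// For each insert and each template offset, score = matches where a
// template T read as C counts as a match but is recorded as a conversion.
// Best unit wins; ties across different units leave the read unassigned.
// A read is kept only if non-conversion mismatches <= nm_max and the
// mapping integrity passes integrity_min (integrity counts conversions as
// mismatches when conv_in_integrity is true).
//
// weights allows deduplicated inserts: each insert contributes weight[i]
// reads to the accumulated per-position coverage/conversion counts.
//
// Returns per-insert assignment (1-based unit, 0 unassigned), offset
// (0-based), conversion and mismatch counts of the winning placement, and
// per-unit accumulated coverage / C-count vectors over template positions.
// [[Rcpp::export(name = ".align_count_cpp")]]
List align_count_cpp(CharacterVector inserts, CharacterVector templates,
                     IntegerVector weights, int nm_max, double integrity_min,
                     bool conv_in_integrity,
                     IntegerVector o_min, IntegerVector end_max) {
  const int n = inserts.size(), nu = templates.size();
  std::vector<std::string> tmpl(nu);
  for (int u = 0; u < nu; ++u) tmpl[u] = as<std::string>(templates[u]);

  IntegerVector unit(n), offset(n), n_conv(n), n_mm(n);
  std::vector<std::vector<int>> cov(nu), ccnt(nu);
  for (int u = 0; u < nu; ++u) {
    cov[u].assign(tmpl[u].size(), 0);
    ccnt[u].assign(tmpl[u].size(), 0);
  }

  for (int i = 0; i < n; ++i) {
    const char *ins = CHAR(STRING_ELT(inserts, i));
    const int ilen = LENGTH(STRING_ELT(inserts, i));
    int best_score = -1, best_unit = -1, best_off = -1;
    int best_conv = 0, best_mm = 0;
    bool tie = false;
    for (int u = 0; u < nu; ++u) {
      const int tlen = tmpl[u].size();
      if (ilen > tlen) continue;
      int u_best = -1, u_off = -1, u_conv = 0, u_mm = 0;
      const int hi = std::min(tlen, end_max[u]);
      for (int o = std::max(0, o_min[u]); o + ilen <= hi; ++o) {
        int m = 0, cv = 0;
        for (int b = 0; b < ilen; ++b) {
          const char t = tmpl[u][o + b], r = ins[b];
          if (r == t) ++m;
          else if (t == 'T' && r == 'C') { ++m; ++cv; }
        }
        if (m > u_best) {
          u_best = m; u_off = o; u_conv = cv; u_mm = ilen - m;
        }
      }
      if (u_best < 0) continue;
      if (u_best > best_score) {
        best_score = u_best; best_unit = u; best_off = u_off;
        best_conv = u_conv; best_mm = u_mm; tie = false;
      } else if (u_best == best_score) {
        tie = true;
      }
    }
    if (best_unit < 0 || tie) { unit[i] = 0; continue; }
    const int match_excl_conv = best_score - best_conv;
    const double integ = conv_in_integrity
      ? (double)match_excl_conv / ilen
      : (double)best_score / ilen;
    if (best_mm > nm_max || integ < integrity_min) { unit[i] = 0; continue; }
    unit[i] = best_unit + 1;
    offset[i] = best_off;
    n_conv[i] = best_conv;
    n_mm[i] = best_mm;
    const int w = weights[i];
    for (int b = 0; b < ilen; ++b) {
      const int p = best_off + b;
      cov[best_unit][p] += w;
      if (tmpl[best_unit][p] == 'T' && ins[b] == 'C') ccnt[best_unit][p] += w;
    }
  }

  List cov_out(nu), ccnt_out(nu);
  for (int u = 0; u < nu; ++u) {
    cov_out[u] = IntegerVector(cov[u].begin(), cov[u].end());
    ccnt_out[u] = IntegerVector(ccnt[u].begin(), ccnt[u].end());
  }
  return List::create(_["unit"] = unit, _["offset"] = offset,
                      _["n_conv"] = n_conv, _["n_mm"] = n_mm,
                      _["cov"] = cov_out, _["ccnt"] = ccnt_out);
}
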