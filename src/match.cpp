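#include <Rcpp.h>
using namespace Rcpp;

// Sequences are encoded as IUPAC bitmasks: A=1, C=2, G=4, T=8, ambiguity
// codes are bitwise ORs.  A probe position matches a target base when the
// masks intersect; mismatch counting is therefore degenerate-aware on the
// probe side while targets stay concrete.  Hot loops use raw int pointers.

// [[Rcpp::export]]
int mm_count_c(IntegerVector oligo, IntegerVector window) {
  const int L = oligo.size();
  if (window.size() != L) stop("oligo and window must have equal length");
  const int *o = INTEGER(oligo), *w = INTEGER(window);
  int mm = 0;
  for (int i = 0; i < L; ++i)
    if ((o[i] & w[i]) == 0) ++mm;
  return mm;
}

// Minimum mismatch count over all windows; ties resolved to smallest start.
// Returns 0-based start.
// [[Rcpp::export]]
List scan_min_c(IntegerVector oligo, IntegerVector target) {
  const int L = oligo.size(), N = target.size();
  if (N < L) stop("target shorter than oligo");
  const int *o = INTEGER(oligo), *t = INTEGER(target);
  int best = L + 1, bestStart = 0;
  for (int s = 0; s + L <= N; ++s) {
    int mm = 0;
    for (int i = 0; i < L; ++i) {
      if ((o[i] & t[s + i]) == 0) {
        ++mm;
        if (mm >= best) break;
      }
    }
    if (mm < best) {
      best = mm;
      bestStart = s;
      if (best == 0) break;  // cannot improve; smallest start already held
    }
  }
  return List::create(_["mismatches"] = best, _["start"] = bestStart);
}

// All windows with mm <= max_mm and zero mismatches inside the clamp
// region.  clamp_at_start = false: clamp covers the last `clamp` oligo
// positions (primer given 5'->3' matching the plus strand left to right);
// true: the first `clamp` positions (reverse-complemented primer scanned
// on the plus strand).  Starts are 0-based.
// [[Rcpp::export]]
DataFrame scan_sites_c(IntegerVector oligo, IntegerVector target, int max_mm,
                       int clamp, bool clamp_at_start) {
  const int L = oligo.size(), N = target.size();
  if (N < L) stop("target shorter than oligo");
  if (clamp > L) stop("clamp longer than oligo");
  const int *o = INTEGER(oligo), *t = INTEGER(target);
  std::vector<int> starts, mms;
  for (int s = 0; s + L <= N; ++s) {
    int mm = 0;
    bool ok = true;
    for (int i = 0; i < L; ++i) {
      if ((o[i] & t[s + i]) == 0) {
        bool in_clamp = clamp_at_start ? (i < clamp) : (i >= L - clamp);
        if (in_clamp) { ok = false; break; }
        ++mm;
        if (mm > max_mm) { ok = false; break; }
      }
    }
    if (ok) { starts.push_back(s); mms.push_back(mm); }
  }
  return DataFrame::create(_["start"] = wrap(starts),
                           _["mismatches"] = wrap(mms));
}

// Per-strain minimum mismatches of one oligo over both strands (exact).
// fwd/rc: lists of encoded strain sequences (plus strand / reverse
// complement).
// [[Rcpp::export]]
IntegerVector scan_min_all_c(IntegerVector oligo, List fwd, List rc) {
  const int n = fwd.size(), L = oligo.size();
  const int *o = INTEGER(oligo);
  IntegerVector out(n);
  for (int k = 0; k < n; ++k) {
    int best = L + 1;
    for (int strand = 0; strand < 2; ++strand) {
      SEXP ts = (strand == 0) ? VECTOR_ELT(fwd, k) : VECTOR_ELT(rc, k);
      const int *t = INTEGER(ts);
      const int N = Rf_length(ts);
      for (int s = 0; s + L <= N && best > 0; ++s) {
        int mm = 0;
        for (int i = 0; i < L; ++i) {
          if ((o[i] & t[s + i]) == 0) {
            ++mm;
            if (mm >= best) break;
          }
        }
        if (mm < best) best = mm;
      }
      if (best == 0) break;
    }
    out[k] = best;
  }
  return out;
}

// Specificity of candidate windows on a group profile against both
// strands of every non-target strain, in two phases.  Phase 1 prunes with
// an upper bound: the candidate's mismatch count in the unshifted
// (homologous) window of each strain; a value below floor_mm proves
// failure.  Phase 2 computes the exact minimum over every window of every
// surviving strain via per-diagonal mismatch prefix sums (branchless
// range queries), so min_mm and nearest (1-based strain index) are exact
// for every passing candidate; candidates pruned in phase 1 report
// pass = FALSE with their (partial) bound.
// [[Rcpp::export]]
List specificity_scan_c(IntegerVector cand_start, IntegerVector cand_len,
                        IntegerVector profile, List fwd, List rc,
                        IntegerVector nontarget_idx, int floor_mm) {
  const int nc = cand_start.size(), nt = nontarget_idx.size();
  const int *cs = INTEGER(cand_start), *cl = INTEGER(cand_len);
  const int *prof = INTEGER(profile), *idx = INTEGER(nontarget_idx);
  const int P = profile.size();
  IntegerVector minmm(nc), nearest(nc);
  LogicalVector pass(nc);
  std::vector<char> alive(nc, 1);
  std::vector<int> best(nc, INT_MAX), bi(nc, NA_INTEGER);
  std::vector<int> pref(P + 1);

  // phase 1: homologous-window upper bound on the forward strand
  for (int k = 0; k < nt; ++k) {
    const int si = idx[k] - 1;
    SEXP ts = VECTOR_ELT(fwd, si);
    const int *t = INTEGER(ts);
    const int ov = std::min(P, (int)Rf_length(ts));
    pref[0] = 0;
    for (int p = 0; p < ov; ++p)
      pref[p + 1] = pref[p] + ((prof[p] & t[p]) == 0 ? 1 : 0);
    for (int ci = 0; ci < nc; ++ci) {
      if (!alive[ci] || cs[ci] + cl[ci] > ov) continue;
      const int mm = pref[cs[ci] + cl[ci]] - pref[cs[ci]];
      if (mm < best[ci]) { best[ci] = mm; bi[ci] = si + 1; }
      if (mm < floor_mm) alive[ci] = 0;
    }
  }

  // phase 2: exact minimum for the survivors over all diagonals
  std::vector<int> act;
  for (int ci = 0; ci < nc; ++ci) if (alive[ci]) act.push_back(ci);
  if (!act.empty()) {
    for (int k = 0; k < nt; ++k) {
      const int si = idx[k] - 1;
      for (int strand = 0; strand < 2; ++strand) {
        SEXP ts = (strand == 0) ? VECTOR_ELT(fwd, si) : VECTOR_ELT(rc, si);
        const int *t = INTEGER(ts);
        const int N = Rf_length(ts);
        for (int d = -(P - 1); d <= N - 1; ++d) {
          const int pLo = std::max(0, -d);
          const int pHi = std::min(P, N - d);  // exclusive
          if (pHi - pLo <= 0) continue;
          pref[pLo] = 0;
          for (int p = pLo; p < pHi; ++p)
            pref[p + 1] = pref[p] + ((prof[p] & t[p + d]) == 0 ? 1 : 0);
          for (size_t a = 0; a < act.size(); ++a) {
            const int ci = act[a];
            const int i = cs[ci], L = cl[ci];
            if (i < pLo || i + L > pHi) continue;
            const int mm = pref[i + L] - pref[i];
            if (mm < best[ci]) { best[ci] = mm; bi[ci] = si + 1; }
          }
        }
      }
    }
  }
  for (int ci = 0; ci < nc; ++ci) {
    minmm[ci] = best[ci] == INT_MAX ? cl[ci] + 1 : best[ci];
    nearest[ci] = bi[ci];
    pass[ci] = alive[ci] && minmm[ci] >= floor_mm;
  }
  return List::create(_["min_mm"] = minmm, _["nearest"] = nearest,
                      _["pass"] = pass);
}

// Fraction of the given strains perfect-matched (0 mismatches, either
// strand) by each candidate window.
// [[Rcpp::export]]
NumericVector batch_coverage_c(IntegerVector cand_start, IntegerVector cand_len,
                               IntegerVector profile, List fwd, List rc,
                               IntegerVector strain_idx) {
  const int nc = cand_start.size(), ns = strain_idx.size();
  const int *cs = INTEGER(cand_start), *cl = INTEGER(cand_len);
  const int *prof = INTEGER(profile), *idx = INTEGER(strain_idx);
  NumericVector frac(nc);
  for (int ci = 0; ci < nc; ++ci) {
    const int *o = prof + cs[ci];
    const int L = cl[ci];
    int hit = 0;
    for (int k = 0; k < ns; ++k) {
      const int si = idx[k] - 1;
      bool found = false;
      for (int strand = 0; strand < 2 && !found; ++strand) {
        SEXP ts = (strand == 0) ? VECTOR_ELT(fwd, si) : VECTOR_ELT(rc, si);
        const int *t = INTEGER(ts);
        const int N = Rf_length(ts);
        for (int s = 0; s + L <= N; ++s) {
          bool perfect = true;
          for (int i = 0; i < L; ++i)
            if ((o[i] & t[s + i]) == 0) { perfect = false; break; }
          if (perfect) { found = true; break; }
        }
      }
      if (found) ++hit;
    }
    frac[ci] = ns ? (double)hit / ns : NA_REAL;
  }
  return frac;
}

// Best gapless offset of `query` against `ref` (no reverse complement):
// offset d means query position i aligns to ref position i + d.  Scores
// matches in the overlap; requires a minimum overlap.
// [[Rcpp::export]]
List best_offset_c(IntegerVector query, IntegerVector ref, int min_overlap) {
  const int Q = query.size(), N = ref.size();
  const int *q = INTEGER(query), *r = INTEGER(ref);
  int bestD = 0, bestScore = -1, bestMm = 0;
  for (int d = -(Q - 1); d <= N - 1; ++d) {
    const int iLo = std::max(0, -d), iHi = std::min(Q, N - d);
    const int ov = iHi - iLo;
    if (ov < min_overlap) continue;
    int match = 0;
    for (int i = iLo; i < iHi; ++i)
      if ((q[i] & r[i + d]) != 0) ++match;
    if (match > bestScore) { bestScore = match; bestD = d; bestMm = ov - match; }
  }
  if (bestScore < 0) stop("no offset satisfies the minimum overlap");
  return List::create(_["offset"] = bestD, _["mismatches"] = bestMm);
}
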