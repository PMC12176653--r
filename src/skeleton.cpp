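#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Row/col offsets of the 8-neighbourhood in Zhang-Suen order P2..P9
// (N, NE, E, SE, S, SW, W, NW) for a matrix with rows growing downward.
static const int DR[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
static const int DC[8] = {0, 1, 1, 1, 0, -1, -1, -1};

// [[Rcpp::export]]
LogicalMatrix cpp_thin(const LogicalMatrix& mask, bool cleanup = true) {
  const int nr = mask.nrow(), nc = mask.ncol();
  std::vector<unsigned char> img(nr * nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      img[i + j * nr] = mask(i, j) ? 1 : 0;

  auto at = [&](int i, int j) -> unsigned char {
    if (i < 0 || j < 0 || i >= nr || j >= nc) return 0;
    return img[i + j * nr];
  };

  std::vector<int> kill;
  kill.reserve(1024);
  bool changed = true;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
          if (!img[i + j * nr]) continue;
          int p[8], b = 0;
          for (int k = 0; k < 8; ++k) {
            p[k] = at(i + DR[k], j + DC[k]);
            b += p[k];
          }
          if (b < 2 || b > 6) continue;
          // corner-tip guard: a pixel whose only two neighbours touch each
          // other is the tip of a diagonal front; deleting such pixels lets
          // Zhang-Suen erode 2-px diagonal strokes end-on indefinitely
          if (b == 2) {
            int k1 = -1, k2 = -1;
            for (int k = 0; k < 8; ++k)
              if (p[k]) { if (k1 < 0) k1 = k; else k2 = k; }
            if (std::abs(DR[k1] - DR[k2]) <= 1 &&
                std::abs(DC[k1] - DC[k2]) <= 1) continue;
          }
          int a = 0;
          for (int k = 0; k < 8; ++k)
            if (p[k] == 0 && p[(k + 1) % 8] == 1) ++a;
          if (a != 1) continue;
          // p[0]=P2(N), p[2]=P4(E), p[4]=P6(S), p[6]=P8(W)
          if (pass == 0) {
            if (p[0] * p[2] * p[4] != 0) continue;
            if (p[2] * p[4] * p[6] != 0) continue;
          } else {
            if (p[0] * p[2] * p[6] != 0) continue;
            if (p[0] * p[4] * p[6] != 0) continue;
          }
          kill.push_back(i + j * nr);
        }
      }
      if (!kill.empty()) {
        changed = true;
        for (int idx : kill) img[idx] = 0;
      }
    }
  }

  // Unit-width cleanup: the parallel passes can leave L-corners and 2-px
  // diagonal ribbons which corrupt junction detection. Sequentially delete
  // non-endpoint simple points (exact (8,4) test: one 8-connected
  // foreground component in N8 computed from true pairwise adjacency, one
  // 4-connected background component touching a 4-neighbour). This is
  // homotopic and yields a minimally 8-connected skeleton.
  auto is_simple = [&](int i, int j) -> bool {
    int fr[8], fc[8], nf = 0;
    bool bg[8];
    for (int k = 0; k < 8; ++k) {
      int ii = i + DR[k], jj = j + DC[k];
      bool v = at(ii, jj) != 0;
      bg[k] = !v;
      if (v) { fr[nf] = DR[k]; fc[nf] = DC[k]; ++nf; }
    }
    if (nf == 0) return false;
    // 8-components of foreground cells (pairwise adjacency)
    int comp[8];
    for (int a = 0; a < nf; ++a) comp[a] = a;
    for (int a = 0; a < nf; ++a)
      for (int b2 = a + 1; b2 < nf; ++b2)
        if (std::abs(fr[a] - fr[b2]) <= 1 && std::abs(fc[a] - fc[b2]) <= 1) {
          int ca = comp[a], cb = comp[b2];
          if (ca != cb)
            for (int t = 0; t < nf; ++t) if (comp[t] == cb) comp[t] = ca;
        }
    int ncomp = 0;
    for (int a = 0; a < nf; ++a) if (comp[a] == a) ++ncomp;
    if (ncomp != 1) return false;
    // 4-components of background among N8 cells, seeded at 4-neighbours
    // (ring positions 0,2,4,6); two bg cells are linked when 4-adjacent.
    int bcomp[8];
    for (int k = 0; k < 8; ++k) bcomp[k] = bg[k] ? k : -1;
    for (int a = 0; a < 8; ++a)
      for (int b2 = a + 1; b2 < 8; ++b2) {
        if (bcomp[a] < 0 || bcomp[b2] < 0) continue;
        if (std::abs(DR[a] - DR[b2]) + std::abs(DC[a] - DC[b2]) == 1) {
          int ca = bcomp[a], cb = bcomp[b2];
          if (ca != cb)
            for (int t = 0; t < 8; ++t) if (bcomp[t] == cb) bcomp[t] = ca;
        }
      }
    int nbg4 = 0;
    bool seen[8] = {false, false, false, false, false, false, false, false};
    for (int k = 0; k < 8; k += 2) {  // 4-neighbours only
      if (bcomp[k] < 0) continue;
      int root = bcomp[k];
      if (!seen[root]) { seen[root] = true; ++nbg4; }
    }
    return nbg4 == 1;
  };
  changed = cleanup;
  while (changed) {
    changed = false;
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        if (!img[i + j * nr]) continue;
        int b = 0, ks[8], cnt = 0;
        for (int k = 0; k < 8; ++k)
          if (at(i + DR[k], j + DC[k])) { if (cnt < 8) ks[cnt] = k; ++cnt; ++b; }
        if (b < 2) continue;  // keep endpoints
        // keep corner tips (two mutually adjacent neighbours): deleting
        // them lets 2-px ribbons erode from their open end
        if (b == 2 &&
            std::abs(DR[ks[0]] - DR[ks[1]]) <= 1 &&
            std::abs(DC[ks[0]] - DC[ks[1]]) <= 1) continue;
        if (is_simple(i, j)) {
          img[i + j * nr] = 0;
          changed = true;
        }
      }
    }
  }

  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = img[i + j * nr] != 0;
  return out;
}

struct DSU {
  std::vector<int> p;
  DSU(int n) : p(n) { for (int i = 0; i < n; ++i) p[i] = i; }
  int find(int x) { while (p[x] != x) { p[x] = p[p[x]]; x = p[x]; } return x; }
  void unite(int a, int b) { a = find(a); b = find(b); if (a != b) p[a] = b; }
};

// Trace a skeleton into a node/edge graph.
//
// Node pixels are skeleton pixels whose 8-neighbour count differs from 2;
// adjacent node pixels are merged into one node cluster (a cluster is a
// junction when any member has >= 3 neighbours, otherwise an endpoint).
// Edges are maximal chains of degree-2 pixels between clusters. Chains with
// no node pixel at all are closed cycles and reported separately.
// dt is the Euclidean distance transform (pixels) used for radius profiles.
// [[Rcpp::export]]
List cpp_skel_graph(const LogicalMatrix& skel, const NumericMatrix& dt,
                    int tip_window = 10) {
  const int nr = skel.nrow(), nc = skel.ncol();
  std::vector<int> px;  // linear indices of skeleton pixels
  std::vector<int> idx_of(nr * nc, -1);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (skel(i, j)) { idx_of[i + j * nr] = (int)px.size(); px.push_back(i + j * nr); }
  const int n = (int)px.size();

  auto nbrs = [&](int lin, int* out) -> int {
    int i = lin % nr, j = lin / nr, cnt = 0;
    for (int k = 0; k < 8; ++k) {
      int ii = i + DR[k], jj = j + DC[k];
      if (ii < 0 || jj < 0 || ii >= nr || jj >= nc) continue;
      int l2 = ii + jj * nr;
      if (idx_of[l2] >= 0) out[cnt++] = l2;
    }
    return cnt;
  };

  std::vector<int> deg(n);
  int nb[8];
  for (int a = 0; a < n; ++a) deg[a] = nbrs(px[a], nb);

  // cluster node pixels
  DSU dsu(n);
  std::vector<bool> isnode(n);
  for (int a = 0; a < n; ++a) isnode[a] = deg[a] != 2;
  for (int a = 0; a < n; ++a) {
    if (!isnode[a]) continue;
    int cnt = nbrs(px[a], nb);
    for (int k = 0; k < cnt; ++k) {
      int b = idx_of[nb[k]];
      if (isnode[b]) dsu.unite(a, b);
    }
  }
  std::vector<int> cluster(n, -1);
  std::vector<int> roots;
  for (int a = 0; a < n; ++a) {
    if (!isnode[a]) continue;
    int r = dsu.find(a);
    int cid = -1;
    for (size_t t = 0; t < roots.size(); ++t) if (roots[t] == r) { cid = (int)t; break; }
    if (cid < 0) { cid = (int)roots.size(); roots.push_back(r); }
    cluster[a] = cid;
  }
  const int ncl = (int)roots.size();
  std::vector<double> cy(ncl, 0), cx(ncl, 0), crad(ncl, 0);
  std::vector<int> csz(ncl, 0), cjun(ncl, 0);
  for (int a = 0; a < n; ++a) {
    if (cluster[a] < 0) continue;
    int c = cluster[a], i = px[a] % nr, j = px[a] / nr;
    cy[c] += i + 1; cx[c] += j + 1; csz[c]++;
    double d = dt(i, j);
    if (d > crad[c]) crad[c] = d;
    if (deg[a] >= 3) cjun[c] = 1;
  }

  auto stepd = [&](int l1, int l2) {
    int di = std::abs(l1 % nr - l2 % nr), dj = std::abs(l1 / nr - l2 / nr);
    return (di + dj == 2) ? std::sqrt(2.0) : 1.0;
  };

  std::vector<bool> visited(n, false);
  std::vector<int> efrom, eto, enpx;
  std::vector<double> elen, emean, emax, etipf, etipt;

  auto push_edge = [&](int cfrom, int cto, double len,
                       const std::vector<double>& prof) {
    efrom.push_back(cfrom + 1);
    eto.push_back(cto + 1);
    elen.push_back(len);
    enpx.push_back((int)prof.size());
    double s = 0, mx = 0;
    for (double v : prof) { s += v; if (v > mx) mx = v; }
    emean.push_back(prof.empty() ? 0.0 : s / prof.size());
    emax.push_back(mx);
    int w = std::min<int>(tip_window, (int)prof.size());
    double tf = 0, tt = 0;
    for (int t = 0; t < w; ++t) {
      if (prof[t] > tf) tf = prof[t];
      if (prof[prof.size() - 1 - t] > tt) tt = prof[prof.size() - 1 - t];
    }
    etipf.push_back(tf);
    etipt.push_back(tt);
  };

  // chains emanating from node clusters
  for (int a = 0; a < n; ++a) {
    if (cluster[a] < 0) continue;
    int cnt = nbrs(px[a], nb);
    for (int k = 0; k < cnt; ++k) {
      int b = idx_of[nb[k]];
      if (isnode[b] || visited[b]) continue;
      std::vector<double> prof;
      double len = stepd(px[a], nb[k]);
      int prev = a, cur = b;
      prof.push_back(dt(px[b] % nr, px[b] / nr));
      visited[b] = true;
      int guard = 0;
      while (true) {
        if (++guard > n + 5) stop("skeleton trace failed to terminate");
        int cnt2 = nbrs(px[cur], nb);
        int nxt = -1;
        for (int t = 0; t < cnt2; ++t) {
          int cand = idx_of[nb[t]];
          if (cand != prev) { nxt = cand; break; }
        }
        if (nxt < 0) break;  // dangling (shouldn't happen: deg==2)
        len += stepd(px[cur], px[nxt]);
        if (isnode[nxt]) {
          push_edge(cluster[a], cluster[nxt], len, prof);
          break;
        }
        if (visited[nxt]) break;  // loop back onto traced chain
        visited[nxt] = true;
        prof.push_back(dt(px[nxt] % nr, px[nxt] / nr));
        prev = cur; cur = nxt;
      }
    }
  }

  // direct cluster-cluster adjacencies (no degree-2 pixel between)
  std::vector<std::pair<int,int> > seen;
  for (int a = 0; a < n; ++a) {
    if (cluster[a] < 0) continue;
    int cnt = nbrs(px[a], nb);
    for (int k = 0; k < cnt; ++k) {
      int b = idx_of[nb[k]];
      if (cluster[b] < 0 || cluster[b] == cluster[a]) continue;
      int c1 = std::min(cluster[a], cluster[b]), c2 = std::max(cluster[a], cluster[b]);
      bool dup = false;
      for (auto& pr : seen) if (pr.first == c1 && pr.second == c2) { dup = true; break; }
      if (dup) continue;
      seen.push_back(std::make_pair(c1, c2));
      std::vector<double> prof;
      push_edge(cluster[a], cluster[b], stepd(px[a], nb[k]), prof);
    }
  }

  // leftover unvisited degree-2 pixels: either pure cycles, or orphan
  // chains missed by the cluster-based tracing; orphan chains whose ends
  // touch node clusters are reconstructed as proper edges.
  std::vector<double> cyclen;
  for (int a = 0; a < n; ++a) {
    if (isnode[a] || visited[a]) continue;
    // gather the orphan component of unvisited degree-2 pixels
    std::vector<int> comp;
    std::vector<int> stack(1, a);
    visited[a] = true;
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      comp.push_back(cur);
      int cnt2 = nbrs(px[cur], nb);
      for (int t = 0; t < cnt2; ++t) {
        int cand = idx_of[nb[t]];
        if (!isnode[cand] && !visited[cand]) {
          visited[cand] = true;
          stack.push_back(cand);
        }
      }
    }
    // ends = component pixels with <= 1 neighbour inside the component
    std::vector<int> ends;
    for (int c : comp) {
      int cnt2 = nbrs(px[c], nb), inn = 0;
      for (int t = 0; t < cnt2; ++t) {
        int cand = idx_of[nb[t]];
        if (!isnode[cand] &&
            std::find(comp.begin(), comp.end(), cand) != comp.end() &&
            cand != c) ++inn;
      }
      if (inn <= 1) ends.push_back(c);
    }
    double len = 0;
    std::vector<double> prof;
    for (int c : comp) prof.push_back(dt(px[c] % nr, px[c] / nr));
    // approximate arc length: unit steps + sqrt2 correction is overkill
    // here; use component size as length proxy plus end connections
    len = (double)comp.size();
    if (ends.size() >= 2) {
      // connect the two ends to their adjacent node clusters
      int cfrom = -1, cto = -1;
      for (size_t ei = 0; ei < 2; ++ei) {
        int cnt2 = nbrs(px[ends[ei]], nb);
        for (int t = 0; t < cnt2; ++t) {
          int cand = idx_of[nb[t]];
          if (isnode[cand] && cluster[cand] >= 0) {
            if (ei == 0) cfrom = cluster[cand]; else cto = cluster[cand];
            break;
          }
        }
      }
      if (cfrom >= 0 && cto >= 0) {
        push_edge(cfrom, cto, len + 2.0, prof);
        continue;
      }
    }
    cyclen.push_back(len * 1.2);  // cycle: diagonal-corrected estimate
  }

  IntegerVector nid(ncl), nsize(ncl);
  NumericVector nrow_(ncl), ncol_(ncl), nrad(ncl);
  LogicalVector njun(ncl);
  for (int c = 0; c < ncl; ++c) {
    nid[c] = c + 1;
    nrow_[c] = cy[c] / csz[c];
    ncol_[c] = cx[c] / csz[c];
    nrad[c] = crad[c];
    nsize[c] = csz[c];
    njun[c] = cjun[c] != 0;
  }

  return List::create(
    _["nodes"] = DataFrame::create(_["id"] = nid, _["row"] = nrow_,
                                   _["col"] = ncol_, _["r_px"] = nrad,
                                   _["npx"] = nsize, _["junction"] = njun),
    _["edges"] = DataFrame::create(_["from"] = efrom, _["to"] = eto,
                                   _["length_px"] = elen, _["mean_r_px"] = emean,
                                   _["max_r_px"] = emax, _["tip_r_from"] = etipf,
                                   _["tip_r_to"] = etipt, _["npx"] = enpx),
    _["cycle_lengths_px"] = NumericVector(cyclen.begin(), cyclen.end()),
    _["n_skel_px"] = n);
}

// One convolution block: 'same' zero-padded conv + bias + ReLU + max-pool.
// x: H x W x Cin array, w: kh x kw x Cin x F array, pool: pool size.
// [[Rcpp::export]]
NumericVector cpp_conv_block(const NumericVector& x, const NumericVector& w,
                             const NumericVector& bias, int pool) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  const int kh = wd[0], kw = wd[1], F = wd[3];
  if (wd[2] != C) stop("channel mismatch");
  const int ph = kh / 2, pw = kw / 2;
  std::vector<double> conv((size_t)H * W * F, 0.0);
  for (int f = 0; f < F; ++f) {
    for (int c = 0; c < C; ++c) {
      const double* xc = &x[(size_t)c * H * W];
      const double* wf = &w[((size_t)f * C + c) * kh * kw];
      for (int j = 0; j < W; ++j) {
        for (int i = 0; i < H; ++i) {
          double acc = 0;
          for (int b = 0; b < kw; ++b) {
            int jj = j + b - pw;
            if (jj < 0 || jj >= W) continue;
            for (int a = 0; a < kh; ++a) {
              int ii = i + a - ph;
              if (ii < 0 || ii >= H) continue;
              acc += xc[ii + jj * H] * wf[a + b * kh];
            }
          }
          conv[(size_t)f * H * W + i + j * H] += acc;
        }
      }
    }
    double bf = bias[f];
    for (size_t t = (size_t)f * H * W; t < (size_t)(f + 1) * H * W; ++t) {
      conv[t] += bf;
      if (conv[t] < 0) conv[t] = 0;  // ReLU
    }
  }
  const int Ho = H / pool, Wo = W / pool;
  NumericVector out((size_t)Ho * Wo * F);
  out.attr("dim") = IntegerVector::create(Ho, Wo, F);
  for (int f = 0; f < F; ++f)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        double mx = -1e300;
        for (int b = 0; b < pool; ++b)
          for (int a = 0; a < pool; ++a) {
            double v = conv[(size_t)f * H * W + (i * pool + a) + (j * pool + b) * H];
            if (v > mx) mx = v;
          }
        out[(size_t)f * Ho * Wo + i + j * Ho] = mx;
      }
  return out;
}
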