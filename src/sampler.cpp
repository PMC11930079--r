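#include <Rcpp.h>
using namespace Rcpp;

// Distance helpers on flat coordinate buffers (x, y, z triplets).
static inline double dist2(const double* a, const double* b) {
  double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
  return dx * dx + dy * dy + dz * dz;
}

// Random unit vector via normalized Gaussian triple (uses R's RNG so that
// set.seed() in R controls the stream).
static inline void rand_unit(double* u) {
  double n2 = 0.0;
  do {
    u[0] = norm_rand(); u[1] = norm_rand(); u[2] = norm_rand();
    n2 = u[0] * u[0] + u[1] * u[1] + u[2] * u[2];
  } while (n2 < 1e-12);
  double inv = 1.0 / std::sqrt(n2);
  u[0] *= inv; u[1] *= inv; u[2] *= inv;
}

// Uniform random rotation matrix from a random quaternion.
static void rand_rotation(double R[3][3]) {
  double q[4]; double n2 = 0.0;
  do {
    for (int i = 0; i < 4; ++i) q[i] = norm_rand();
    n2 = q[0]*q[0] + q[1]*q[1] + q[2]*q[2] + q[3]*q[3];
  } while (n2 < 1e-12);
  double inv = 1.0 / std::sqrt(n2);
  double w = q[0]*inv, x = q[1]*inv, y = q[2]*inv, z = q[3]*inv;
  R[0][0] = 1 - 2*(y*y + z*z); R[0][1] = 2*(x*y - w*z); R[0][2] = 2*(x*z + w*y);
  R[1][0] = 2*(x*y + w*z); R[1][1] = 1 - 2*(x*x + z*z); R[1][2] = 2*(y*z - w*x);
  R[2][0] = 2*(x*z - w*y); R[2][1] = 2*(y*z + w*x); R[2][2] = 1 - 2*(x*x + y*y);
}

// [[Rcpp::export]]
NumericVector cpp_pair_stats(NumericMatrix coords, double cutoff) {
  // Returns c(rg, dmax, n_clash) where n_clash counts non-bonded pairs
  // (|i - j| > 1 along the chain) closer than cutoff.
  int n = coords.nrow();
  std::vector<double> buf(3 * n);
  double cx = 0, cy = 0, cz = 0;
  for (int i = 0; i < n; ++i) {
    buf[3*i] = coords(i, 0); buf[3*i+1] = coords(i, 1); buf[3*i+2] = coords(i, 2);
    cx += buf[3*i]; cy += buf[3*i+1]; cz += buf[3*i+2];
  }
  cx /= n; cy /= n; cz /= n;
  double sum2 = 0;
  for (int i = 0; i < n; ++i) {
    double dx = buf[3*i] - cx, dy = buf[3*i+1] - cy, dz = buf[3*i+2] - cz;
    sum2 += dx*dx + dy*dy + dz*dz;
  }
  double rg = std::sqrt(sum2 / n);
  double dmax2 = 0, cut2 = cutoff * cutoff;
  int nclash = 0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d2 = dist2(&buf[3*i], &buf[3*j]);
      if (d2 > dmax2) dmax2 = d2;
      if (j > i + 1 && d2 < cut2) ++nclash;
    }
  }
  return NumericVector::create(rg, std::sqrt(dmax2), (double)nclash);
}

// [[Rcpp::export]]
NumericVector cpp_debye(NumericMatrix coords, NumericVector q,
                        NumericVector f) {
  // I(q) = sum_i sum_j f_i f_j sinc(q r_ij), sinc(0) = 1.
  int n = coords.nrow(), nq = q.size();
  std::vector<double> buf(3 * n);
  for (int i = 0; i < n; ++i) {
    buf[3*i] = coords(i, 0); buf[3*i+1] = coords(i, 1); buf[3*i+2] = coords(i, 2);
  }
  // Pairwise distances once (i < j).
  std::vector<double> d; d.reserve((size_t)n * (n - 1) / 2);
  std::vector<double> fw; fw.reserve(d.capacity());
  double self = 0.0;
  for (int i = 0; i < n; ++i) {
    self += f[i] * f[i];
    for (int j = i + 1; j < n; ++j) {
      d.push_back(std::sqrt(dist2(&buf[3*i], &buf[3*j])));
      fw.push_back(f[i] * f[j]);
    }
  }
  NumericVector I(nq);
  for (int k = 0; k < nq; ++k) {
    double qq = q[k], s = self;
    if (qq <= 0) {
      for (size_t m = 0; m < d.size(); ++m) s += 2.0 * fw[m];
    } else {
      for (size_t m = 0; m < d.size(); ++m) {
        double x = qq * d[m];
        s += 2.0 * fw[m] * (x < 1e-9 ? 1.0 : std::sin(x) / x);
      }
    }
    I[k] = s;
  }
  return I;
}

// [[Rcpp::export]]
List cpp_sample_conformers(NumericMatrix dom1, NumericMatrix dom2_local,
                           int n_linker, double bond, int mode,
                           double cutoff, int max_retries, int n_models,
                           double stiffness, double hinge_prob) {
  // Grows n_models conformers: dom1 fixed, linker regrown bead by bead from
  // dom1's last bead, dom2 rigid body re-attached with a random orientation.
  // mode 0 = FJC (no clash checks), mode 1 = excluded volume (per-bead
  // redraw on clash, whole-model restart when a bead or the domain
  // placement exhausts max_retries draws).
  int n1 = dom1.nrow(), n2 = dom2_local.nrow();
  int ntot = n1 + n_linker + n2;
  double cut2 = cutoff * cutoff;
  List out(n_models);
  NumericVector rg(n_models), dmax(n_models), clash(n_models);
  IntegerVector restarts(n_models);
  RNGScope scope;

  std::vector<double> buf(3 * ntot);
  for (int i = 0; i < n1; ++i) {
    buf[3*i] = dom1(i, 0); buf[3*i+1] = dom1(i, 1); buf[3*i+2] = dom1(i, 2);
  }

  for (int m = 0; m < n_models; ++m) {
    int model_restarts = 0;
    bool done = false;
    while (!done) {
      if (model_restarts > max_retries)
        stop("retry budget exhausted after %d model restarts (acceptance rate too low)",
             model_restarts);
      bool failed = false;
      // Grow linker. stiffness > 0 gives a correlated (wormlike) proposal:
      // each bond direction = normalize(stiffness * previous + gaussian);
      // stiffness = 0 recovers independent FJC bonds exactly.
      double prev_dir[3] = { 0, 0, 0 };
      bool have_dir = false;
      for (int k = 0; k < n_linker && !failed; ++k) {
        int idx = n1 + k;                    // bead being placed
        const double* prev = &buf[3 * (idx - 1)];
        int tries = 0;
        while (true) {
          double u[3]; rand_unit(u);
          // with probability hinge_prob this bond is a flexible hinge:
          // drawn isotropically, breaking the directional correlation
          bool hinge = hinge_prob > 0 && unif_rand() < hinge_prob;
          if (stiffness > 0 && have_dir && !hinge) {
            u[0] += stiffness * prev_dir[0];
            u[1] += stiffness * prev_dir[1];
            u[2] += stiffness * prev_dir[2];
            double n2u = u[0]*u[0] + u[1]*u[1] + u[2]*u[2];
            double inv = 1.0 / std::sqrt(n2u);
            u[0] *= inv; u[1] *= inv; u[2] *= inv;
          }
          double c[3] = { prev[0] + bond * u[0], prev[1] + bond * u[1],
                          prev[2] + bond * u[2] };
          bool ok = true;
          if (mode == 1) {
            // check against all placed beads except the bonded neighbour
            for (int j = 0; j < idx - 1; ++j) {
              if (dist2(c, &buf[3*j]) < cut2) { ok = false; break; }
            }
          }
          if (ok) {
            buf[3*idx] = c[0]; buf[3*idx+1] = c[1]; buf[3*idx+2] = c[2];
            prev_dir[0] = u[0]; prev_dir[1] = u[1]; prev_dir[2] = u[2];
            have_dir = true;
            break;
          }
          if (++tries >= max_retries) { failed = true; break; }
        }
      }
      // Attach dom2 as a rigid body.
      if (!failed) {
        int base = n1 + n_linker;
        const double* last = &buf[3 * (base - 1)];
        int tries = 0;
        while (true) {
          double u[3]; rand_unit(u);
          double R[3][3]; rand_rotation(R);
          double ax = last[0] + bond * u[0], ay = last[1] + bond * u[1],
                 az = last[2] + bond * u[2];
          bool ok = true;
          for (int i = 0; i < n2 && ok; ++i) {
            double lx = dom2_local(i, 0), ly = dom2_local(i, 1), lz = dom2_local(i, 2);
            double px = ax + R[0][0]*lx + R[0][1]*ly + R[0][2]*lz;
            double py = ay + R[1][0]*lx + R[1][1]*ly + R[1][2]*lz;
            double pz = az + R[2][0]*lx + R[2][1]*ly + R[2][2]*lz;
            buf[3*(base+i)] = px; buf[3*(base+i)+1] = py; buf[3*(base+i)+2] = pz;
            if (mode == 1) {
              double p[3] = { px, py, pz };
              // skip the bonded pair: dom2 bead 0 vs last linker bead
              int skip = (i == 0) ? base - 1 : -1;
              for (int j = 0; j < base; ++j) {
                if (j == skip) continue;
                if (dist2(p, &buf[3*j]) < cut2) { ok = false; break; }
              }
            }
          }
          if (ok) break;
          if (++tries >= max_retries) { failed = true; break; }
        }
      }
      if (failed) { ++model_restarts; continue; }
      done = true;
    }
    NumericMatrix coords(ntot, 3);
    for (int i = 0; i < ntot; ++i) {
      coords(i, 0) = buf[3*i]; coords(i, 1) = buf[3*i+1]; coords(i, 2) = buf[3*i+2];
    }
    NumericVector st = cpp_pair_stats(coords, cutoff);
    rg[m] = st[0]; dmax[m] = st[1]; clash[m] = st[2];
    restarts[m] = model_restarts;
    out[m] = coords;
  }
  return List::create(_["coords"] = out, _["rg"] = rg, _["dmax"] = dmax,
                      _["clash"] = clash, _["restarts"] = restarts);
}

// [[Rcpp::export]]
NumericMatrix cpp_grow_compact(int n, double bond, double min_sep,
                               int n_cand, int max_retries) {
  // Deterministic-under-seed compact self-avoiding chain: each bead chooses,
  // among n_cand non-clashing random directions, the one closest to the
  // running centroid. Used to build surrogate rigid domains.
  NumericMatrix coords(n, 3);
  RNGScope scope;
  coords(0, 0) = 0; coords(0, 1) = 0; coords(0, 2) = 0;
  std::vector<double> buf(3 * n, 0.0);
  double cx = 0, cy = 0, cz = 0;
  double ms2 = min_sep * min_sep;
  int backtracks = 0;
  for (int k = 1; k < n; ++k) {
    const double* prev = &buf[3 * (k - 1)];
    double best[3]; double bestscore = R_PosInf; bool found = false;
    int rounds = 0;
    while (!found && rounds < max_retries) {
      for (int c = 0; c < n_cand; ++c) {
        double u[3]; rand_unit(u);
        double p[3] = { prev[0] + bond * u[0], prev[1] + bond * u[1],
                        prev[2] + bond * u[2] };
        bool ok = true;
        for (int j = 0; j < k - 1; ++j) {
          if (dist2(p, &buf[3*j]) < ms2) { ok = false; break; }
        }
        if (!ok) continue;
        double dx = p[0] - cx / k, dy = p[1] - cy / k, dz = p[2] - cz / k;
        double score = dx*dx + dy*dy + dz*dz;
        if (score < bestscore) {
          bestscore = score; best[0] = p[0]; best[1] = p[1]; best[2] = p[2];
          found = true;
        }
      }
      ++rounds;
    }
    if (!found) {
      // dead end (growing tip buried): back off a few beads and regrow
      if (++backtracks > 50 * n) stop("compact growth stalled at bead %d", k + 1);
      int back = k > 6 ? 5 : k - 1;
      for (int j = k - back; j < k; ++j) {
        cx -= buf[3*j]; cy -= buf[3*j+1]; cz -= buf[3*j+2];
      }
      k -= back + 1;  // loop increment brings us to the first removed bead
      continue;
    }
    buf[3*k] = best[0]; buf[3*k+1] = best[1]; buf[3*k+2] = best[2];
    cx += best[0]; cy += best[1]; cz += best[2];
  }
  for (int i = 0; i < n; ++i) {
    coords(i, 0) = buf[3*i]; coords(i, 1) = buf[3*i+1]; coords(i, 2) = buf[3*i+2];
  }
  return coords;
}
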