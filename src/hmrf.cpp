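// Low-level kernels for the hidden Markov random field stage: sequential
// ICM sweeps, neighborhood label counts and disagreement-pair counts on a
// 3D grid with a 6- or 26-neighborhood, plus 3D connected-component
// labeling used by the optional MIP post-processing filter.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

// Full neighbor offsets; first 3 (resp. 13) entries are the positive
// half-space used for unordered pair enumeration.
void neighbor_offsets(int order, std::vector<std::array<int, 3>>& off) {
  off.clear();
  if (order == 6) {
    off = {{{1, 0, 0}}, {{0, 1, 0}}, {{0, 0, 1}},
           {{-1, 0, 0}}, {{0, -1, 0}}, {{0, 0, -1}}};
  } else if (order == 26) {
    // positive half first
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (dx == 0 && dy == 0 && dz == 0) continue;
          if (dz > 0 || (dz == 0 && (dy > 0 || (dy == 0 && dx > 0))))
            off.push_back({{dx, dy, dz}});
        }
    size_t half = off.size();
    for (size_t k = 0; k < half; ++k)
      off.push_back({{-off[k][0], -off[k][1], -off[k][2]}});
  } else {
    stop("neighborhood order must be 6 or 26");
  }
}

inline int idx3(int x, int y, int z, int d1, int d2) {
  return x + d1 * (y + d2 * z);
}

}  // namespace

// Posterior energy of a labeling: likelihood energy over labeled voxels
// plus beta times the number of unordered disagreeing neighbor pairs.
// labels are 0-based class indices; -1 marks voxels outside the mask.
// [[Rcpp::export]]
double posterior_energy_cpp(NumericVector y, IntegerVector labels,
                            IntegerVector dim, NumericVector mu,
                            NumericVector sigma, double beta, int order) {
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  std::vector<std::array<int, 3>> off;
  neighbor_offsets(order, off);
  int half = order == 6 ? 3 : 13;
  double e_lik = 0.0, pairs = 0.0;
  for (int z = 0; z < d3; ++z)
    for (int yy = 0; yy < d2; ++yy)
      for (int x = 0; x < d1; ++x) {
        int i = idx3(x, yy, z, d1, d2);
        int l = labels[i];
        if (l < 0) continue;
        double dmu = y[i] - mu[l];
        e_lik += dmu * dmu / (2.0 * sigma[l] * sigma[l]) + std::log(sigma[l]);
        for (int k = 0; k < half; ++k) {
          int nx = x + off[k][0], ny = yy + off[k][1], nz = z + off[k][2];
          if (nx < 0 || ny < 0 || nz < 0 || nx >= d1 || ny >= d2 || nz >= d3)
            continue;
          int lj = labels[idx3(nx, ny, nz, d1, d2)];
          if (lj >= 0 && lj != l) pairs += 1.0;
        }
      }
  return e_lik + beta * pairs;
}

// [[Rcpp::export]]
double count_disagree_pairs_cpp(IntegerVector labels, IntegerVector dim,
                                int order) {
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  std::vector<std::array<int, 3>> off;
  neighbor_offsets(order, off);
  int half = order == 6 ? 3 : 13;
  double pairs = 0.0;
  for (int z = 0; z < d3; ++z)
    for (int yy = 0; yy < d2; ++yy)
      for (int x = 0; x < d1; ++x) {
        int l = labels[idx3(x, yy, z, d1, d2)];
        if (l < 0) continue;
        for (int k = 0; k < half; ++k) {
          int nx = x + off[k][0], ny = yy + off[k][1], nz = z + off[k][2];
          if (nx < 0 || ny < 0 || nz < 0 || nx >= d1 || ny >= d2 || nz >= d3)
            continue;
          int lj = labels[idx3(nx, ny, nz, d1, d2)];
          if (lj >= 0 && lj != l) pairs += 1.0;
        }
      }
  return pairs;
}

// counts[i, l] = number of in-mask neighbors of voxel i carrying label l
// [[Rcpp::export]]
NumericMatrix neighbor_label_counts_cpp(IntegerVector labels,
                                        IntegerVector dim, int n_classes,
                                        int order) {
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  int n = d1 * d2 * d3;
  std::vector<std::array<int, 3>> off;
  neighbor_offsets(order, off);
  NumericMatrix counts(n, n_classes);
  for (int z = 0; z < d3; ++z)
    for (int yy = 0; yy < d2; ++yy)
      for (int x = 0; x < d1; ++x) {
        int i = idx3(x, yy, z, d1, d2);
        for (size_t k = 0; k < off.size(); ++k) {
          int nx = x + off[k][0], ny = yy + off[k][1], nz = z + off[k][2];
          if (nx < 0 || ny < 0 || nz < 0 || nx >= d1 || ny >= d2 || nz >= d3)
            continue;
          int lj = labels[idx3(nx, ny, nz, d1, d2)];
          if (lj >= 0) counts(i, lj) += 1.0;
        }
      }
  return counts;
}

// Sequential raster-order ICM sweeps. Each voxel is assigned the class
// minimizing its local conditional energy
//   (y - mu_l)^2 / (2 sigma_l^2) + log(sigma_l) + beta * #{neighbors != l};
// ties break toward the lowest class index. Sweeps stop when a full sweep
// changes no voxel or max_iters is reached. The posterior energy after the
// initial labeling and after every sweep is returned.
// [[Rcpp::export]]
List icm_sweeps_cpp(NumericVector y, IntegerVector labels_in,
                    IntegerVector dim, NumericVector mu, NumericVector sigma,
                    double beta, int order, int max_iters) {
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  int L = mu.size();
  IntegerVector labels = clone(labels_in);
  std::vector<std::array<int, 3>> off;
  neighbor_offsets(order, off);

  std::vector<double> energy;
  energy.push_back(
      posterior_energy_cpp(y, labels, dim, mu, sigma, beta, order));

  std::vector<double> lik(L);
  int sweeps = 0;
  for (int it = 0; it < max_iters; ++it) {
    int changed = 0;
    for (int z = 0; z < d3; ++z)
      for (int yy = 0; yy < d2; ++yy)
        for (int x = 0; x < d1; ++x) {
          int i = idx3(x, yy, z, d1, d2);
          if (labels[i] < 0) continue;
          for (int l = 0; l < L; ++l) {
            double dmu = y[i] - mu[l];
            lik[l] = dmu * dmu / (2.0 * sigma[l] * sigma[l]) +
                     std::log(sigma[l]);
          }
          // neighbor label tally
          std::vector<int> cnt(L, 0);
          int n_in = 0;
          for (size_t k = 0; k < off.size(); ++k) {
            int nx = x + off[k][0], ny = yy + off[k][1], nz = z + off[k][2];
            if (nx < 0 || ny < 0 || nz < 0 || nx >= d1 || ny >= d2 ||
                nz >= d3)
              continue;
            int lj = labels[idx3(nx, ny, nz, d1, d2)];
            if (lj >= 0) {
              cnt[lj] += 1;
              n_in += 1;
            }
          }
          int best = 0;
          double best_e = R_PosInf;
          for (int l = 0; l < L; ++l) {
            double e = lik[l] + beta * (n_in - cnt[l]);
            if (e < best_e) {  // strict: lowest index wins ties
              best_e = e;
              best = l;
            }
          }
          if (best != labels[i]) {
            labels[i] = best;
            ++changed;
          }
        }
    ++sweeps;
    energy.push_back(
        posterior_energy_cpp(y, labels, dim, mu, sigma, beta, order));
    if (changed == 0) break;
  }
  return List::create(_["labels"] = labels, _["energy"] = wrap(energy),
                      _["sweeps"] = sweeps);
}

// Connected components of a binary mask (BFS), 6- or 26-connectivity.
// Returns 0 for background, components numbered from 1.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim,
                                   int order) {
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  int n = d1 * d2 * d3;
  std::vector<std::array<int, 3>> off;
  neighbor_offsets(order, off);
  IntegerVector comp(n, 0);
  std::vector<int> queue;
  int cur = 0;
  for (int i = 0; i < n; ++i) {
    if (!mask[i] || comp[i] != 0) continue;
    ++cur;
    comp[i] = cur;
    queue.clear();
    queue.push_back(i);
    while (!queue.empty()) {
      int j = queue.back();
      queue.pop_back();
      int x = j % d1, yy = (j / d1) % d2, z = j / (d1 * d2);
      for (size_t k = 0; k < off.size(); ++k) {
        int nx = x + off[k][0], ny = yy + off[k][1], nz = z + off[k][2];
        if (nx < 0 || ny < 0 || nz < 0 || nx >= d1 || ny >= d2 || nz >= d3)
          continue;
        int jj = idx3(nx, ny, nz, d1, d2);
        if (mask[jj] && comp[jj] == 0) {
          comp[jj] = cur;
          queue.push_back(jj);
        }
      }
    }
  }
  return comp;
}
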