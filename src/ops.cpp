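// Low-level numerical kernels: stride-1 "same" convolution via im2col,
// 2x2 max pooling, block transposed convolution (stride s, kernel s),
// connected-component labelling, Zhang-Suen thinning, and directed
// Hausdorff distance.  Tensors are arma::cube with dims (H, W, C).
#include <RcppArmadillo.h>
#include <functional>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// column r-index for kernel offset (a, b) and input channel ci:
// r = (ci * k + a) * k + b   (a = row offset, b = col offset, 0-based)
static arma::mat im2col(const arma::cube& x, int k, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat col(k * k * C, H * W, arma::fill::zeros);
  for (int ci = 0; ci < C; ++ci) {
    const arma::mat& xs = x.slice(ci);
    for (int a = 0; a < k; ++a) {
      for (int b = 0; b < k; ++b) {
        const int r = (ci * k + a) * k + b;
        for (int j = 0; j < W; ++j) {
          const int xj = j + b - pad;
          if (xj < 0 || xj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int xi = i + a - pad;
            if (xi < 0 || xi >= H) continue;
            col(r, i + j * H) = xs(xi, xj);
          }
        }
      }
    }
  }
  return col;
}

static arma::cube col2im(const arma::mat& col, int H, int W, int C, int k,
                         int pad) {
  arma::cube x(H, W, C, arma::fill::zeros);
  for (int ci = 0; ci < C; ++ci) {
    arma::mat& xs = x.slice(ci);
    for (int a = 0; a < k; ++a) {
      for (int b = 0; b < k; ++b) {
        const int r = (ci * k + a) * k + b;
        for (int j = 0; j < W; ++j) {
          const int xj = j + b - pad;
          if (xj < 0 || xj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int xi = i + a - pad;
            if (xi < 0 || xi >= H) continue;
            xs(xi, xj) += col(r, i + j * H);
          }
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export]]
arma::cube cpp_conv2d_forward(const arma::cube& x, const arma::mat& Wm,
                              const arma::vec& b, int k, int pad) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = Wm.n_rows;
  arma::mat col = im2col(x, k, pad);
  arma::mat y = Wm * col;        // Cout x (H*W)
  y.each_col() += b;
  arma::cube out(H, W, Cout);
  for (int co = 0; co < Cout; ++co)
    out.slice(co) = arma::reshape(y.row(co), H, W);
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(const arma::cube& x, const arma::mat& Wm,
                         const arma::cube& gy, int k, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Cout = gy.n_slices;
  arma::mat gym(Cout, H * W);
  for (int co = 0; co < Cout; ++co)
    gym.row(co) = arma::vectorise(gy.slice(co)).t();
  arma::mat col = im2col(x, k, pad);
  arma::mat gW = gym * col.t();
  arma::vec gb = arma::sum(gym, 1);
  arma::cube gx = col2im(Wm.t() * gym, H, W, C, k, pad);
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// [[Rcpp::export]]
List cpp_maxpool2_forward(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::cube y(Ho, Wo, C);
  arma::ucube idx(Ho, Wo, C);  // linear index into the input slice
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = -arma::datum::inf;
        arma::uword bi = 0;
        for (int b = 0; b < 2; ++b) {
          for (int a = 0; a < 2; ++a) {
            const int ii = 2 * i + a, jj = 2 * j + b;
            const double v = x(ii, jj, c);
            if (v > best) { best = v; bi = ii + jj * H; }
          }
        }
        y(i, j, c) = best;
        idx(i, j, c) = bi;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_backward(const arma::ucube& idx, const arma::cube& gy,
                                 int H, int W) {
  const int C = gy.n_slices;
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* gs = gx.slice_memptr(c);
    for (arma::uword m = 0; m < gy.slice(c).n_elem; ++m)
      gs[idx.slice(c)(m)] += gy.slice(c)(m);
  }
  return gx;
}

// Transposed convolution with kernel size == stride s (non-overlapping
// blocks):  y[s*i+a, s*j+b, co] = sum_ci x[i,j,ci] * W[ci, (co*s+a)*s+b] + bias
// [[Rcpp::export]]
arma::cube cpp_tconv_forward(const arma::cube& x, const arma::mat& Wm,
                             const arma::vec& b, int s) {
  const int h = x.n_rows, w = x.n_cols, C = x.n_slices;
  const int Cout = Wm.n_cols / (s * s);
  arma::cube y(h * s, w * s, Cout);
  for (int co = 0; co < Cout; ++co) y.slice(co).fill(b(co));
  arma::vec xv(C);
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      for (int c = 0; c < C; ++c) xv(c) = x(i, j, c);
      arma::rowvec blk = xv.t() * Wm;  // 1 x (s*s*Cout)
      for (int co = 0; co < Cout; ++co)
        for (int a = 0; a < s; ++a)
          for (int bb = 0; bb < s; ++bb)
            y(s * i + a, s * j + bb, co) += blk((co * s + a) * s + bb);
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_tconv_backward(const arma::cube& x, const arma::mat& Wm,
                        const arma::cube& gy, int s) {
  const int h = x.n_rows, w = x.n_cols, C = x.n_slices;
  const int Cout = gy.n_slices;
  arma::cube gx(h, w, C, arma::fill::zeros);
  arma::mat gW(C, s * s * Cout, arma::fill::zeros);
  arma::vec gb(Cout, arma::fill::zeros);
  for (int co = 0; co < Cout; ++co) gb(co) = arma::accu(gy.slice(co));
  arma::vec xv(C), gblk(s * s * Cout);
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      for (int co = 0; co < Cout; ++co)
        for (int a = 0; a < s; ++a)
          for (int bb = 0; bb < s; ++bb)
            gblk((co * s + a) * s + bb) = gy(s * i + a, s * j + bb, co);
      for (int c = 0; c < C; ++c) xv(c) = x(i, j, c);
      gx.tube(i, j) = Wm * gblk;
      gW += xv * gblk.t();
    }
  }
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// Connected-component labelling by BFS; connectivity 4 or 8.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask,
                                   int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  const int dx8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dy8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nd = (connectivity == 8) ? 8 : 4;
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.push_back(i + j * H);
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int pi = p % H, pj = p / H;
        for (int d = 0; d < nd; ++d) {
          const int qi = pi + dx8[d], qj = pj + dy8[d];
          if (qi < 0 || qi >= H || qj < 0 || qj >= W) continue;
          if (mask(qi, qj) && lab(qi, qj) == 0) {
            lab(qi, qj) = next;
            stack.push_back(qi + qj * H);
          }
        }
      }
    }
  }
  return lab;
}

// Zhang-Suen thinning to a one-pixel-wide skeleton.
// [[Rcpp::export]]
LogicalMatrix cpp_thin_zhangsuen(const LogicalMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  std::vector<unsigned char> img(H * W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) img[i + j * H] = mask(i, j) ? 1 : 0;
  auto at = [&](int i, int j) -> int {
    if (i < 0 || i >= H || j < 0 || j >= W) return 0;
    return img[i + j * H];
  };
  bool changed = true;
  std::vector<int> kill;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int j = 0; j < W; ++j) {
        for (int i = 0; i < H; ++i) {
          if (!img[i + j * H]) continue;
          // neighbours P2..P9 clockwise starting above
          const int p2 = at(i - 1, j), p3 = at(i - 1, j + 1), p4 = at(i, j + 1),
                    p5 = at(i + 1, j + 1), p6 = at(i + 1, j),
                    p7 = at(i + 1, j - 1), p8 = at(i, j - 1),
                    p9 = at(i - 1, j - 1);
          const int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = 0;
          const int seq[9] = {p2, p3, p4, p5, p6, p7, p8, p9, p2};
          for (int t = 0; t < 8; ++t)
            if (seq[t] == 0 && seq[t + 1] == 1) ++A;
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(i + j * H);
        }
      }
      if (!kill.empty()) changed = true;
      for (int p : kill) img[p] = 0;
    }
  }
  LogicalMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) out(i, j) = img[i + j * H] != 0;
  return out;
}

// number of 8-connected groups of foreground pixels within the 8-neighbour
// ring of (i, j): 1 = line end, 2 = interior path pixel, >= 3 = branch.
static const int RING_DI[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
static const int RING_DJ[8] = {0, 1, 1, 1, 0, -1, -1, -1};

static int ring_groups(const std::vector<unsigned char>& img, int H, int W,
                       int i, int j) {
  bool on[8];
  for (int t = 0; t < 8; ++t) {
    const int ii = i + RING_DI[t], jj = j + RING_DJ[t];
    on[t] = ii >= 0 && ii < H && jj >= 0 && jj < W && img[ii + jj * H];
  }
  // union-find over the 8 ring positions using true 8-adjacency of cells
  int parent[8];
  for (int t = 0; t < 8; ++t) parent[t] = t;
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) a = parent[a] = parent[parent[a]];
    return a;
  };
  for (int a = 0; a < 8; ++a) {
    if (!on[a]) continue;
    for (int b = a + 1; b < 8; ++b) {
      if (!on[b]) continue;
      if (std::abs(RING_DI[a] - RING_DI[b]) <= 1 &&
          std::abs(RING_DJ[a] - RING_DJ[b]) <= 1)
        parent[find(a)] = find(b);
    }
  }
  int groups = 0;
  for (int t = 0; t < 8; ++t)
    if (on[t] && find(t) == t) ++groups;
  return groups;
}

// Remove redundant pixels left by thinning (staircase corners).  A pixel
// with 2+ neighbours is (8,4)-simple — deletable without changing either
// foreground connectivity or holes — iff (i) its foreground ring cells form
// one 8-connected group and (ii) its axial (N/E/S/W) background cells are
// non-empty and all lie in a single background arc of the ring (consecutive
// ring cells are 4-adjacent, so arcs are the 4-components).
// ring order N, NE, E, SE, S, SW, W, NW; axial positions 0, 2, 4, 6
static const int CYC_DI[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
static const int CYC_DJ[8] = {0, 1, 1, 1, 0, -1, -1, -1};

// [[Rcpp::export]]
LogicalMatrix cpp_remove_redundant(const LogicalMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  std::vector<unsigned char> img(H * W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) img[i + j * H] = mask(i, j) ? 1 : 0;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        if (!img[i + j * H]) continue;
        int on[8], nb = 0;
        for (int t = 0; t < 8; ++t) {
          const int ii = i + CYC_DI[t], jj = j + CYC_DJ[t];
          on[t] = ii >= 0 && ii < H && jj >= 0 && jj < W && img[ii + jj * H];
          nb += on[t];
        }
        if (nb < 2 || nb > 7) continue;
        if (ring_groups(img, H, W, i, j) != 1) continue;
        // background arcs: label each bg ring cell by its run
        int arc_id[8], n_arcs = 0;
        for (int t = 0; t < 8; ++t) arc_id[t] = -1;
        for (int t = 0; t < 8; ++t) {
          if (on[t]) continue;
          if (arc_id[t] >= 0) continue;
          // start of a run if previous cell is fg, or seed anywhere and
          // sweep both ways; simplest: flood along the cycle
          int id = n_arcs++;
          int u = t;
          while (!on[u] && arc_id[u] < 0) { arc_id[u] = id; u = (u + 1) % 8; }
          u = (t + 7) % 8;
          while (!on[u] && arc_id[u] < 0) { arc_id[u] = id; u = (u + 7) % 8; }
        }
        int ax_arc = -2;
        bool ok = false, split = false;
        for (int t = 0; t < 8; t += 2) {  // axial positions
          if (on[t]) continue;
          if (ax_arc == -2) { ax_arc = arc_id[t]; ok = true; }
          else if (arc_id[t] != ax_arc) split = true;
        }
        if (ok && !split) {
          img[i + j * H] = 0;
          changed = true;
        }
      }
    }
  }
  LogicalMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) out(i, j) = img[i + j * H] != 0;
  return out;
}

// per-pixel Rutovitz crossing number: the number of 0->1 transitions along
// the cyclic 8-neighbour ring (0 for background pixels).  1 = line end,
// 2 = interior path pixel, >= 3 = branch point.
// [[Rcpp::export]]
IntegerMatrix cpp_crossing_number(const LogicalMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  // cyclic ring order N, NE, E, SE, S, SW, W, NW
  const int CDI[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  const int CDJ[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  IntegerMatrix out(H, W);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j)) continue;
      int on[8];
      for (int t = 0; t < 8; ++t) {
        const int ii = i + CDI[t], jj = j + CDJ[t];
        on[t] = ii >= 0 && ii < H && jj >= 0 && jj < W && mask(ii, jj);
      }
      int c = 0;
      for (int t = 0; t < 8; ++t)
        if (!on[t] && on[(t + 1) % 8]) ++c;
      out(i, j) = c;
    }
  }
  return out;
}

// max over rows of A of the min Euclidean distance to rows of B
// [[Rcpp::export]]
double cpp_hausdorff_directed(const NumericMatrix& A, const NumericMatrix& B) {
  double worst = 0.0;
  for (int i = 0; i < A.nrow(); ++i) {
    double best = R_PosInf;
    const double ax = A(i, 0), ay = A(i, 1);
    for (int j = 0; j < B.nrow(); ++j) {
      const double dx = ax - B(j, 0), dy = ay - B(j, 1);
      const double d = dx * dx + dy * dy;
      if (d < best) best = d;
      if (best == 0.0) break;
    }
    if (best > worst) worst = best;
  }
  return std::sqrt(worst);
}
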