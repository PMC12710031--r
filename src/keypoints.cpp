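// Scale/rotation-invariant keypoint detection and description for
// template matching of the reference chart: Gaussian scale-space pyramid,
// difference-of-Gaussian extrema with subpixel refinement, dominant
// gradient orientation, and 4x4x8 gradient-histogram descriptors.
//
// Input images are grayscale matrices in [0, 1]; keypoint coordinates are
// returned in the 0-based continuous pixel frame used by the R side
// (pixel center of matrix cell (r, c), 1-based, is (c - 0.5, r - 0.5)).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

namespace {

struct FImage {
  int h = 0, w = 0;
  std::vector<float> d;
  FImage() = default;
  FImage(int h_, int w_) : h(h_), w(w_), d((size_t)h_ * w_, 0.f) {}
  inline float at(int r, int c) const { return d[(size_t)r * w + c]; }
  inline float& at(int r, int c) { return d[(size_t)r * w + c]; }
};

inline int reflect(int i, int n) {
  // border handling: replicate
  if (i < 0) return 0;
  if (i >= n) return n - 1;
  return i;
}

FImage gaussian_blur(const FImage& src, double sigma) {
  if (sigma <= 0.01) return src;
  int radius = (int)std::ceil(4.0 * sigma);
  std::vector<float> k(2 * radius + 1);
  double s2 = 2.0 * sigma * sigma, sum = 0.0;
  for (int i = -radius; i <= radius; ++i) {
    k[i + radius] = (float)std::exp(-(double)i * i / s2);
    sum += k[i + radius];
  }
  for (auto& v : k) v = (float)(v / sum);

  FImage tmp(src.h, src.w), dst(src.h, src.w);
  for (int r = 0; r < src.h; ++r)
    for (int c = 0; c < src.w; ++c) {
      float acc = 0.f;
      for (int i = -radius; i <= radius; ++i)
        acc += k[i + radius] * src.at(r, reflect(c + i, src.w));
      tmp.at(r, c) = acc;
    }
  for (int r = 0; r < src.h; ++r)
    for (int c = 0; c < src.w; ++c) {
      float acc = 0.f;
      for (int i = -radius; i <= radius; ++i)
        acc += k[i + radius] * tmp.at(reflect(r + i, src.h), c);
      dst.at(r, c) = acc;
    }
  return dst;
}

FImage downsample2(const FImage& src) {
  FImage dst(src.h / 2, src.w / 2);
  for (int r = 0; r < dst.h; ++r)
    for (int c = 0; c < dst.w; ++c)
      dst.at(r, c) = src.at(2 * r, 2 * c);
  return dst;
}

// bilinear 2x upsampling for the -1 octave
FImage upsample2(const FImage& src) {
  FImage dst(src.h * 2, src.w * 2);
  for (int r = 0; r < dst.h; ++r) {
    double sr = r * 0.5;
    int r0 = std::min((int)sr, src.h - 1), r1 = std::min(r0 + 1, src.h - 1);
    double fr = sr - r0;
    for (int c = 0; c < dst.w; ++c) {
      double sc = c * 0.5;
      int c0 = std::min((int)sc, src.w - 1), c1 = std::min(c0 + 1, src.w - 1);
      double fc = sc - c0;
      dst.at(r, c) = (float)(
        (1 - fr) * ((1 - fc) * src.at(r0, c0) + fc * src.at(r0, c1)) +
        fr * ((1 - fc) * src.at(r1, c0) + fc * src.at(r1, c1)));
    }
  }
  return dst;
}

FImage subtract(const FImage& a, const FImage& b) {
  FImage out(a.h, a.w);
  for (size_t i = 0; i < a.d.size(); ++i) out.d[i] = a.d[i] - b.d[i];
  return out;
}

struct Keypoint {
  double x, y;        // octave-0 pixel coordinates
  double size;        // characteristic scale (sigma in octave-0 units)
  double angle;       // dominant orientation, degrees in [0, 360)
  double response;    // |DoG| contrast
  int octave, layer;  // pyramid position
  double xo, yo;      // coordinates within its octave
  double scale_oct;   // sigma within its octave
};

// 3x3 linear solve by Cramer's rule; returns false if near-singular
bool solve3(const double A[3][3], const double b[3], double x[3]) {
  double det =
    A[0][0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1]) -
    A[0][1] * (A[1][0] * A[2][2] - A[1][2] * A[2][0]) +
    A[0][2] * (A[1][0] * A[2][1] - A[1][1] * A[2][0]);
  if (std::fabs(det) < 1e-12) return false;
  double inv = 1.0 / det;
  x[0] = inv * (b[0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1]) -
                A[0][1] * (b[1] * A[2][2] - A[1][2] * b[2]) +
                A[0][2] * (b[1] * A[2][1] - A[1][1] * b[2]));
  x[1] = inv * (A[0][0] * (b[1] * A[2][2] - A[1][2] * b[2]) -
                b[0] * (A[1][0] * A[2][2] - A[1][2] * A[2][0]) +
                A[0][2] * (A[1][0] * b[2] - b[1] * A[2][0]));
  x[2] = inv * (A[0][0] * (A[1][1] * b[2] - b[1] * A[2][1]) -
                A[0][1] * (A[1][0] * b[2] - b[1] * A[2][0]) +
                b[0] * (A[1][0] * A[2][1] - A[1][1] * A[2][0]));
  return true;
}

// orientation histogram around (r, c) on gaussian image g
// returns peak angles (degrees)
std::vector<double> dominant_orientations(const FImage& g, double x, double y,
                                          double sigma_oct) {
  const int nbins = 36;
  double hist[nbins] = {0.0};
  double sigma_w = 1.5 * sigma_oct;
  int radius = (int)std::round(3.0 * sigma_w);
  int rc = (int)std::round(y), cc = (int)std::round(x);
  double denom = 2.0 * sigma_w * sigma_w;
  for (int dr = -radius; dr <= radius; ++dr) {
    int r = rc + dr;
    if (r < 1 || r >= g.h - 1) continue;
    for (int dc = -radius; dc <= radius; ++dc) {
      int c = cc + dc;
      if (c < 1 || c >= g.w - 1) continue;
      double dx = g.at(r, c + 1) - g.at(r, c - 1);
      double dy = g.at(r + 1, c) - g.at(r - 1, c);
      double mag = std::sqrt(dx * dx + dy * dy);
      double ang = std::atan2(dy, dx) * 180.0 / M_PI;
      if (ang < 0) ang += 360.0;
      double wgt = std::exp(-((double)dr * dr + (double)dc * dc) / denom);
      int bin = (int)std::floor(ang / 10.0) % nbins;
      hist[bin] += wgt * mag;
    }
  }
  // circular smoothing, two passes of [1 2 1]/4
  for (int pass = 0; pass < 2; ++pass) {
    double tmp[nbins];
    for (int i = 0; i < nbins; ++i) {
      double l = hist[(i + nbins - 1) % nbins];
      double r = hist[(i + 1) % nbins];
      tmp[i] = 0.25 * l + 0.5 * hist[i] + 0.25 * r;
    }
    std::copy(tmp, tmp + nbins, hist);
  }
  double mx = *std::max_element(hist, hist + nbins);
  std::vector<double> out;
  if (mx <= 0) return out;
  for (int i = 0; i < nbins; ++i) {
    double l = hist[(i + nbins - 1) % nbins];
    double r = hist[(i + 1) % nbins];
    if (hist[i] > l && hist[i] > r && hist[i] >= 0.8 * mx) {
      double interp = 0.5 * (l - r) / (l - 2.0 * hist[i] + r);
      double ang = (i + 0.5 + interp) * 10.0;
      if (ang < 0) ang += 360.0;
      if (ang >= 360.0) ang -= 360.0;
      out.push_back(ang);
    }
  }
  return out;
}

// 4x4 spatial x 8 orientation gradient-histogram descriptor (128-d)
void compute_descriptor(const FImage& g, const Keypoint& kp, float* dst) {
  const int d = 4, n = 8;
  double angle_rad = kp.angle * M_PI / 180.0;
  double cos_t = std::cos(angle_rad), sin_t = std::sin(angle_rad);
  double hist_width = 3.0 * kp.scale_oct;
  double radius_f = hist_width * std::sqrt(2.0) * (d + 1) * 0.5;
  int radius = std::min((int)std::round(radius_f),
                        (int)std::sqrt((double)g.h * g.h + (double)g.w * g.w));
  double exp_scale = -1.0 / (d * d * 0.5);
  double bins_per_deg = n / 360.0;
  cos_t /= hist_width;
  sin_t /= hist_width;

  std::vector<double> hist((d + 2) * (d + 2) * (n + 2), 0.0);
  int rc = (int)std::round(kp.yo), cc = (int)std::round(kp.xo);

  for (int dr = -radius; dr <= radius; ++dr) {
    for (int dc = -radius; dc <= radius; ++dc) {
      double c_rot = dc * cos_t + dr * sin_t;
      double r_rot = -dc * sin_t + dr * cos_t;
      double rbin = r_rot + d / 2.0 - 0.5;
      double cbin = c_rot + d / 2.0 - 0.5;
      int r = rc + dr, c = cc + dc;
      if (rbin <= -1 || rbin >= d || cbin <= -1 || cbin >= d) continue;
      if (r < 1 || r >= g.h - 1 || c < 1 || c >= g.w - 1) continue;
      double dx = g.at(r, c + 1) - g.at(r, c - 1);
      double dy = g.at(r + 1, c) - g.at(r - 1, c);
      double mag = std::sqrt(dx * dx + dy * dy);
      double ang = std::atan2(dy, dx) * 180.0 / M_PI;
      if (ang < 0) ang += 360.0;
      double obin = (ang - kp.angle) * bins_per_deg;
      double wgt = std::exp((c_rot * c_rot + r_rot * r_rot) * exp_scale);
      mag *= wgt;

      int r0 = (int)std::floor(rbin);
      int c0 = (int)std::floor(cbin);
      int o0 = (int)std::floor(obin);
      rbin -= r0; cbin -= c0; obin -= o0;
      o0 = ((o0 % n) + n) % n;

      // trilinear distribution into the histogram
      for (int ir = 0; ir <= 1; ++ir) {
        int rb = r0 + ir;
        if (rb < -1 || rb > d) continue;
        double wr = mag * (ir ? rbin : 1.0 - rbin);
        for (int ic = 0; ic <= 1; ++ic) {
          int cb = c0 + ic;
          if (cb < -1 || cb > d) continue;
          double wc = wr * (ic ? cbin : 1.0 - cbin);
          for (int io = 0; io <= 1; ++io) {
            int ob = (o0 + io) % n;
            double wo = wc * (io ? obin : 1.0 - obin);
            size_t idx = ((size_t)(rb + 1) * (d + 2) + (cb + 1)) * (n + 2) + ob;
            hist[idx] += wo;
          }
        }
      }
    }
  }

  // collapse the padded histogram into the 128-vector
  int k = 0;
  double nrm2 = 0.0;
  std::vector<double> raw(d * d * n);
  for (int r = 0; r < d; ++r)
    for (int c = 0; c < d; ++c)
      for (int o = 0; o < n; ++o) {
        double v = hist[((size_t)(r + 1) * (d + 2) + (c + 1)) * (n + 2) + o];
        raw[k++] = v;
        nrm2 += v * v;
      }
  double thr = std::sqrt(nrm2) * 0.2;
  double nrm1 = 0.0;
  for (auto& v : raw) { v = std::min(v, thr); nrm1 += v; }
  // root-descriptor normalization: L1-normalize then take square roots,
  // which makes Euclidean matching behave like a Hellinger kernel and
  // discriminates repetitive structure better
  double scale = 1.0 / std::max(nrm1, 1e-12);
  for (int i = 0; i < d * d * n; ++i)
    dst[i] = (float)std::sqrt(raw[i] * scale);
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".detect_keypoints_cpp")]]
List detect_keypoints_cpp(NumericMatrix gray, int n_octave_layers = 3,
                          double contrast_thr = 0.04, double edge_thr = 10.0,
                          double sigma = 1.6, bool upscale = true) {
  int h = gray.nrow(), w = gray.ncol();
  FImage base(h, w);
  for (int r = 0; r < h; ++r)
    for (int c = 0; c < w; ++c)
      base.at(r, c) = (float)gray(r, c);

  // assumed capture blur 0.5 (1.0 after 2x upsampling); bring base to sigma
  double coord_scale = 1.0;
  double init_blur = 0.5;
  if (upscale) {
    base = upsample2(base);
    coord_scale = 0.5;
    init_blur = 1.0;
  }
  double sig_diff =
    std::sqrt(std::max(sigma * sigma - init_blur * init_blur, 0.01));
  base = gaussian_blur(base, sig_diff);

  int n_octaves = std::max(1, (int)std::floor(
      std::log2((double)std::min(base.h, base.w)) - 3.0));

  double k = std::pow(2.0, 1.0 / n_octave_layers);
  std::vector<double> sig(n_octave_layers + 3);
  sig[0] = sigma;
  for (int i = 1; i < n_octave_layers + 3; ++i) {
    double prev = sigma * std::pow(k, i - 1);
    double total = prev * k;
    sig[i] = std::sqrt(total * total - prev * prev);
  }

  std::vector<std::vector<FImage>> gauss(n_octaves), dog(n_octaves);
  for (int o = 0; o < n_octaves; ++o) {
    gauss[o].resize(n_octave_layers + 3);
    if (o == 0) gauss[o][0] = base;
    else gauss[o][0] = downsample2(gauss[o - 1][n_octave_layers]);
    for (int i = 1; i < n_octave_layers + 3; ++i)
      gauss[o][i] = gaussian_blur(gauss[o][i - 1], sig[i]);
    dog[o].resize(n_octave_layers + 2);
    for (int i = 0; i < n_octave_layers + 2; ++i)
      dog[o][i] = subtract(gauss[o][i + 1], gauss[o][i]);
  }

  double prelim_thr = 0.5 * contrast_thr / n_octave_layers;
  std::vector<Keypoint> kps;

  for (int o = 0; o < n_octaves; ++o) {
    int oh = dog[o][0].h, ow = dog[o][0].w;
    if (oh < 10 || ow < 10) break;
    for (int s = 1; s <= n_octave_layers; ++s) {
      const FImage& prev = dog[o][s - 1];
      const FImage& cur = dog[o][s];
      const FImage& next = dog[o][s + 1];
      for (int r = 5; r < oh - 5; ++r) {
        for (int c = 5; c < ow - 5; ++c) {
          float v = cur.at(r, c);
          if (std::fabs(v) <= prelim_thr) continue;
          bool mx = true, mn = true;
          for (int dr = -1; dr <= 1 && (mx || mn); ++dr)
            for (int dc = -1; dc <= 1; ++dc) {
              float p = prev.at(r + dr, c + dc);
              float q = cur.at(r + dr, c + dc);
              float t = next.at(r + dr, c + dc);
              if (p > v || t > v || (q > v && !(dr == 0 && dc == 0))) mx = false;
              if (p < v || t < v || (q < v && !(dr == 0 && dc == 0))) mn = false;
            }
          if (!mx && !mn) continue;

          // iterative subpixel refinement
          int ri = r, ci = c, si = s;
          double xr = 0, xc = 0, xs = 0, contr = 0;
          bool ok = false;
          for (int it = 0; it < 5; ++it) {
            const FImage& D0 = dog[o][si - 1];
            const FImage& D1 = dog[o][si];
            const FImage& D2 = dog[o][si + 1];
            double dx = 0.5 * (D1.at(ri, ci + 1) - D1.at(ri, ci - 1));
            double dy = 0.5 * (D1.at(ri + 1, ci) - D1.at(ri - 1, ci));
            double ds = 0.5 * (D2.at(ri, ci) - D0.at(ri, ci));
            double dxx = D1.at(ri, ci + 1) + D1.at(ri, ci - 1) - 2.0 * D1.at(ri, ci);
            double dyy = D1.at(ri + 1, ci) + D1.at(ri - 1, ci) - 2.0 * D1.at(ri, ci);
            double dss = D2.at(ri, ci) + D0.at(ri, ci) - 2.0 * D1.at(ri, ci);
            double dxy = 0.25 * (D1.at(ri + 1, ci + 1) - D1.at(ri + 1, ci - 1) -
                                 D1.at(ri - 1, ci + 1) + D1.at(ri - 1, ci - 1));
            double dxs = 0.25 * (D2.at(ri, ci + 1) - D2.at(ri, ci - 1) -
                                 D0.at(ri, ci + 1) + D0.at(ri, ci - 1));
            double dys = 0.25 * (D2.at(ri + 1, ci) - D2.at(ri - 1, ci) -
                                 D0.at(ri + 1, ci) + D0.at(ri - 1, ci));
            double A[3][3] = {{dxx, dxy, dxs}, {dxy, dyy, dys}, {dxs, dys, dss}};
            double bvec[3] = {-dx, -dy, -ds};
            double sol[3];
            if (!solve3(A, bvec, sol)) break;
            xc = sol[0]; xr = sol[1]; xs = sol[2];
            if (std::fabs(xc) < 0.5 && std::fabs(xr) < 0.5 && std::fabs(xs) < 0.5) {
              contr = D1.at(ri, ci) + 0.5 * (dx * xc + dy * xr + ds * xs);
              // principal-curvature (edge response) test on the refined point
              double tr = dxx + dyy, det = dxx * dyy - dxy * dxy;
              if (det <= 0 ||
                  tr * tr * edge_thr >= (edge_thr + 1) * (edge_thr + 1) * det)
                break;
              ok = true;
              break;
            }
            ci += (int)std::round(xc);
            ri += (int)std::round(xr);
            si += (int)std::round(xs);
            if (si < 1 || si > n_octave_layers ||
                ri < 5 || ri >= oh - 5 || ci < 5 || ci >= ow - 5)
              break;
          }
          if (!ok) continue;
          if (std::fabs(contr) * n_octave_layers < contrast_thr) continue;

          Keypoint kp;
          kp.octave = o;
          kp.layer = si;
          kp.xo = ci + xc;
          kp.yo = ri + xr;
          kp.x = kp.xo * std::pow(2.0, o);
          kp.y = kp.yo * std::pow(2.0, o);
          kp.scale_oct = sigma * std::pow(2.0, (si + xs) / n_octave_layers);
          kp.size = kp.scale_oct * std::pow(2.0, o);
          kp.response = std::fabs(contr);

          const FImage& g = gauss[o][si];
          std::vector<double> angles =
            dominant_orientations(g, kp.xo, kp.yo, kp.scale_oct);
          for (double a : angles) {
            kp.angle = a;
            kps.push_back(kp);
          }
        }
      }
    }
  }

  int nkp = (int)kps.size();
  NumericMatrix pts(nkp, 5);
  NumericMatrix desc(nkp, 128);
  std::vector<float> buf(128);
  for (int i = 0; i < nkp; ++i) {
    const Keypoint& kp = kps[i];
    pts(i, 0) = kp.x * coord_scale;
    pts(i, 1) = kp.y * coord_scale;
    pts(i, 2) = kp.size * coord_scale;
    pts(i, 3) = kp.angle;
    pts(i, 4) = kp.response;
    compute_descriptor(gauss[kp.octave][kp.layer], kp, buf.data());
    for (int j = 0; j < 128; ++j) desc(i, j) = buf[j];
  }
  colnames(pts) = CharacterVector::create("x", "y", "size", "angle", "response");
  return List::create(_["keypoints"] = pts, _["descriptors"] = desc);
}
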