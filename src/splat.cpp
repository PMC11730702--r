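// CPU forward and backward pass of the 3D Gaussian-splat renderer.
//
// Rendering model: each Gaussian (mean, anisotropic covariance from
// scale/rotation, opacity, degree-0 RGB) is projected perspectively; the 2D
// covariance is J W Sigma W^T J^T + 0.3 I (EWA splatting with isotropic
// dilation), Gaussians are composited front-to-back per pixel with
// transmittance. Outputs: RGB over a background colour, alpha-normalized
// expected depth, composited (renormalized) per-Gaussian normals, and the
// accumulated alpha. The backward pass propagates per-pixel adjoints of all
// four outputs to analytic gradients of every Gaussian parameter.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const double ZMIN = 0.2;         // near clip (mm)
static const double DILATION = 0.3;     // px^2 isotropic screen-space dilation
static const double ALPHA_MIN = 1.0 / 255.0;
static const double ALPHA_MAX = 0.99;
static const double T_STOP = 1e-6;      // early transmittance stop

struct Prep {
  int N, W, H;
  std::vector<int> keep;              // indices of non-culled gaussians, depth order
  // per original gaussian index:
  std::vector<double> u, v;           // projected mean (pixels)
  std::vector<double> qa, qb, qc;     // conic (inverse 2D covariance)
  std::vector<double> opa;            // activated opacity
  std::vector<double> tx, ty, tz;     // camera-frame mean
  std::vector<double> ncx, ncy, ncz;  // camera-frame unit normal (flipped)
  std::vector<double> s0, s1, s2;     // activated scales
  std::vector<int> kmin;              // axis of smallest scale
  std::vector<double> flip;           // normal flip sign
  std::vector<double> A;              // 3x3 W*R3 per gaussian (row-major, 9)
  std::vector<double> Jb;             // 2x3 J*B per gaussian (row-major, 6)
  std::vector<int> x0, x1, y0, y1;    // pixel bbox (inclusive)
  std::vector<bool> valid;
  std::vector<std::vector<int> > rows; // per image row: kept gaussians (depth order)
};

static void prep_gaussians(const NumericMatrix& xyz, const NumericMatrix& log_scales,
                           const NumericMatrix& quats, const NumericVector& logits,
                           const NumericMatrix& Wp, const NumericVector& tvec,
                           double fx, double fy, double cx, double cy,
                           int width, int height, Prep& P) {
  const int N = xyz.nrow();
  P.N = N; P.W = width; P.H = height;
  P.u.assign(N,0); P.v.assign(N,0); P.qa.assign(N,0); P.qb.assign(N,0); P.qc.assign(N,0);
  P.opa.assign(N,0); P.tx.assign(N,0); P.ty.assign(N,0); P.tz.assign(N,0);
  P.ncx.assign(N,0); P.ncy.assign(N,0); P.ncz.assign(N,0);
  P.s0.assign(N,0); P.s1.assign(N,0); P.s2.assign(N,0);
  P.kmin.assign(N,0); P.flip.assign(N,1.0);
  P.A.assign(9*N,0); P.Jb.assign(6*N,0);
  P.x0.assign(N,0); P.x1.assign(N,0); P.y0.assign(N,0); P.y1.assign(N,0);
  P.valid.assign(N,false);
  double R00=Wp(0,0),R01=Wp(0,1),R02=Wp(0,2),
         R10=Wp(1,0),R11=Wp(1,1),R12=Wp(1,2),
         R20=Wp(2,0),R21=Wp(2,1),R22=Wp(2,2);
  for (int i = 0; i < N; ++i) {
    double mx = xyz(i,0), my = xyz(i,1), mz = xyz(i,2);
    double tx_ = R00*mx + R01*my + R02*mz + tvec[0];
    double ty_ = R10*mx + R11*my + R12*mz + tvec[1];
    double tz_ = R20*mx + R21*my + R22*mz + tvec[2];
    if (tz_ < ZMIN) continue;
    double o = 1.0 / (1.0 + std::exp(-logits[i]));
    if (o < ALPHA_MIN) continue;
    // quaternion (normalized) -> rotation
    double qw = quats(i,0), qx = quats(i,1), qy = quats(i,2), qz = quats(i,3);
    double qn = std::sqrt(qw*qw + qx*qx + qy*qy + qz*qz);
    if (qn < 1e-12) continue;
    qw/=qn; qx/=qn; qy/=qn; qz/=qn;
    double Rq[9] = {
      1-2*(qy*qy+qz*qz), 2*(qx*qy-qw*qz),   2*(qx*qz+qw*qy),
      2*(qx*qy+qw*qz),   1-2*(qx*qx+qz*qz), 2*(qy*qz-qw*qx),
      2*(qx*qz-qw*qy),   2*(qy*qz+qw*qx),   1-2*(qx*qx+qy*qy) };
    // A = Wpose * Rq
    double Aa[9];
    Aa[0]=R00*Rq[0]+R01*Rq[3]+R02*Rq[6]; Aa[1]=R00*Rq[1]+R01*Rq[4]+R02*Rq[7]; Aa[2]=R00*Rq[2]+R01*Rq[5]+R02*Rq[8];
    Aa[3]=R10*Rq[0]+R11*Rq[3]+R12*Rq[6]; Aa[4]=R10*Rq[1]+R11*Rq[4]+R12*Rq[7]; Aa[5]=R10*Rq[2]+R11*Rq[5]+R12*Rq[8];
    Aa[6]=R20*Rq[0]+R21*Rq[3]+R22*Rq[6]; Aa[7]=R20*Rq[1]+R21*Rq[4]+R22*Rq[7]; Aa[8]=R20*Rq[2]+R21*Rq[5]+R22*Rq[8];
    double s0 = std::exp(log_scales(i,0)), s1 = std::exp(log_scales(i,1)),
           s2 = std::exp(log_scales(i,2));
    // B = A diag(s); Jacobian J at the mean
    double J00 = fx / tz_, J02 = -fx * tx_ / (tz_*tz_);
    double J11 = fy / tz_, J12 = -fy * ty_ / (tz_*tz_);
    double B[9] = { Aa[0]*s0, Aa[1]*s1, Aa[2]*s2,
                    Aa[3]*s0, Aa[4]*s1, Aa[5]*s2,
                    Aa[6]*s0, Aa[7]*s1, Aa[8]*s2 };
    double Jb[6];
    Jb[0] = J00*B[0] + J02*B[6]; Jb[1] = J00*B[1] + J02*B[7]; Jb[2] = J00*B[2] + J02*B[8];
    Jb[3] = J11*B[3] + J12*B[6]; Jb[4] = J11*B[4] + J12*B[7]; Jb[5] = J11*B[5] + J12*B[8];
    double c00 = Jb[0]*Jb[0] + Jb[1]*Jb[1] + Jb[2]*Jb[2] + DILATION;
    double c01 = Jb[0]*Jb[3] + Jb[1]*Jb[4] + Jb[2]*Jb[5];
    double c11 = Jb[3]*Jb[3] + Jb[4]*Jb[4] + Jb[5]*Jb[5] + DILATION;
    double det = c00*c11 - c01*c01;
    if (det <= 0) continue;
    double qa =  c11/det, qb = -c01/det, qc =  c00/det;
    double u = fx * tx_ / tz_ + cx, v = fy * ty_ / tz_ + cy;
    double lmax = 0.5*(c00+c11) + std::sqrt(0.25*(c00-c11)*(c00-c11) + c01*c01);
    double rad = 3.0 * std::sqrt(lmax);
    int bx0 = (int)std::floor(u - rad), bx1 = (int)std::ceil(u + rad);
    int by0 = (int)std::floor(v - rad), by1 = (int)std::ceil(v + rad);
    if (bx0 < 0) bx0 = 0; if (by0 < 0) by0 = 0;
    if (bx1 > width-1) bx1 = width-1; if (by1 > height-1) by1 = height-1;
    if (bx0 > bx1 || by0 > by1) continue;
    // normal: world axis of smallest activated scale, camera frame, flipped
    int km = 0; double smin = s0;
    if (s1 < smin) { smin = s1; km = 1; }
    if (s2 < smin) { smin = s2; km = 2; }
    double nx = Aa[km], ny = Aa[3+km], nz = Aa[6+km];
    double fl = (nx*tx_ + ny*ty_ + nz*tz_ > 0) ? -1.0 : 1.0;
    P.u[i]=u; P.v[i]=v; P.qa[i]=qa; P.qb[i]=qb; P.qc[i]=qc; P.opa[i]=o;
    P.tx[i]=tx_; P.ty[i]=ty_; P.tz[i]=tz_;
    P.ncx[i]=fl*nx; P.ncy[i]=fl*ny; P.ncz[i]=fl*nz;
    P.s0[i]=s0; P.s1[i]=s1; P.s2[i]=s2; P.kmin[i]=km; P.flip[i]=fl;
    for (int k = 0; k < 9; ++k) P.A[9*i+k] = Aa[k];
    for (int k = 0; k < 6; ++k) P.Jb[6*i+k] = Jb[k];
    P.x0[i]=bx0; P.x1[i]=bx1; P.y0[i]=by0; P.y1[i]=by1;
    P.valid[i] = true;
  }
  // depth-sorted kept list (stable sort for deterministic ties)
  P.keep.clear();
  for (int i = 0; i < N; ++i) if (P.valid[i]) P.keep.push_back(i);
  std::stable_sort(P.keep.begin(), P.keep.end(),
                   [&P](int a, int b) { return P.tz[a] < P.tz[b]; });
  P.rows.assign(height, std::vector<int>());
  for (size_t k = 0; k < P.keep.size(); ++k) {
    int i = P.keep[k];
    for (int y = P.y0[i]; y <= P.y1[i]; ++y) P.rows[y].push_back(i);
  }
}

// [[Rcpp::export]]
List splat_render_cpp(NumericMatrix xyz, NumericMatrix log_scales,
                      NumericMatrix quats, NumericVector logits,
                      NumericMatrix colors, NumericMatrix Wp,
                      NumericVector tvec, double fx, double fy,
                      double cx, double cy, int width, int height,
                      NumericVector bg, IntegerVector flag) {
  Prep P;
  prep_gaussians(xyz, log_scales, quats, logits, Wp, tvec,
                 fx, fy, cx, cy, width, height, P);
  const int H = height, Wd = width, HW = H * Wd;
  NumericVector image(HW * 3), depth(HW), normal(HW * 3), alpha(HW);
  bool use_flag = flag.size() == xyz.nrow();
  NumericVector flagw(use_flag ? HW : 0);
  for (int y = 0; y < H; ++y) {
    const std::vector<int>& lst = P.rows[y];
    for (int x = 0; x < Wd; ++x) {
      double T = 1.0, Cr = 0, Cg = 0, Cb = 0, Dr = 0, Aacc = 0;
      double Nx = 0, Ny = 0, Nz = 0, Fw = 0;
      for (size_t k = 0; k < lst.size(); ++k) {
        int i = lst[k];
        if (x < P.x0[i] || x > P.x1[i]) continue;
        double dx = x - P.u[i], dy = y - P.v[i];
        double power = -0.5*(P.qa[i]*dx*dx + P.qc[i]*dy*dy) - P.qb[i]*dx*dy;
        if (power > 0) continue;
        double a = P.opa[i] * std::exp(power);
        if (a > ALPHA_MAX) a = ALPHA_MAX;
        if (a < ALPHA_MIN) continue;
        double w = a * T;
        Cr += w * colors(i,0); Cg += w * colors(i,1); Cb += w * colors(i,2);
        Dr += w * P.tz[i];
        Nx += w * P.ncx[i]; Ny += w * P.ncy[i]; Nz += w * P.ncz[i];
        Aacc += w;
        if (use_flag && flag[i]) Fw += w;
        T *= (1.0 - a);
        if (T < T_STOP) break;
      }
      int p = y + x * H;
      image[p]        = Cr + T * bg[0];
      image[p + HW]   = Cg + T * bg[1];
      image[p + 2*HW] = Cb + T * bg[2];
      alpha[p] = Aacc;
      depth[p] = (Aacc > 1e-12) ? Dr / Aacc : 0.0;
      double nn = std::sqrt(Nx*Nx + Ny*Ny + Nz*Nz);
      if (nn > 1e-12) {
        normal[p] = Nx/nn; normal[p + HW] = Ny/nn; normal[p + 2*HW] = Nz/nn;
      }
      if (use_flag) flagw[p] = Fw;
    }
  }
  image.attr("dim") = Dimension(H, Wd, 3);
  depth.attr("dim") = Dimension(H, Wd);
  normal.attr("dim") = Dimension(H, Wd, 3);
  alpha.attr("dim") = Dimension(H, Wd);
  List out = List::create(_["image"] = image, _["depth"] = depth,
                          _["normal"] = normal, _["alpha"] = alpha);
  if (use_flag) { flagw.attr("dim") = Dimension(H, Wd); out["flag_weight"] = flagw; }
  return out;
}

// Backward pass: adjoints g_image (H,W,3), g_depth (H,W), g_normal (H,W,3),
// g_alpha (H,W) -> gradients of all Gaussian parameters.
// [[Rcpp::export]]
List splat_backward_cpp(NumericMatrix xyz, NumericMatrix log_scales,
                        NumericMatrix quats, NumericVector logits,
                        NumericMatrix colors, NumericMatrix Wp,
                        NumericVector tvec, double fx, double fy,
                        double cx, double cy, int width, int height,
                        NumericVector bg, NumericVector g_image,
                        NumericVector g_depth, NumericVector g_normal,
                        NumericVector g_alpha) {
  Prep P;
  prep_gaussians(xyz, log_scales, quats, logits, Wp, tvec,
                 fx, fy, cx, cy, width, height, P);
  const int N = xyz.nrow(), H = height, Wd = width, HW = H * Wd;
  // per-gaussian accumulators
  std::vector<double> gm_u(N,0), gm_v(N,0), gQa(N,0), gQb(N,0), gQc(N,0),
    g_o(N,0), g_tzacc(N,0), g_ncam(3*N,0);
  NumericMatrix g_xyz(N,3), g_ls(N,3), g_q(N,4), g_col(N,3);
  NumericVector g_logit(N);
  // pixel loop
  std::vector<int> cidx; std::vector<double> ca, cw, cT;
  for (int y = 0; y < H; ++y) {
    const std::vector<int>& lst = P.rows[y];
    for (int x = 0; x < Wd; ++x) {
      int p = y + x * H;
      double gI0 = g_image[p], gI1 = g_image[p+HW], gI2 = g_image[p+2*HW];
      double gD = g_depth[p], gA_ext = g_alpha[p];
      double gN0 = g_normal[p], gN1 = g_normal[p+HW], gN2 = g_normal[p+2*HW];
      if (gI0==0 && gI1==0 && gI2==0 && gD==0 && gA_ext==0 &&
          gN0==0 && gN1==0 && gN2==0) continue;
      // forward re-walk, storing contributions
      cidx.clear(); ca.clear(); cw.clear(); cT.clear();
      double T = 1.0, Dr = 0, Aacc = 0, Nx = 0, Ny = 0, Nz = 0;
      for (size_t k = 0; k < lst.size(); ++k) {
        int i = lst[k];
        if (x < P.x0[i] || x > P.x1[i]) continue;
        double dx = x - P.u[i], dy = y - P.v[i];
        double power = -0.5*(P.qa[i]*dx*dx + P.qc[i]*dy*dy) - P.qb[i]*dx*dy;
        if (power > 0) continue;
        double a = P.opa[i] * std::exp(power);
        if (a > ALPHA_MAX) a = ALPHA_MAX;
        if (a < ALPHA_MIN) continue;
        double w = a * T;
        cidx.push_back(i); ca.push_back(a); cw.push_back(w); cT.push_back(T);
        Dr += w * P.tz[i];
        Nx += w * P.ncx[i]; Ny += w * P.ncy[i]; Nz += w * P.ncz[i];
        Aacc += w;
        T *= (1.0 - a);
        if (T < T_STOP) break;
      }
      if (cidx.empty()) continue;
      // chain through the output normalizations
      double gDr = 0, gA_tot = gA_ext;
      if (Aacc > 1e-12) {
        gDr = gD / Aacc;
        gA_tot += -gD * Dr / (Aacc * Aacc);
      }
      double gNr0 = 0, gNr1 = 0, gNr2 = 0;
      double nn = std::sqrt(Nx*Nx + Ny*Ny + Nz*Nz);
      if (nn > 1e-12) {
        double inx = Nx/nn, iny = Ny/nn, inz = Nz/nn;
        double dot = inx*gN0 + iny*gN1 + inz*gN2;
        gNr0 = (gN0 - inx*dot)/nn;
        gNr1 = (gN1 - iny*dot)/nn;
        gNr2 = (gN2 - inz*dot)/nn;
      }
      double gT_fin = gI0*bg[0] + gI1*bg[1] + gI2*bg[2];
      // reverse sweep over contributions
      int M = (int)cidx.size();
      double S = gT_fin * T;  // T is the final transmittance
      for (int k = M - 1; k >= 0; --k) {
        int i = cidx[k];
        double a = ca[k], w = cw[k], Tk = cT[k];
        double ui = gI0*colors(i,0) + gI1*colors(i,1) + gI2*colors(i,2)
          + gDr * P.tz[i]
          + gNr0 * P.ncx[i] + gNr1 * P.ncy[i] + gNr2 * P.ncz[i]
          + gA_tot;
        // channel gradients
        g_col(i,0) += w * gI0; g_col(i,1) += w * gI1; g_col(i,2) += w * gI2;
        g_tzacc[i] += w * gDr;
        g_ncam[3*i]   += w * gNr0;
        g_ncam[3*i+1] += w * gNr1;
        g_ncam[3*i+2] += w * gNr2;
        double galpha = ui * Tk - S / (1.0 - a);
        S += ui * w;
        if (a >= ALPHA_MAX) continue;  // clamped: no gradient through alpha
        // alpha = o * exp(power)
        double G = a / P.opa[i];
        g_o[i] += galpha * G;
        double ge = galpha * a;  // d alpha/d power = alpha
        double dx = x - P.u[i], dy = y - P.v[i];
        // power = -0.5(qa dx^2 + qc dy^2) - qb dx dy ; d = pix - mean
        gm_u[i] += ge * (P.qa[i]*dx + P.qb[i]*dy);
        gm_v[i] += ge * (P.qc[i]*dy + P.qb[i]*dx);
        gQa[i] += ge * (-0.5*dx*dx);
        gQc[i] += ge * (-0.5*dy*dy);
        gQb[i] += ge * (-dx*dy);
      }
    }
  }
  // per-gaussian chain to parameters
  double R00=Wp(0,0),R01=Wp(0,1),R02=Wp(0,2),
         R10=Wp(1,0),R11=Wp(1,1),R12=Wp(1,2),
         R20=Wp(2,0),R21=Wp(2,1),R22=Wp(2,2);
  for (size_t kk = 0; kk < P.keep.size(); ++kk) {
    int i = P.keep[kk];
    double o = P.opa[i];
    g_logit[i] = g_o[i] * o * (1.0 - o);
    // conic -> 2D covariance
    double c00, c01, c11;
    {
      // rebuild covariance from Jb
      const double* Jb = &P.Jb[6*i];
      c00 = Jb[0]*Jb[0]+Jb[1]*Jb[1]+Jb[2]*Jb[2] + DILATION;
      c01 = Jb[0]*Jb[3]+Jb[1]*Jb[4]+Jb[2]*Jb[5];
      c11 = Jb[3]*Jb[3]+Jb[4]*Jb[4]+Jb[5]*Jb[5] + DILATION;
    }
    double det = c00*c11 - c01*c01;
    double qa = c11/det, qb = -c01/det, qc = c00/det;
    // Qbar (symmetric, off-diagonal split)
    double Q00 = gQa[i], Q01 = 0.5*gQb[i], Q11 = gQc[i];
    // Sigma2bar = -Q Qbar Q
    double M00 = qa*Q00 + qb*Q01, M01 = qa*Q01 + qb*Q11;
    double M10 = qb*Q00 + qc*Q01, M11 = qb*Q01 + qc*Q11;
    double S00 = -(M00*qa + M01*qb);
    double S01 = -(M00*qb + M01*qc);
    double S10 = -(M10*qa + M11*qb);
    double S11 = -(M10*qb + M11*qc);
    // symmetrize (should already be)
    double sym01 = 0.5*(S01+S10);
    S01 = sym01; S10 = sym01;
    // Jbbar = 2 Sigma2bar Jb   (2x3)
    const double* Jb = &P.Jb[6*i];
    double Jbb[6];
    Jbb[0] = 2*(S00*Jb[0] + S01*Jb[3]);
    Jbb[1] = 2*(S00*Jb[1] + S01*Jb[4]);
    Jbb[2] = 2*(S00*Jb[2] + S01*Jb[5]);
    Jbb[3] = 2*(S10*Jb[0] + S11*Jb[3]);
    Jbb[4] = 2*(S10*Jb[1] + S11*Jb[4]);
    Jbb[5] = 2*(S10*Jb[2] + S11*Jb[5]);
    // J entries
    double tx_ = P.tx[i], ty_ = P.ty[i], tz_ = P.tz[i];
    double J00 = fx/tz_, J02 = -fx*tx_/(tz_*tz_);
    double J11 = fy/tz_, J12 = -fy*ty_/(tz_*tz_);
    // B = A diag(s); rebuild B
    const double* Aa = &P.A[9*i];
    double s[3] = { P.s0[i], P.s1[i], P.s2[i] };
    double B[9] = { Aa[0]*s[0], Aa[1]*s[1], Aa[2]*s[2],
                    Aa[3]*s[0], Aa[4]*s[1], Aa[5]*s[2],
                    Aa[6]*s[0], Aa[7]*s[1], Aa[8]*s[2] };
    // Jbar = Jbbar B^T (2x3); Bbar = J^T Jbbar (3x3)
    // J has structure [[J00,0,J02],[0,J11,J12]]
    double Jbar00 = Jbb[0]*B[0] + Jbb[1]*B[1] + Jbb[2]*B[2];
    double Jbar02 = Jbb[0]*B[6] + Jbb[1]*B[7] + Jbb[2]*B[8];
    double Jbar11 = Jbb[3]*B[3] + Jbb[4]*B[4] + Jbb[5]*B[5];
    double Jbar12 = Jbb[3]*B[6] + Jbb[4]*B[7] + Jbb[5]*B[8];
    double Bb[9];
    Bb[0] = J00*Jbb[0];            Bb[1] = J00*Jbb[1];            Bb[2] = J00*Jbb[2];
    Bb[3] = J11*Jbb[3];            Bb[4] = J11*Jbb[4];            Bb[5] = J11*Jbb[5];
    Bb[6] = J02*Jbb[0] + J12*Jbb[3]; Bb[7] = J02*Jbb[1] + J12*Jbb[4]; Bb[8] = J02*Jbb[2] + J12*Jbb[5];
    // Abar = Bbar diag(s); sbar_k = sum_r Bbar[r,k] * A[r,k]
    double Ab[9];
    for (int r = 0; r < 3; ++r)
      for (int c = 0; c < 3; ++c) Ab[3*r+c] = Bb[3*r+c] * s[c];
    double sbar[3];
    for (int c = 0; c < 3; ++c)
      sbar[c] = Bb[c]*Aa[c] + Bb[3+c]*Aa[3+c] + Bb[6+c]*Aa[6+c];
    // normal path: ncam = flip * A[, kmin]
    int km = P.kmin[i]; double fl = P.flip[i];
    Ab[km]   += fl * g_ncam[3*i];
    Ab[3+km] += fl * g_ncam[3*i+1];
    Ab[6+km] += fl * g_ncam[3*i+2];
    // log-scale gradient
    g_ls(i,0) = sbar[0]*s[0]; g_ls(i,1) = sbar[1]*s[1]; g_ls(i,2) = sbar[2]*s[2];
    // R3bar = Wpose^T Abar
    double Rb[9];
    Rb[0]=R00*Ab[0]+R10*Ab[3]+R20*Ab[6]; Rb[1]=R00*Ab[1]+R10*Ab[4]+R20*Ab[7]; Rb[2]=R00*Ab[2]+R10*Ab[5]+R20*Ab[8];
    Rb[3]=R01*Ab[0]+R11*Ab[3]+R21*Ab[6]; Rb[4]=R01*Ab[1]+R11*Ab[4]+R21*Ab[7]; Rb[5]=R01*Ab[2]+R11*Ab[5]+R21*Ab[8];
    Rb[6]=R02*Ab[0]+R12*Ab[3]+R22*Ab[6]; Rb[7]=R02*Ab[1]+R12*Ab[4]+R22*Ab[7]; Rb[8]=R02*Ab[2]+R12*Ab[5]+R22*Ab[8];
    // quaternion gradient (through normalization)
    double qw = quats(i,0), qx = quats(i,1), qy = quats(i,2), qz = quats(i,3);
    double qn = std::sqrt(qw*qw + qx*qx + qy*qy + qz*qz);
    double w_ = qw/qn, x_ = qx/qn, y_ = qy/qn, z_ = qz/qn;
    // dR/dq for unit quaternion
    double dRw[9] = { 0, -2*z_, 2*y_,  2*z_, 0, -2*x_,  -2*y_, 2*x_, 0 };
    double dRx[9] = { 0, 2*y_, 2*z_,  2*y_, -4*x_, -2*w_,  2*z_, 2*w_, -4*x_ };
    double dRy[9] = { -4*y_, 2*x_, 2*w_,  2*x_, 0, 2*z_,  -2*w_, 2*z_, -4*y_ };
    double dRz[9] = { -4*z_, -2*w_, 2*x_,  2*w_, -4*z_, 2*y_,  2*x_, 2*y_, 0 };
    double gq_unit[4] = {0,0,0,0};
    for (int k = 0; k < 9; ++k) {
      gq_unit[0] += Rb[k]*dRw[k];
      gq_unit[1] += Rb[k]*dRx[k];
      gq_unit[2] += Rb[k]*dRy[k];
      gq_unit[3] += Rb[k]*dRz[k];
    }
    double qu[4] = { w_, x_, y_, z_ };
    double dotq = gq_unit[0]*qu[0] + gq_unit[1]*qu[1] + gq_unit[2]*qu[2] + gq_unit[3]*qu[3];
    for (int k = 0; k < 4; ++k) g_q(i,k) = (gq_unit[k] - dotq*qu[k]) / qn;
    // position gradient: mean2 path + J(t) path + depth channel
    double gt0 = J00*gm_u[i];
    double gt1 = J11*gm_v[i];
    double gt2 = J02*gm_u[i] + J12*gm_v[i] + g_tzacc[i];
    // dJ/dt
    gt0 += Jbar02 * (-fx/(tz_*tz_));
    gt1 += Jbar12 * (-fy/(tz_*tz_));
    gt2 += Jbar00 * (-fx/(tz_*tz_)) + Jbar11 * (-fy/(tz_*tz_))
         + Jbar02 * (2*fx*tx_/(tz_*tz_*tz_)) + Jbar12 * (2*fy*ty_/(tz_*tz_*tz_));
    g_xyz(i,0) = R00*gt0 + R10*gt1 + R20*gt2;
    g_xyz(i,1) = R01*gt0 + R11*gt1 + R21*gt2;
    g_xyz(i,2) = R02*gt0 + R12*gt1 + R22*gt2;
  }
  return List::create(_["positions"] = g_xyz, _["log_scales"] = g_ls,
                      _["rotations"] = g_q, _["opacity_logits"] = g_logit,
                      _["colors"] = g_col);
}
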