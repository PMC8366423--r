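#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Minimal complex value type with naive arithmetic. SLDs are real, so
// every normal wavevector is either purely real or purely imaginary and
// all transcendentals reduce to real exp/cos/sin; a hand-rolled type
// avoids the checked complex multiplication and complex exp/sqrt of the
// standard library in this hot loop.
struct cplx {
  double re, im;
};

static inline cplx cadd(cplx a, cplx b) { return {a.re + b.re, a.im + b.im}; }
static inline cplx csub(cplx a, cplx b) { return {a.re - b.re, a.im - b.im}; }
static inline cplx cmul(cplx a, cplx b) {
  return {a.re * b.re - a.im * b.im, a.re * b.im + a.im * b.re};
}
static inline cplx cdiv(cplx a, cplx b) {
  const double d = b.re * b.re + b.im * b.im;
  return {(a.re * b.re + a.im * b.im) / d,
          (a.im * b.re - a.re * b.im) / d};
}
// exp(z) for general z
static inline cplx cexp_(cplx z) {
  const double m = std::exp(z.re);
  if (z.im == 0.0) return {m, 0.0};
  return {m * std::cos(z.im), m * std::sin(z.im)};
}

// Specular reflectivity of a stratified medium by the Abeles
// characteristic-matrix recursion with Nevot-Croce roughness damping.
//
// sld:       length n+2, media SLDs (A^-2), fronting first, backing last
// thickness: length n+2; entries 1..n are layer thicknesses (A)
// roughness: length n+1; roughness[i] belongs to the interface between
//            medium i and medium i+1
//
// k_m = sqrt((Q/2)^2 - 4 pi (sld_m - sld_fronting)) (principal root, so
// evanescent media below the critical edge get k = i|k|), Fresnel
// coefficients damped by exp(-2 k_m k_{m+1} sigma^2), matrices multiplied
// fronting -> backing, r = |M10/M00|^2.
// [[Rcpp::export(name = ".abeles_cpp")]]
NumericVector abeles_cpp(NumericVector q, NumericVector sld,
                         NumericVector thickness, NumericVector roughness) {
  const int nq = q.size();
  const int nmedia = sld.size();
  const int nint = nmedia - 1;
  if (thickness.size() != nmedia)
    stop("thickness must have one entry per medium");
  if (roughness.size() != nint)
    stop("roughness must have one entry per interface");

  NumericVector out(nq);
  std::vector<double> four_pi_drho(nmedia);
  for (int m = 0; m < nmedia; ++m)
    four_pi_drho[m] = 4.0 * M_PI * (sld[m] - sld[0]);

  std::vector<cplx> k(nmedia);
  for (int iq = 0; iq < nq; ++iq) {
    const double q2 = 0.5 * q[iq];
    const double q2sq = q2 * q2;
    for (int m = 0; m < nmedia; ++m) {
      const double arg = q2sq - four_pi_drho[m];
      if (arg >= 0.0) k[m] = {std::sqrt(arg), 0.0};
      else            k[m] = {0.0, std::sqrt(-arg)};
    }

    cplx M00 = {1.0, 0.0}, M01 = {0.0, 0.0},
         M10 = {0.0, 0.0}, M11 = {1.0, 0.0};
    for (int i = 0; i < nint; ++i) {
      cplx rf = cdiv(csub(k[i], k[i + 1]), cadd(k[i], k[i + 1]));
      const double sig = roughness[i];
      if (sig > 0.0) {
        // -2 k_i k_{i+1} sigma^2; each k is real or imaginary, so the
        // product needs no special casing beyond cmul
        cplx damp = cmul(k[i], k[i + 1]);
        damp.re *= -2.0 * sig * sig;
        damp.im *= -2.0 * sig * sig;
        rf = cmul(rf, cexp_(damp));
      }
      cplx C00, C01, C10, C11;
      if (i > 0) {
        // beta = i k_i d_i; exp(+beta), exp(-beta)
        const cplx beta = {-k[i].im * thickness[i], k[i].re * thickness[i]};
        const cplx ep = cexp_(beta);
        const cplx em = cexp_({-beta.re, -beta.im});
        C00 = ep;          C01 = cmul(rf, ep);
        C10 = cmul(rf, em); C11 = em;
      } else {
        C00 = {1.0, 0.0}; C01 = rf;
        C10 = rf;         C11 = {1.0, 0.0};
      }
      const cplx n00 = cadd(cmul(M00, C00), cmul(M01, C10));
      const cplx n01 = cadd(cmul(M00, C01), cmul(M01, C11));
      const cplx n10 = cadd(cmul(M10, C00), cmul(M11, C10));
      const cplx n11 = cadd(cmul(M10, C01), cmul(M11, C11));
      M00 = n00; M01 = n01; M10 = n10; M11 = n11;
    }

    const cplx amp = cdiv(M10, M00);
    double r = amp.re * amp.re + amp.im * amp.im;
    if (r > 1.0) r = 1.0;  // clip rounding excursions at total reflection
    out[iq] = r;
  }
  return out;
}
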