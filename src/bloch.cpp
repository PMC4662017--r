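#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Gyromagnetic ratio of 1H, rad s^-1 T^-1 (gamma-bar = 42.577478518 MHz/T)
static const double GAMMA = 2.0 * M_PI * 42.577478518e6;

// Event table layout (columns of the events matrix):
//   0 dur_s      event duration in seconds (> 0)
//   1 rf_uT     RF amplitude in microtesla
//   2 phase_rad  RF phase
//   3 grad_mTm   slice-axis gradient in mT/m
//   4 crusher    1 = ideal crusher (zero transverse, no rotation)
//   5 adc        0 = none, k>0 = sample image k at the END of this event
enum { COL_DUR = 0, COL_RF, COL_PH, COL_GRAD, COL_CRUSH, COL_ADC };

struct Mag { double x, y, z; };

// Rotate m about the angular-velocity vector w (rad/s) for dur seconds.
// Bloch precession dM/dt = -w x M, i.e. rotation by angle -|w|*dur about w/|w|.
static inline void rotate(Mag &m, double wx, double wy, double wz, double dur) {
    double w2 = wx * wx + wy * wy + wz * wz;
    if (w2 <= 0.0) return;
    double w = std::sqrt(w2);
    double nx = wx / w, ny = wy / w, nz = wz / w;
    double th = -w * dur;
    double c = std::cos(th), s = std::sin(th), onec = 1.0 - c;
    double dot = nx * m.x + ny * m.y + nz * m.z;
    double cx = ny * m.z - nz * m.y;
    double cy = nz * m.x - nx * m.z;
    double cz = nx * m.y - ny * m.x;
    double mx = m.x * c + cx * s + nx * dot * onec;
    double my = m.y * c + cy * s + ny * dot * onec;
    double mz = m.z * c + cz * s + nz * dot * onec;
    m.x = mx; m.y = my; m.z = mz;
}

// Propagate one isochromat through the whole event table.
// samples (length n_images, may be 0) receives mx + i*my at each ADC marker.
// Returns final magnetization. Throws on NaN with the 1-based step index.
static Mag propagate(const NumericMatrix &ev, double z_m, double t1_s, double t2_s,
                     double off_hz, double eq, Mag m, bool relax,
                     std::complex<double> *samples) {
    int n = ev.nrow();
    double w_off = 2.0 * M_PI * off_hz;
    for (int i = 0; i < n; ++i) {
        double dur = ev(i, COL_DUR);
        if (ev(i, COL_CRUSH) != 0.0) {
            m.x = 0.0; m.y = 0.0;
            if (relax) m.z = eq + (m.z - eq) * std::exp(-dur / t1_s);
        } else {
            double b1 = ev(i, COL_RF) * 1e-6;
            double wz = GAMMA * ev(i, COL_GRAD) * 1e-3 * z_m + w_off;
            if (b1 != 0.0 || wz != 0.0) {
                double ph = ev(i, COL_PH);
                rotate(m, GAMMA * b1 * std::cos(ph), GAMMA * b1 * std::sin(ph), wz, dur);
            }
            if (relax) {
                double e2 = std::exp(-dur / t2_s);
                m.x *= e2; m.y *= e2;
                m.z = eq + (m.z - eq) * std::exp(-dur / t1_s);
            }
        }
        if (!(std::isfinite(m.x) && std::isfinite(m.y) && std::isfinite(m.z)))
            stop("Bloch propagation produced a non-finite magnetization at step %d", i + 1);
        int adc = (int) ev(i, COL_ADC);
        if (adc > 0 && samples != nullptr)
            samples[adc - 1] = std::complex<double>(m.x, m.y);
    }
    return m;
}

// [[Rcpp::export]]
List bloch_propagate_cpp(NumericMatrix events, double z_m, double t1_ms, double t2_ms,
                         double off_hz, double eq, NumericVector m_init,
                         bool relax, int n_images) {
    std::vector< std::complex<double> > buf(std::max(n_images, 0),
                                            std::complex<double>(0.0, 0.0));
    Mag m = { m_init[0], m_init[1], m_init[2] };
    m = propagate(events, z_m, t1_ms * 1e-3, t2_ms * 1e-3, off_hz, eq, m, relax,
                  n_images > 0 ? buf.data() : nullptr);
    ComplexVector samples(n_images);
    for (int k = 0; k < n_images; ++k) {
        samples[k].r = buf[k].real();
        samples[k].i = buf[k].imag();
    }
    return List::create(_["samples"] = samples,
                        _["final"] = NumericVector::create(m.x, m.y, m.z));
}

// Ensemble signal: complex sum over slice positions, one value per image.
// [[Rcpp::export]]
ComplexVector bloch_ensemble_cpp(NumericMatrix events, NumericVector z_m,
                                 double t1_ms, double t2_ms, double off_hz,
                                 bool relax, int n_images) {
    int ns = z_m.size();
    std::vector< std::complex<double> > acc(n_images, std::complex<double>(0.0, 0.0));
    std::vector< std::complex<double> > buf(n_images);
    double t1_s = t1_ms * 1e-3, t2_s = t2_ms * 1e-3;
    for (int s = 0; s < ns; ++s) {
        std::fill(buf.begin(), buf.end(), std::complex<double>(0.0, 0.0));
        Mag m = { 0.0, 0.0, 1.0 };
        propagate(events, z_m[s], t1_s, t2_s, off_hz, 1.0, m, relax, buf.data());
        for (int k = 0; k < n_images; ++k) acc[k] += buf[k];
    }
    ComplexVector out(n_images);
    for (int k = 0; k < n_images; ++k) { out[k].r = acc[k].real(); out[k].i = acc[k].imag(); }
    return out;
}

// Whole-dictionary kernel: for each (T1,T2) pair propagate the full ensemble.
// Returns a complex matrix, entries x images.
// [[Rcpp::export]]
ComplexMatrix bloch_dictionary_cpp(NumericMatrix events, NumericVector z_m,
                                   NumericVector t1_ms, NumericVector t2_ms,
                                   int n_images) {
    int ne = t1_ms.size(), ns = z_m.size();
    ComplexMatrix out(ne, n_images);
    std::vector< std::complex<double> > acc(n_images), buf(n_images);
    for (int e = 0; e < ne; ++e) {
        std::fill(acc.begin(), acc.end(), std::complex<double>(0.0, 0.0));
        double t1_s = t1_ms[e] * 1e-3, t2_s = t2_ms[e] * 1e-3;
        for (int s = 0; s < ns; ++s) {
            std::fill(buf.begin(), buf.end(), std::complex<double>(0.0, 0.0));
            Mag m = { 0.0, 0.0, 1.0 };
            propagate(events, z_m[s], t1_s, t2_s, 0.0, 1.0, m, true, buf.data());
            for (int k = 0; k < n_images; ++k) acc[k] += buf[k];
        }
        for (int k = 0; k < n_images; ++k) { out(e, k).r = acc[k].real(); out(e, k).i = acc[k].imag(); }
        if (e % 256 == 0) Rcpp::checkUserInterrupt();
    }
    return out;
}
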