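#include <Rcpp.h>
using namespace Rcpp;

// Weighted-packet Monte Carlo photon transport in a homogeneous turbid
// medium, MCML-style: exponential free paths with mu_t = mu_a + mu_s, a
// weight deposit of w * mu_a / mu_t at every interaction, Henyey-Greenstein
// direction updates, and Russian roulette below a weight threshold.  The
// fluence tally is the deposited weight per voxel of an axis-aligned box;
// packets terminate by absorption, roulette, or leaving the box (the face
// crossed first classifies the exit as transmitted / reflected / side).
//
// Uses R's RNG (RNGScope), so set.seed() on the R side makes runs
// reproducible bit-for-bit.

static inline double hg_cos(double g) {
  double u = unif_rand();
  if (std::fabs(g) < 1e-8) return 2.0 * u - 1.0;
  double s = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double c = (1.0 + g * g - s * s) / (2.0 * g);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return c;
}

static inline void spin(double &ux, double &uy, double &uz, double g) {
  double ct = hg_cos(g);
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double phi = 2.0 * M_PI * unif_rand();
  double cp = std::cos(phi), sp = std::sin(phi);
  if (std::fabs(uz) > 0.99999) {
    ux = st * cp;
    uy = st * sp;
    uz = ct * (uz >= 0 ? 1.0 : -1.0);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    double nx = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    double ny = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    double nz = -den * st * cp + uz * ct;
    ux = nx; uy = ny; uz = nz;
  }
  double n = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= n; uy /= n; uz /= n;
}

// [[Rcpp::export(name = ".mc_transport_cpp")]]
List mc_transport_cpp(NumericMatrix pos, NumericMatrix dir, NumericVector w0,
                      double mu_a, double mu_s, double g,
                      NumericVector xlim, NumericVector ylim, NumericVector zlim,
                      int nx, int ny, int nz, double voxel,
                      double roulette_threshold, double survival_factor,
                      int max_events) {
  const int n = pos.nrow();
  const double mu_t = mu_a + mu_s;
  NumericVector fluence(static_cast<R_xlen_t>(nx) * ny * nz);
  IntegerVector status(n);          // 0 absorbed/rouletted, 1 z+ exit, 2 z- exit, 3 side
  NumericVector exit_w(n), exit_x(n), exit_y(n), exit_z(n);
  NumericVector exit_ux(n), exit_uy(n), exit_uz(n);
  double absorbed = 0.0, roulette_net = 0.0;

  for (int i = 0; i < n; ++i) {
    double x = pos(i, 0), y = pos(i, 1), z = pos(i, 2);
    double ux = dir(i, 0), uy = dir(i, 1), uz = dir(i, 2);
    double w = w0[i];
    int events = 0;
    status[i] = 0;
    exit_w[i] = 0.0;
    exit_x[i] = NA_REAL; exit_y[i] = NA_REAL; exit_z[i] = NA_REAL;
    exit_ux[i] = NA_REAL; exit_uy[i] = NA_REAL; exit_uz[i] = NA_REAL;

    for (;;) {
      if (++events > max_events)
        stop("photon exceeded the per-packet event budget (tracer bug guard)");
      if (!R_finite(x) || !R_finite(y) || !R_finite(z))
        stop("non-finite photon position (tracer bug guard)");

      double step = (mu_t > 0.0) ? -std::log(unif_rand()) / mu_t
                                 : std::numeric_limits<double>::infinity();

      // distance to the first box face along the current direction
      double t_exit = std::numeric_limits<double>::infinity();
      int face = -1;
      if (ux > 0) { double t = (xlim[1] - x) / ux; if (t < t_exit) { t_exit = t; face = 3; } }
      if (ux < 0) { double t = (xlim[0] - x) / ux; if (t < t_exit) { t_exit = t; face = 3; } }
      if (uy > 0) { double t = (ylim[1] - y) / uy; if (t < t_exit) { t_exit = t; face = 3; } }
      if (uy < 0) { double t = (ylim[0] - y) / uy; if (t < t_exit) { t_exit = t; face = 3; } }
      if (uz > 0) { double t = (zlim[1] - z) / uz; if (t < t_exit) { t_exit = t; face = 1; } }
      if (uz < 0) { double t = (zlim[0] - z) / uz; if (t < t_exit) { t_exit = t; face = 2; } }

      if (step >= t_exit) {          // leaves the box before interacting
        x += t_exit * ux; y += t_exit * uy; z += t_exit * uz;
        status[i] = face;
        exit_w[i] = w;
        exit_x[i] = x; exit_y[i] = y; exit_z[i] = z;
        exit_ux[i] = ux; exit_uy[i] = uy; exit_uz[i] = uz;
        break;
      }

      x += step * ux; y += step * uy; z += step * uz;

      // deposit the absorbed fraction in the voxel of the interaction
      double dw = w * mu_a / mu_t;
      if (dw > 0) {
        int ix = static_cast<int>((x - xlim[0]) / voxel);
        int iy = static_cast<int>((y - ylim[0]) / voxel);
        int iz = static_cast<int>((z - zlim[0]) / voxel);
        if (ix >= 0 && ix < nx && iy >= 0 && iy < ny && iz >= 0 && iz < nz)
          fluence[ix + static_cast<R_xlen_t>(nx) * (iy + static_cast<R_xlen_t>(ny) * iz)] += dw;
        absorbed += dw;
        w -= dw;
      }

      if (w <= 0.0) break;           // fully absorbed (mu_s == 0)
      spin(ux, uy, uz, g);

      if (w < roulette_threshold) {  // Russian roulette, net-weight bookkeeping
        if (unif_rand() < 1.0 / survival_factor) {
          roulette_net -= w * (survival_factor - 1.0);
          w *= survival_factor;
        } else {
          roulette_net += w;
          break;
        }
      }
    }
  }

  return List::create(_["fluence"] = fluence,
                      _["status"] = status,
                      _["exit_w"] = exit_w,
                      _["exit_x"] = exit_x, _["exit_y"] = exit_y,
                      _["exit_z"] = exit_z,
                      _["exit_ux"] = exit_ux, _["exit_uy"] = exit_uy,
                      _["exit_uz"] = exit_uz,
                      _["absorbed"] = absorbed,
                      _["roulette_net"] = roulette_net);
}
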