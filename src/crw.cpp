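#include <Rcpp.h>
using namespace Rcpp;

// Correlated-random-walk stepper shared by the single-fish, social and shoal
// simulators.  All randomness is consumed from pre-drawn standard-normal
// matrices (one column per fish) so that a shoal with zero cohesion is
// bit-identical to the same fish simulated independently under the same
// per-fish seeds.
//
// Per step k (duration dt):
//   speed:   Euler mean-reverting pull toward mu * mult[k], clamped at 0
//   heading: += sigma_h * noise
//            + dt * kappa_wall     * sin(bearing_to_nearest_wall - h)
//            + dt * kappa_social   * social_on[k] * sin(social_angle - h)
//            + dt * kappa_cohesion * sin(bearing_to_other_centroid - h)
//   position: advance v*dt along heading, specular reflection at walls
//
// Arena encoding: type 0 = rectangle with bounds (0, w, 0, hgt) in `bounds`
// (xmin, xmax, ymin, ymax); type 1 = circle centred at origin, bounds[0] = R.

static inline double wrap_angle(double a) {
  return a - 2.0 * M_PI * std::floor((a + M_PI) / (2.0 * M_PI)) ;
}

// [[Rcpp::export]]
List crw_sim_cpp(NumericMatrix noise_v, NumericMatrix noise_h,
                 NumericVector x0, NumericVector y0, NumericVector h0,
                 NumericVector v0,
                 double dt, double mu, double sigma, double tau,
                 double sigma_h,
                 double kappa_wall, double kappa_social, double social_angle,
                 NumericVector social_on, NumericVector mult,
                 double kappa_cohesion,
                 int arena_type, NumericVector bounds) {
  const int n_steps = noise_v.nrow();
  const int n_fish  = noise_v.ncol();
  NumericMatrix X(n_steps + 1, n_fish), Y(n_steps + 1, n_fish);
  std::vector<double> h(n_fish), v(n_fish), x(n_fish), y(n_fish);
  for (int i = 0; i < n_fish; ++i) {
    x[i] = x0[i]; y[i] = y0[i]; h[i] = h0[i]; v[i] = v0[i];
    X(0, i) = x[i]; Y(0, i) = y[i];
  }
  const double xmin = (arena_type == 0) ? bounds[0] : -bounds[0];
  const double xmax = (arena_type == 0) ? bounds[1] :  bounds[0];
  const double ymin = (arena_type == 0) ? bounds[2] : -bounds[0];
  const double ymax = (arena_type == 0) ? bounds[3] :  bounds[0];
  const double R    = bounds[0]; // circle radius when arena_type == 1
  const double sdrive = sigma * std::sqrt(2.0 * dt / tau);

  for (int k = 0; k < n_steps; ++k) {
    double cx = 0.0, cy = 0.0;
    if (kappa_cohesion > 0.0 && n_fish > 1) {
      for (int i = 0; i < n_fish; ++i) { cx += x[i]; cy += y[i]; }
    }
    for (int i = 0; i < n_fish; ++i) {
      // speed: mean reversion toward the (possibly modulated) target
      double target = mu * mult[k];
      v[i] += (target - v[i]) * dt / tau + sdrive * noise_v(k, i);
      if (v[i] < 0.0) v[i] = 0.0;

      // heading: persistence noise + turn biases
      double dh = sigma_h * noise_h(k, i);
      if (kappa_wall > 0.0) {
        double phi;
        if (arena_type == 0) {
          // bearing toward the nearest of the four walls
          double dl = x[i] - xmin, dr = xmax - x[i];
          double db = y[i] - ymin, dtp = ymax - y[i];
          double m = dl; phi = M_PI;            // left wall
          if (dr  < m) { m = dr;  phi = 0.0; }  // right
          if (db  < m) { m = db;  phi = -M_PI / 2.0; } // bottom
          if (dtp < m) { m = dtp; phi =  M_PI / 2.0; } // top
        } else {
          // nearest boundary point of the circle lies radially outward
          phi = std::atan2(y[i], x[i]);
        }
        dh += dt * kappa_wall * std::sin(phi - h[i]);
      }
      if (kappa_social != 0.0 && social_on[k] != 0.0) {
        dh += dt * kappa_social * social_on[k] * std::sin(social_angle - h[i]);
      }
      if (kappa_cohesion > 0.0 && n_fish > 1) {
        double ox = (cx - x[i]) / (n_fish - 1), oy = (cy - y[i]) / (n_fish - 1);
        double d = std::sqrt((ox - x[i]) * (ox - x[i]) + (oy - y[i]) * (oy - y[i]));
        if (d > 1e-9) {
          double phi = std::atan2(oy - y[i], ox - x[i]);
          dh += dt * kappa_cohesion * std::sin(phi - h[i]);
        }
      }
      h[i] = wrap_angle(h[i] + dh);

      // advance and reflect
      double nx = x[i] + v[i] * dt * std::cos(h[i]);
      double ny = y[i] + v[i] * dt * std::sin(h[i]);
      if (arena_type == 0) {
        for (int it = 0; it < 8; ++it) {
          bool ok = true;
          if (nx < xmin) { nx = 2 * xmin - nx; h[i] = wrap_angle(M_PI - h[i]); ok = false; }
          else if (nx > xmax) { nx = 2 * xmax - nx; h[i] = wrap_angle(M_PI - h[i]); ok = false; }
          if (ny < ymin) { ny = 2 * ymin - ny; h[i] = wrap_angle(-h[i]); ok = false; }
          else if (ny > ymax) { ny = 2 * ymax - ny; h[i] = wrap_angle(-h[i]); ok = false; }
          if (ok) break;
        }
        // degenerate fallback (step larger than arena): clamp
        if (nx < xmin) nx = xmin; if (nx > xmax) nx = xmax;
        if (ny < ymin) ny = ymin; if (ny > ymax) ny = ymax;
      } else {
        for (int it = 0; it < 8; ++it) {
          double r = std::sqrt(nx * nx + ny * ny);
          if (r <= R) break;
          // radial mirror about the boundary plus specular heading reflection
          double s = (2.0 * R - r) / r;
          double nxr = nx / r, nyr = ny / r; // outward normal
          nx *= s; ny *= s;
          double hx = std::cos(h[i]), hy = std::sin(h[i]);
          double dot = hx * nxr + hy * nyr;
          hx -= 2.0 * dot * nxr; hy -= 2.0 * dot * nyr;
          h[i] = std::atan2(hy, hx);
        }
        double r = std::sqrt(nx * nx + ny * ny);
        if (r > R) { nx *= R / r; ny *= R / r; }
      }
      x[i] = nx; y[i] = ny;
      X(k + 1, i) = nx; Y(k + 1, i) = ny;
    }
  }
  return List::create(_["x"] = X, _["y"] = Y);
}
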