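#include <Rcpp.h>
using namespace Rcpp;

// Advance a point inside a disc of radius R (centred at origin) by `len`
// along `heading`, reflecting billiard-style off the wall so path length is
// preserved. Updates x, y, heading in place.
static void advance_reflect(double &x, double &y, double &heading,
                            double len, double R) {
  int guard = 0;
  while (len > 1e-12 && guard++ < 64) {
    double dx = std::cos(heading), dy = std::sin(heading);
    double nx = x + len * dx, ny = y + len * dy;
    if (nx * nx + ny * ny <= R * R) { x = nx; y = ny; return; }
    // solve |p + t d| = R for smallest positive t
    double b = x * dx + y * dy;
    double c = x * x + y * y - R * R;
    double disc = b * b - c;
    if (disc < 0) disc = 0;
    double t = -b + std::sqrt(disc);
    if (t < 0) t = 0;
    if (t > len) t = len;
    x += t * dx; y += t * dy;
    len -= t;
    // reflect heading about the tangent at the contact point
    double nrm = std::sqrt(x * x + y * y);
    if (nrm < 1e-12) nrm = 1e-12;
    double ux = x / nrm, uy = y / nrm;          // outward normal
    double dot = dx * ux + dy * uy;
    double rx = dx - 2.0 * dot * ux, ry = dy - 2.0 * dot * uy;
    heading = std::atan2(ry, rx);
    // nudge inward to avoid re-triggering the wall test at the same point
    x = ux * (nrm - 1e-9); y = uy * (nrm - 1e-9);
  }
}

// Spontaneous bout-based walk. One position per frame; bouts within a frame
// interval arrive Poisson with per-frame mean lambda[i]; each bout has an
// independent uniform heading and a shifted-exponential displacement
// min_disp + Exp(mean_excess). Returns per-frame x, y and bout count.
// [[Rcpp::export]]
List cpp_bout_walk(int n_frames, NumericVector lambda, double min_disp,
                   double mean_excess, double x0, double y0, double R) {
  NumericVector x(n_frames), y(n_frames);
  IntegerVector nbout(n_frames);
  double cx = x0, cy = y0;
  RNGScope scope;
  for (int i = 0; i < n_frames; i++) {
    int nb = (lambda[i] > 0) ? R::rpois(lambda[i]) : 0;
    for (int b = 0; b < nb; b++) {
      double heading = R::runif(0.0, 2.0 * M_PI);
      double len = min_disp + R::rexp(mean_excess);
      advance_reflect(cx, cy, heading, len, R);
    }
    x[i] = cx; y[i] = cy; nbout[i] = nb;
  }
  return List::create(_["x"] = x, _["y"] = y, _["n_bouts"] = nbout);
}

// Startle swim path: per-frame step lengths `steps` executed with a
// persistent heading plus Gaussian turn noise, billiard reflection at the
// wall. Returns positions after each step.
// [[Rcpp::export]]
List cpp_swim_path(NumericVector steps, double x0, double y0,
                   double heading0, double turn_sd, double R) {
  int n = steps.size();
  NumericVector x(n), y(n);
  double cx = x0, cy = y0, heading = heading0;
  RNGScope scope;
  for (int i = 0; i < n; i++) {
    if (steps[i] > 0) {
      heading += R::rnorm(0.0, turn_sd);
      advance_reflect(cx, cy, heading, steps[i], R);
    }
    x[i] = cx; y[i] = cy;
  }
  return List::create(_["x"] = x, _["y"] = y);
}
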