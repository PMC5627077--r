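#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double wrap_pi(double a) {
  double t = a + M_PI;
  return t - 2.0 * M_PI * std::floor(t / (2.0 * M_PI)) - M_PI;
}

// Discrete-time kinematic shoal update inside an annulus centred at the
// origin. Per step and fish: a desired direction is the normalised sum of
// alignment (mean neighbour heading within range), attraction (unit vector
// to the neighbour centroid) and a wall term (inward normal ramping up
// within wall_zone of either wall); the heading relaxes toward it by
// turn_rate, is perturbed by wrapped-normal noise, and the fish steps by a
// lognormal speed draw / fps. Positions are reflected at the walls.
// Uses R's RNG: two draws (rnorm, rlnorm) per fish per step, in fish order,
// so trajectories are bit-reproducible under set.seed().
// [[Rcpp::export]]
NumericVector sim_annulus_core(int n_fish, int n_frames,
                               double inner_radius, double outer_radius,
                               double fps,
                               double alignment_weight,
                               double attraction_weight,
                               double wall_weight,
                               double heading_noise_sd,
                               double speed_log_mean, double speed_log_sd,
                               double interaction_range,
                               double turn_rate, double wall_zone,
                               NumericVector init_x, NumericVector init_y,
                               NumericVector init_theta) {
  NumericVector out(Dimension(n_frames, n_fish, 2));
  std::vector<double> x(init_x.begin(), init_x.end());
  std::vector<double> y(init_y.begin(), init_y.end());
  std::vector<double> th(init_theta.begin(), init_theta.end());
  std::vector<double> nx(n_fish), ny(n_fish), nth(n_fish);

  for (int i = 0; i < n_fish; ++i) {
    out[0 + n_frames * i] = x[i];
    out[0 + n_frames * i + n_frames * n_fish] = y[i];
  }

  for (int k = 1; k < n_frames; ++k) {
    for (int i = 0; i < n_fish; ++i) {
      double sum_hx = 0, sum_hy = 0, sum_px = 0, sum_py = 0;
      int cnt = 0;
      for (int j = 0; j < n_fish; ++j) {
        if (j == i) continue;
        double dx = x[j] - x[i], dy = y[j] - y[i];
        double d = std::sqrt(dx * dx + dy * dy);
        if (d <= interaction_range) {
          sum_hx += std::cos(th[j]);
          sum_hy += std::sin(th[j]);
          sum_px += x[j];
          sum_py += y[j];
          ++cnt;
        }
      }
      // social desired direction: own heading (persistence, weight 1)
      // plus alignment with the mean neighbour heading and attraction to
      // the neighbour centroid
      double des_x = std::cos(th[i]), des_y = std::sin(th[i]);
      if (cnt > 0) {
        des_x += alignment_weight * sum_hx / cnt;
        des_y += alignment_weight * sum_hy / cnt;
        // attraction ramps with distance to the neighbour centroid so a
        // spreading group is pulled back together before it fragments,
        // however strong the alignment signal is
        double cx = sum_px / cnt - x[i], cy = sum_py / cnt - y[i];
        double cn = std::sqrt(cx * cx + cy * cy);
        if (cn > 1e-12) {
          double ramp = cn / interaction_range;
          double aw = attraction_weight * (1.0 + alignment_weight) * ramp;
          des_x += aw * cx / cn;
          des_y += aw * cy / cn;
        }
      }
      double theta = th[i];
      double dn = std::sqrt(des_x * des_x + des_y * des_y);
      if (dn > 1e-12) {
        double target = std::atan2(des_y, des_x);
        theta += turn_rate * wrap_pi(target - theta);
      }
      // wall steering overrides social steering as a wall gets close: the
      // target blends the wall-parallel tangent (in the fish's direction of
      // travel) with the escape normal, tilting toward the normal with
      // proximity, so avoidance stays effective however strong the social
      // signals are while an aligned group simply curves along the channel
      double r = std::sqrt(x[i] * x[i] + y[i] * y[i]);
      if (r > 1e-12) {
        double wx = 0, wy = 0, w = 0;
        if (r > outer_radius - wall_zone) {
          w = (r - (outer_radius - wall_zone)) / wall_zone;
          wx = -x[i] / r; wy = -y[i] / r;
        } else if (r < inner_radius + wall_zone) {
          w = ((inner_radius + wall_zone) - r) / wall_zone;
          wx = x[i] / r; wy = y[i] / r;
        }
        if (w > 0) {
          double tx = -y[i] / r, ty = x[i] / r;
          if (tx * std::cos(theta) + ty * std::sin(theta) < 0) {
            tx = -tx; ty = -ty;
          }
          double gx = (1.0 - w) * tx + w * wx;
          double gy = (1.0 - w) * ty + w * wy;
          double lam = wall_weight * w;
          if (lam > 1.0) lam = 1.0;
          theta += lam * wrap_pi(std::atan2(gy, gx) - theta);
        }
      }
      theta += R::rnorm(0.0, heading_noise_sd);
      theta = wrap_pi(theta);
      double speed = R::rlnorm(speed_log_mean, speed_log_sd);
      double step = speed / fps;
      double px = x[i] + step * std::cos(theta);
      double py = y[i] + step * std::sin(theta);
      // reflect at walls; heading mirrors across the local tangent
      double rn = std::sqrt(px * px + py * py);
      if (rn > outer_radius && rn > 1e-12) {
        double rr = 2.0 * outer_radius - rn;
        double psi = std::atan2(py, px);
        px = rr * std::cos(psi);
        py = rr * std::sin(psi);
        theta = wrap_pi(2.0 * psi + M_PI - theta);
        rn = rr;
      }
      if (rn < inner_radius) {
        double psi = std::atan2(py, px);
        double rr = 2.0 * inner_radius - rn;
        px = rr * std::cos(psi);
        py = rr * std::sin(psi);
        theta = wrap_pi(2.0 * psi + M_PI - theta);
        rn = rr;
      }
      if (rn > outer_radius || rn < inner_radius) { // pathological step: clamp
        double psi = std::atan2(py, px);
        double rr = std::min(outer_radius, std::max(inner_radius, rn));
        px = rr * std::cos(psi);
        py = rr * std::sin(psi);
      }
      nx[i] = px; ny[i] = py; nth[i] = theta;
    }
    for (int i = 0; i < n_fish; ++i) {
      x[i] = nx[i]; y[i] = ny[i]; th[i] = nth[i];
      out[k + n_frames * i] = x[i];
      out[k + n_frames * i + n_frames * n_fish] = y[i];
    }
  }
  return out;
}
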