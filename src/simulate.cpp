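#include <Rcpp.h>
using namespace Rcpp;

// Compiled trial simulator. Mirrors the reference R stepper (step_prey)
// phase for phase, consuming R's RNG in the identical draw order: per step,
// n uniform speed draws then n uniform heading draws, in agent order.
// [[Rcpp::export]]
List cpp_simulate(NumericMatrix pos0, NumericVector speed0,
                  NumericMatrix heading0, NumericVector m, int target,
                  int n_steps, double v_e, int burst_steps,
                  double v_star, double phi, double eta,
                  double v_min, double v_max, double turn_limit, double dt) {
  const int n = pos0.nrow();
  const int T = n_steps + 1;
  NumericMatrix X(T, n), Y(T, n), S(T, n), HX(T, n), HY(T, n);

  std::vector<double> px(n), py(n), sp(n), hx(n), hy(n);
  for (int i = 0; i < n; ++i) {
    px[i] = pos0(i, 0); py[i] = pos0(i, 1);
    sp[i] = speed0[i];
    hx[i] = heading0(i, 0); hy[i] = heading0(i, 1);
    X(0, i) = px[i]; Y(0, i) = py[i]; S(0, i) = sp[i];
    HX(0, i) = hx[i]; HY(0, i) = hy[i];
  }

  std::vector<double> w(n * n), wbar(n), vsx(n), vsy(n),
      nsp(n), theta(n), u1(n), u2(n);
  const int tgt = target - 1;
  RNGScope scope;

  for (int t = 1; t <= n_steps; ++t) {
    // pairwise apparent-motion weights from the synchronous time-t state
    if (n > 1) {
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        for (int j = 0; j < n; ++j) {
          if (j == i) { w[j + n * i] = 0.0; continue; }
          double dx = px[j] - px[i], dy = py[j] - py[i];
          double d = std::sqrt(dx * dx + dy * dy);
          double rvx = sp[j] * hx[j] - sp[i] * hx[i];
          double rvy = sp[j] * hy[j] - sp[i] * hy[i];
          double wij = std::sqrt(rvx * rvx + rvy * rvy) / std::max(d, 1.0);
          w[j + n * i] = wij;
          acc += wij;
        }
        wbar[i] = acc / (n - 1);
      }
    }
    for (int i = 0; i < n; ++i) {
      double vx = sp[i] * hx[i], vy = sp[i] * hy[i];
      double ax = 0.0, ay = 0.0;
      int na = 0;
      // attended contribution omega_ji * dir(v_j - v_i) simplifies to
      // (v_j - v_i) / max(d_ij, 1)
      if (n > 1 && wbar[i] > 0.0) {
        for (int j = 0; j < n; ++j) {
          if (j == i) continue;
          double wij = w[j + n * i];
          if (wij / wbar[i] >= m[i]) {
            double ddx = px[j] - px[i], ddy = py[j] - py[i];
            double dcl = std::max(std::sqrt(ddx * ddx + ddy * ddy), 1.0);
            ax += (sp[j] * hx[j] - vx) / dcl;
            ay += (sp[j] * hy[j] - vy) / dcl;
            ++na;
          }
        }
      }
      if (na > 0) { vx += ax / na; vy += ay / na; }
      vsx[i] = vx; vsy[i] = vy;
    }

    // cost-regulated speed and desired heading
    for (int i = 0; i < n; ++i) {
      double s = std::sqrt(vsx[i] * vsx[i] + vsy[i] * vsy[i]);
      double theta_old = std::atan2(hy[i], hx[i]);
      double ns, td;
      if (s > 0.0) {
        double g = phi * (s - v_star) / v_star;
        g = std::min(std::max(g, -0.9), 0.9);
        ns = s * (1.0 - g);
        td = std::atan2(vsy[i], vsx[i]);
      } else {
        double g = phi * (v_min - v_star) / v_star;
        g = std::min(std::max(g, -0.9), 0.9);
        ns = v_min * (1.0 - g);
        td = theta_old;
      }
      nsp[i] = ns; theta[i] = td;
    }

    // noise draws: all speed factors first, then all heading angles
    for (int i = 0; i < n; ++i) u1[i] = unif_rand();
    for (int i = 0; i < n; ++i) u2[i] = unif_rand();
    for (int i = 0; i < n; ++i) {
      double theta_old = std::atan2(hy[i], hx[i]);
      nsp[i] = nsp[i] * (1.0 + eta * (2.0 * u1[i] - 1.0));
      double theta_new = theta[i] + eta * (M_PI / 2.0) * (2.0 * u2[i] - 1.0);
      double delta = std::atan2(std::sin(theta_new - theta_old),
                                std::cos(theta_new - theta_old));
      delta = std::min(std::max(delta, -turn_limit), turn_limit);
      double th = theta_old + delta;
      if (i == tgt && t <= burst_steps && v_e != 1.0) nsp[i] *= v_e;
      nsp[i] = std::min(std::max(nsp[i], v_min), v_max);
      hx[i] = std::cos(th); hy[i] = std::sin(th);
      sp[i] = nsp[i];
      px[i] += sp[i] * hx[i] * dt;
      py[i] += sp[i] * hy[i] * dt;
    }

    // symmetric separation of pairs closer than one body diameter
    for (int i = 0; i < n - 1; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double dx = px[j] - px[i], dy = py[j] - py[i];
        double d = std::sqrt(dx * dx + dy * dy);
        if (d < 1.0) {
          double ux = 1.0, uy = 0.0;
          if (d > 0.0) { ux = dx / d; uy = dy / d; }
          double push = (1.0 - d) / 2.0;
          px[i] -= ux * push; py[i] -= uy * push;
          px[j] += ux * push; py[j] += uy * push;
        }
      }
    }

    for (int i = 0; i < n; ++i) {
      X(t, i) = px[i]; Y(t, i) = py[i]; S(t, i) = sp[i];
      HX(t, i) = hx[i]; HY(t, i) = hy[i];
    }
  }

  return List::create(_["x"] = X, _["y"] = Y, _["speed"] = S,
                      _["hx"] = HX, _["hy"] = HY);
}
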