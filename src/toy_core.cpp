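// Two-variable cubic excitable kernel on a 1D cable: a fast stand-in for the
// ionic model when exercising protocol machinery (activation detection,
// conduction classification, bisection plumbing).
//
//   du/dt = (J_{i+1/2} - J_{i-1/2})/h^2 + k u (u - a)(1 - u) - w
//   dw/dt = eps (b u - w)
//
// Resting state (0, 0); a stimulus sets u = 1 in a region. With the frozen
// parameters the kernel has a stable rest state and supports a propagating
// pulse that can be blocked at an abrupt coupling jump.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List toy_run_cpp(int nx, NumericVector sig, double h, double dt,
                 double duration, NumericVector stim_times,
                 IntegerVector stim_nodes,
                 IntegerVector probe_nodes, double probe_threshold,
                 double probe_debounce,
                 IntegerVector record_sites, double record_stride,
                 double kk, double aa, double eps, double bb) {
  std::vector<double> u(nx, 0.0), w(nx, 0.0), lap(nx, 0.0);
  long nsteps = (long) std::llround(duration / dt);
  double h2inv = 1.0 / (h * h);

  std::vector<long> stim_step(stim_times.size());
  for (int k = 0; k < stim_times.size(); ++k)
    stim_step[k] = (long) std::llround(stim_times[k] / dt);

  std::vector<std::vector<double> > acts(probe_nodes.size());
  std::vector<double> lastu(probe_nodes.size(), 0.0),
      lastact(probe_nodes.size(), -1e9);

  long rec_every = record_stride > 0 ? (long) std::llround(record_stride / dt) : 0;
  std::vector<double> trace_t;
  std::vector<std::vector<double> > traces(record_sites.size());

  for (long step = 0; step < nsteps; ++step) {
    double t = step * dt;
    for (size_t k = 0; k < stim_step.size(); ++k)
      if (stim_step[k] == step)
        for (int q = 0; q < stim_nodes.size(); ++q) u[stim_nodes[q]] = 1.0;

    if (rec_every > 0 && step % rec_every == 0) {
      trace_t.push_back(t);
      for (int k = 0; k < record_sites.size(); ++k)
        traces[k].push_back(u[record_sites[k]]);
    }

    lap[0] = sig[0] * (u[1] - u[0]) * h2inv;
    for (int i = 1; i < nx - 1; ++i)
      lap[i] = (sig[i] * (u[i + 1] - u[i]) - sig[i - 1] * (u[i] - u[i - 1])) * h2inv;
    lap[nx - 1] = -sig[nx - 2] * (u[nx - 1] - u[nx - 2]) * h2inv;

    for (int i = 0; i < nx; ++i) {
      double ui = u[i];
      u[i] = ui + dt * (lap[i] + kk * ui * (ui - aa) * (1.0 - ui) - w[i]);
      w[i] += dt * eps * (bb * ui - w[i]);
    }

    for (int k = 0; k < probe_nodes.size(); ++k) {
      double v = u[probe_nodes[k]];
      if (lastu[k] < probe_threshold && v >= probe_threshold &&
          (t + dt) - lastact[k] > probe_debounce) {
        acts[k].push_back(t + dt);
        lastact[k] = t + dt;
      }
      lastu[k] = v;
    }
  }

  List probe_acts(acts.size());
  for (size_t k = 0; k < acts.size(); ++k) probe_acts[k] = wrap(acts[k]);
  List tr(traces.size());
  for (size_t k = 0; k < traces.size(); ++k) tr[k] = wrap(traces[k]);
  return List::create(_["u"] = wrap(u), _["w"] = wrap(w),
                      _["probe_activations"] = probe_acts,
                      _["trace_times"] = wrap(trace_t), _["traces"] = tr);
}
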