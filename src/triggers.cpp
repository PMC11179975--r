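#include <Rcpp.h>
#include <algorithm>
#include <deque>
#include <vector>
using namespace Rcpp;

namespace {

// Linearly interpolated order statistic at `pct` percent of a sorted vector.
// Matches the R-level percentile_threshold() arithmetic exactly.
double interp_pct(const std::vector<double>& s, double pct) {
  const int n = static_cast<int>(s.size());
  const double h = (n - 1) * (pct / 100.0);
  const int lo = static_cast<int>(std::floor(h));
  if (lo >= n - 1) return s[n - 1];
  return s[lo] + (h - lo) * (s[lo + 1] - s[lo]);
}

// Inverse of the interpolated quantile: the largest rank r (in percent) such
// that the interpolated quantile at r does not exceed v. By monotonicity,
// v > Q(p) implies rank(v) > p, which is what makes the within-buffer
// percentile rank of a triggering value exceed the configured percentile by
// construction.
double inv_quantile_rank(const std::vector<double>& s, double v) {
  const int n = static_cast<int>(s.size());
  if (n == 1) return v >= s[0] ? 100.0 : 0.0;
  if (v < s[0]) return 0.0;
  if (v >= s[n - 1]) return 100.0;
  // number of elements <= v; s[j-1] <= v < s[j]
  const int j = static_cast<int>(std::upper_bound(s.begin(), s.end(), v) -
                                 s.begin());
  const double h = (j - 1) + (v - s[j - 1]) / (s[j] - s[j - 1]);
  return 100.0 * h / (n - 1);
}

// Bounded FIFO whose contents are also kept sorted, so the percentile is an
// O(1) lookup after an O(n) insert/evict (memmove-dominated, fast for the
// 3000-sample capacity used here).
struct RollingBuffer {
  std::vector<double> sorted;
  std::deque<double> fifo;
  size_t cap;
  explicit RollingBuffer(size_t c) : cap(c) {}
  void push(double v) {
    if (fifo.size() == cap) {
      const double old = fifo.front();
      fifo.pop_front();
      sorted.erase(std::lower_bound(sorted.begin(), sorted.end(), old));
    }
    fifo.push_back(v);
    sorted.insert(std::upper_bound(sorted.begin(), sorted.end(), v), v);
  }
  int size() const { return static_cast<int>(fifo.size()); }
};

}  // namespace

// Streaming dynamic-percentile trigger algorithm over a whole session.
// direction_mode: 0 both, 1 positive_only, 2 negative_only, 3 bidirectional.
// Negative-direction buffers store magnitudes so that "exceeds" always means
// strictly greater in the comparison space.
// [[Rcpp::export]]
List run_dynamic_cpp(NumericVector time, NumericVector value,
                     LogicalVector supra, double percentile, int buffer_size,
                     double min_isi, int direction_mode, int min_fill,
                     bool include_subminimum, bool keep_snapshots) {
  const int n = time.size();
  RollingBuffer pos(static_cast<size_t>(buffer_size));
  RollingBuffer neg(static_cast<size_t>(buffer_size));
  bool initiated = false;
  bool has_trig = false;
  double last_trig = 0.0;
  double prev_t = R_NegInf;

  NumericVector thr_pos(n, NA_REAL), thr_neg(n, NA_REAL);
  std::vector<double> ev_time, ev_val, ev_thr, ev_rank;
  std::vector<int> ev_dir;
  List snaps;

  for (int i = 0; i < n; ++i) {
    const double t = time[i];
    const double v = value[i];
    const bool sup = supra[i] == TRUE;
    if (!(t > prev_t)) {
      stop("timestamps must be strictly increasing (sample %d)", i + 1);
    }
    prev_t = t;
    if (sup) initiated = true;

    if (sup || include_subminimum) {
      switch (direction_mode) {
        case 0: pos.push(v); break;
        case 1: if (v > 0) pos.push(v); break;
        case 2: if (v < 0) pos.push(-v); break;
        case 3:
          if (v > 0) pos.push(v);
          else if (v < 0) neg.push(-v);
          break;
      }
    }

    double qp = NA_REAL, qn = NA_REAL;
    if (pos.size() >= min_fill) qp = interp_pct(pos.sorted, percentile);
    if (direction_mode == 3 && neg.size() >= min_fill) {
      qn = interp_pct(neg.sorted, percentile);
    }
    if (direction_mode == 2) {
      thr_neg[i] = ISNAN(qp) ? NA_REAL : -qp;
    } else {
      thr_pos[i] = qp;
      if (direction_mode == 3) thr_neg[i] = ISNAN(qn) ? NA_REAL : -qn;
    }

    const bool isi_ok = !has_trig || (t - last_trig >= min_isi - 1e-9);
    if (initiated && sup && isi_ok) {
      bool fire = false;
      double thr_signed = NA_REAL, cmpv = NA_REAL;
      int dir = 1;
      const std::vector<double>* gov = NULL;
      if (direction_mode == 0) {
        if (!ISNAN(qp) && v > qp) {
          fire = true; thr_signed = qp; cmpv = v;
          dir = (v >= 0) ? 1 : -1; gov = &pos.sorted;
        }
      } else if (direction_mode == 1) {
        if (!ISNAN(qp) && v > 0 && v > qp) {
          fire = true; thr_signed = qp; cmpv = v; dir = 1; gov = &pos.sorted;
        }
      } else if (direction_mode == 2) {
        if (!ISNAN(qp) && v < 0 && -v > qp) {
          fire = true; thr_signed = -qp; cmpv = -v; dir = -1;
          gov = &pos.sorted;
        }
      } else {
        if (!ISNAN(qp) && v > 0 && v > qp) {
          fire = true; thr_signed = qp; cmpv = v; dir = 1; gov = &pos.sorted;
        } else if (!ISNAN(qn) && v < 0 && -v > qn) {
          fire = true; thr_signed = -qn; cmpv = -v; dir = -1;
          gov = &neg.sorted;
        }
      }
      if (fire) {
        has_trig = true;
        last_trig = t;
        ev_time.push_back(t);
        ev_val.push_back(v);
        ev_thr.push_back(thr_signed);
        ev_dir.push_back(dir);
        ev_rank.push_back(inv_quantile_rank(*gov, cmpv));
        if (keep_snapshots) {
          snaps.push_back(NumericVector(gov->begin(), gov->end()));
        }
      }
    }
  }

  return List::create(
      _["time"] = wrap(ev_time), _["paired_value"] = wrap(ev_val),
      _["threshold"] = wrap(ev_thr), _["direction"] = wrap(ev_dir),
      _["buffer_rank"] = wrap(ev_rank), _["threshold_pos"] = thr_pos,
      _["threshold_neg"] = thr_neg, _["snapshots"] = snaps);
}

// Max |value| within +/- halfwidth seconds of each center time; NA when the
// window contains no samples. Times must be sorted ascending.
// [[Rcpp::export]]
NumericVector window_abs_max_cpp(NumericVector time, NumericVector value,
                                 NumericVector centers, double halfwidth) {
  const int n = time.size();
  const int m = centers.size();
  NumericVector out(m, NA_REAL);
  for (int j = 0; j < m; ++j) {
    const double lo = centers[j] - halfwidth;
    const double hi = centers[j] + halfwidth;
    const int i0 = static_cast<int>(
        std::lower_bound(time.begin(), time.end(), lo) - time.begin());
    double best = R_NegInf;
    for (int i = i0; i < n && time[i] <= hi; ++i) {
      const double a = std::fabs(value[i]);
      if (a > best) best = a;
    }
    if (best > R_NegInf) out[j] = best;
  }
  return out;
}
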