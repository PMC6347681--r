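#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Coalescent merge-event engine.
//
// Models: 0 = Kingman (constant N), 1 = Kingman with exponential population
// growth (backward-time intensity (k choose 2) * exp(g * t), i.e.
// N(t) = N0 * exp(-g * t) looking back), 2 = Bolthausen-Sznitman
// multiple-merger coalescent with standard rates: a b-merger (2 <= b <= k)
// occurs at total rate k / (b (b-1)) so the overall merger rate is k - 1 and
// P(b) is proportional to 1 / (b (b-1)); participants chosen uniformly.
// Time is in scaled coalescent units (N = 1).

struct MergeEvent {
    double time;
    std::vector<int> children; // node ids merged at this event
};

// One genealogy as a sequence of merge events over node ids:
// leaves are 0..n-1; the j-th event creates internal node n + j.
static void sim_events(int n, int model, double growth,
                       std::vector<MergeEvent> &events,
                       std::vector<double> &node_time) {
    std::vector<int> active(n);
    for (int i = 0; i < n; ++i) active[i] = i;
    node_time.assign(2 * n - 1, 0.0);
    events.clear();
    double t = 0.0;
    int next_id = n;
    int k = n;
    while (k > 1) {
        int b = 2;
        if (model == 2) { // Bolthausen-Sznitman
            t += R::exp_rand() / (k - 1);
            double U = unif_rand();
            // P(B <= b) = (1 - 1/b) / (1 - 1/k)  =>  invert
            double denom = 1.0 - U * (1.0 - 1.0 / k);
            b = (int)std::ceil(1.0 / denom - 1e-12);
            if (b < 2) b = 2;
            if (b > k) b = k;
        } else if (model == 1) { // exponential growth
            double rate0 = 0.5 * k * (k - 1.0);
            double E = R::exp_rand();
            // solve int_t^{t'} rate0 e^{g s} ds = E
            double y = growth * t;
            double ynew = y + std::log1p(growth * E / rate0 * std::exp(-y));
            t = ynew / growth;
        } else {
            t += R::exp_rand() * 2.0 / (k * (k - 1.0));
        }
        MergeEvent ev;
        ev.time = t;
        ev.children.reserve(b);
        for (int j = 0; j < b; ++j) { // partial Fisher-Yates draw
            int pick = (int)(unif_rand() * (k - j));
            if (pick >= k - j) pick = k - j - 1;
            ev.children.push_back(active[pick]);
            active[pick] = active[k - j - 1];
        }
        k -= b;
        active[k] = next_id;
        node_time[next_id] = t;
        events.push_back(ev);
        ++next_id;
        ++k;
    }
}

// [[Rcpp::export(name = ".coal_sim_cpp")]]
List coal_sim_cpp(int n, int model, double growth) {
    std::vector<MergeEvent> events;
    std::vector<double> node_time;
    sim_events(n, model, growth, events, node_time);
    int m = (int)events.size();       // internal nodes
    int total = n + m;
    IntegerVector parent(total, NA_INTEGER);
    for (int j = 0; j < m; ++j)
        for (int c : events[j].children) parent[c] = n + j;
    NumericVector times(total);
    for (int i = 0; i < total; ++i) times[i] = node_time[i];
    return List::create(_["parent"] = parent, _["time"] = times,
                        _["n"] = n, _["nInternal"] = m);
}

// Allocation-free core for class lengths: runs the merge process over flat
// block arrays, accumulating, per frequency class i, the total branch
// length subtending exactly i leaves. `cls` must have length n - 1.
static void class_lengths_one(int n, int model, double growth, double *cls,
                              std::vector<int> &size,
                              std::vector<double> &birth) {
    size.resize(n);
    birth.resize(n);
    for (int i = 0; i < n; ++i) { size[i] = 1; birth[i] = 0.0; }
    std::fill(cls, cls + (n - 1), 0.0);
    double t = 0.0;
    int k = n;
    while (k > 1) {
        int b = 2;
        if (model == 2) {
            t += R::exp_rand() / (k - 1);
            double U = unif_rand();
            double denom = 1.0 - U * (1.0 - 1.0 / k);
            b = (int)std::ceil(1.0 / denom - 1e-12);
            if (b < 2) b = 2;
            if (b > k) b = k;
        } else if (model == 1) {
            double rate0 = 0.5 * k * (k - 1.0);
            double E = R::exp_rand();
            double y = growth * t;
            t = (y + std::log1p(growth * E / rate0 * std::exp(-y))) / growth;
        } else {
            t += R::exp_rand() * 2.0 / (k * (k - 1.0));
        }
        int merged = 0;
        for (int j = 0; j < b; ++j) { // partial Fisher-Yates draw
            int pick = (int)(unif_rand() * (k - j));
            if (pick >= k - j) pick = k - j - 1;
            int sz = size[pick];
            merged += sz;
            if (sz < n) cls[sz - 1] += t - birth[pick];
            size[pick] = size[k - j - 1];
            birth[pick] = birth[k - j - 1];
        }
        k -= b;
        size[k] = merged;
        birth[k] = t;
        ++k;
    }
}

// Total branch length subtending exactly i leaves (i = 1..n-1), one column
// per replicate.
// [[Rcpp::export(name = ".coal_class_lengths_cpp")]]
NumericMatrix coal_class_lengths_cpp(int n, int reps, int model, double growth) {
    NumericMatrix L(n - 1, reps);
    std::vector<int> size;
    std::vector<double> birth;
    for (int r = 0; r < reps; ++r)
        class_lengths_one(n, model, growth, &L(0, r), size, birth);
    return L;
}

// Null machinery for fixed-S tests: simulate a genealogy, then place exactly
// S mutations on branches with probability proportional to branch length
// (equivalently: multinomial over frequency classes weighted by class
// lengths). Returns the S x reps matrix of derived-allele counts.
// [[Rcpp::export(name = ".coal_null_sites_cpp")]]
IntegerMatrix coal_null_sites_cpp(int n, int S, int reps, int model,
                                  double growth) {
    IntegerMatrix sites(S, reps);
    std::vector<int> size;
    std::vector<double> birth;
    std::vector<double> cum(n - 1);
    for (int r = 0; r < reps; ++r) {
        class_lengths_one(n, model, growth, cum.data(), size, birth);
        for (int i = 1; i < n - 1; ++i) cum[i] += cum[i - 1];
        double tot = cum[n - 2];
        for (int s = 0; s < S; ++s) {
            double u = unif_rand() * tot;
            int lo = (int)(std::upper_bound(cum.begin(), cum.end(), u)
                           - cum.begin());
            if (lo > n - 2) lo = n - 2;
            sites(s, r) = lo + 1; // derived-allele count
        }
    }
    return sites;
}
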