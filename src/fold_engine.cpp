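// Dynamic-programming engine for the nearest-neighbor (NN) and extended
// nearest-neighbor (ENN, triplet) energy models.
//
// Seven constrained arrays are filled over all subintervals [i, j]:
//   Z    all structures                      Zb   structures containing (i,j)
//   Zbb  containing (i,j) and (i+1,j-1)      Zbl  containing (i,j) and (i+2,j-1)
//   Zbr  containing (i,j) and (i+1,j-2)      Zm   inside a multiloop, >=1 branch
//   Zm1  inside a multiloop, exactly one branch anchored at i
// plus the helper Znt = Zb minus its Zbb component (the structures in which
// (i+1,j-1) does NOT pair, i.e. (i,j) closes a loop or stacks across a
// size-1 bulge).
//
// The helix contract shared with the R reference evaluator:
//  * junction (i,j)->(i+1,j-1) where (i+1,j-1) stacks directly onward:
//      triplet energy G3(t(i,j), t(i+1,j-1), t(i+2,j-2))   [NN mode: stack]
//  * junction (i,j)->(i+1,j-1) where (i+1,j-1) terminates (hairpin, loop of
//      size >= 2, multiloop, or a size-1 bulge): NN stack energy
//  * size-1 bulge: bulge(1) + NN stack across the bulge; triplet windows
//      never span a bulge
// Terminal non-GC penalties tau attach at helix ends adjacent to hairpin,
// internal/bulge(>=2), multiloop and exterior loops; never inside a helix
// or at a size-1 bulge.
//
// Three semirings share the fill code: min-plus (MFE), log-sum-exp
// (partition function, numerically safe for n up to several hundred), and
// counting (weights 1, exact in doubles up to 2^53).

#include <Rcpp.h>
#include <cmath>
#include <cfloat>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

enum ArrId { A_Z = 0, A_Zb, A_Zbb, A_Zbl, A_Zbr, A_Znt, A_Zm, A_Zm1, N_ARR };

struct Tables {
  int n, theta, maxInternal;
  std::vector<int> seq;      // 0..3 = A C G U
  std::vector<int> pt;       // pair type code 1..6, 0 = non-canonical
  double stack[6][6];
  double junction[6][6][6];  // helix-continuation term (ENN: triplet; NN: stack)
  double tau[6];             // terminal non-GC closing penalty per pair type
  std::vector<double> hp, bu, il; // loop energies, index = size (1-based)
  double mlA, mlB, mlC;
  double RT;
  bool hasTetra = false;
  std::unordered_map<int, double> tetra; // 6-mer code -> bonus energy

  int ptype(int i, int j) const { return pt[i * n + j]; } // 0-based i, j

  double hairpinE(int i, int j) const {
    int size = j - i - 1;
    double e = hp[size] + tau[ptype(i, j) - 1];
    if (hasTetra && size == 4) {
      int code = 0;
      for (int k = i; k <= j; ++k) code = code * 4 + seq[k];
      auto it = tetra.find(code);
      if (it != tetra.end()) e += it->second;
    }
    return e;
  }
};

static Tables buildTables(const IntegerVector& iseq, const List& tl) {
  Tables t;
  t.n = iseq.size();
  t.seq.assign(iseq.begin(), iseq.end());
  t.theta = as<int>(tl["theta"]);
  t.maxInternal = as<int>(tl["maxInternal"]);
  t.RT = as<double>(tl["RT"]);
  NumericMatrix st = tl["stack"];
  NumericVector ju = tl["junction"]; // 6x6x6, R array layout
  NumericVector ta = tl["tau"];
  NumericVector hp = tl["hairpin"], bu = tl["bulge"], il = tl["internal"];
  t.mlA = as<double>(tl["mlA"]);
  t.mlB = as<double>(tl["mlB"]);
  t.mlC = as<double>(tl["mlC"]);
  for (int x = 0; x < 6; ++x) {
    t.tau[x] = ta[x];
    for (int y = 0; y < 6; ++y) {
      t.stack[x][y] = st(x, y);
      for (int z = 0; z < 6; ++z)
        t.junction[x][y][z] = ju[x + 6 * y + 36 * z];
    }
  }
  t.hp.resize(t.n + 1, R_PosInf);
  t.bu.resize(t.n + 1, R_PosInf);
  t.il.resize(t.n + 1, R_PosInf);
  for (int s = 1; s <= t.n && s <= hp.size(); ++s) {
    t.hp[s] = hp[s - 1];
    t.bu[s] = bu[s - 1];
    t.il[s] = il[s - 1];
  }
  if (tl.containsElementNamed("tetraCodes")) {
    IntegerVector tc = tl["tetraCodes"];
    NumericVector te = tl["tetraE"];
    for (int k = 0; k < tc.size(); ++k) t.tetra[tc[k]] = te[k];
    t.hasTetra = tc.size() > 0;
  }
  // pair-type matrix: AU UA GC CG GU UG -> 1..6  (A=0 C=1 G=2 U=3)
  t.pt.assign((size_t)t.n * t.n, 0);
  auto code = [](int a, int b) {
    if (a == 0 && b == 3) return 1; if (a == 3 && b == 0) return 2;
    if (a == 2 && b == 1) return 3; if (a == 1 && b == 2) return 4;
    if (a == 2 && b == 3) return 5; if (a == 3 && b == 2) return 6;
    return 0;
  };
  for (int i = 0; i < t.n; ++i)
    for (int j = 0; j < t.n; ++j)
      t.pt[i * t.n + j] = code(t.seq[i], t.seq[j]);
  return t;
}

// ---------------------------------------------------------------- semirings

struct MinPlus {
  static double zero() { return R_PosInf; }
  static double one() { return 0.0; }
  static double mul(double a, double b) { return a + b; }
  static double add(double a, double b) { return a < b ? a : b; }
  static double fromE(double e, double) { return e; }
};

struct LogSum {
  static double zero() { return R_NegInf; }
  static double one() { return 0.0; }
  static double mul(double a, double b) { return a + b; }
  static double add(double a, double b) {
    if (a == R_NegInf) return b;
    if (b == R_NegInf) return a;
    double m = a > b ? a : b;
    return m + std::log1p(std::exp((a > b ? b : a) - m));
  }
  static double fromE(double e, double RT) {
    return e == R_PosInf ? R_NegInf : -e / RT;
  }
};

struct Count {
  static double zero() { return 0.0; }
  static double one() { return 1.0; }
  static double mul(double a, double b) { return a * b; }
  static double add(double a, double b) { return a + b; }
  static double fromE(double e, double) { return e == R_PosInf ? 0.0 : 1.0; }
};

// ------------------------------------------------------------------- engine

struct Sub { int arr, i, j; };
struct Branch {
  double sc;
  int ns = 0, np = 0;
  Sub sub[2];
  int pi = 0, pj = 0; // pair recorded when this branch is taken
  void addSub(int a, int i, int j) { sub[ns].arr = a; sub[ns].i = i; sub[ns].j = j; ++ns; }
  void setPair(int i, int j) { np = 1; pi = i; pj = j; }
};

template <class SR>
struct Engine {
  const Tables& t;
  int n;
  std::vector<double> M[N_ARR];

  explicit Engine(const Tables& tab) : t(tab), n(tab.n) {
    for (int a = 0; a < N_ARR; ++a) M[a].assign((size_t)n * n, SR::zero());
  }

  double get(int a, int i, int j) const {
    if (a == A_Z) {
      if (j < i) return SR::one();          // empty interval
      if (j - i <= t.theta) return SR::one(); // only the empty structure
    }
    if (i < 0 || j >= n || j < i) return SR::zero();
    return M[a][(size_t)i * n + j];
  }
  void set(int a, int i, int j, double v) { M[a][(size_t)i * n + j] = v; }

  double w(double e) const { return SR::fromE(e, t.RT); }

  // Branch lists.  Order within each list is the deterministic tie-break
  // order used by the MFE traceback.
  void branchesZbb(int i, int j, std::vector<Branch>& out) const {
    int x = t.ptype(i, j), y = t.ptype(i + 1, j - 1);
    if (!x || !y || (j - 1) - (i + 1) <= t.theta) return;
    int z = (i + 2 < j - 2) ? t.ptype(i + 2, j - 2) : 0;
    if (z) { // helix continues: triplet window (i,j),(i+1,j-1),(i+2,j-2)
      Branch b;
      b.sc = SR::mul(w(t.junction[x - 1][y - 1][z - 1]), get(A_Zbb, i + 1, j - 1));
      b.addSub(A_Zbb, i + 1, j - 1);
      b.setPair(i + 1, j - 1);
      out.push_back(b);
    }
    { // (i+1,j-1) terminates the helix: NN stack at the stem end
      Branch b;
      b.sc = SR::mul(w(t.stack[x - 1][y - 1]), get(A_Znt, i + 1, j - 1));
      b.addSub(A_Znt, i + 1, j - 1);
      b.setPair(i + 1, j - 1);
      out.push_back(b);
    }
  }

  void branchesZbl(int i, int j, std::vector<Branch>& out) const {
    int x = t.ptype(i, j);
    int y = (i + 2 < j - 1) ? t.ptype(i + 2, j - 1) : 0;
    if (!x || !y || (j - 1) - (i + 2) <= t.theta) return;
    Branch b; // size-1 left bulge: penalty + NN stack across the bulge
    b.sc = SR::mul(w(t.bu[1] + t.stack[x - 1][y - 1]), get(A_Zb, i + 2, j - 1));
    b.addSub(A_Zb, i + 2, j - 1);
    b.setPair(i + 2, j - 1);
    out.push_back(b);
  }

  void branchesZbr(int i, int j, std::vector<Branch>& out) const {
    int x = t.ptype(i, j);
    int y = (i + 1 < j - 2) ? t.ptype(i + 1, j - 2) : 0;
    if (!x || !y || (j - 2) - (i + 1) <= t.theta) return;
    Branch b;
    b.sc = SR::mul(w(t.bu[1] + t.stack[x - 1][y - 1]), get(A_Zb, i + 1, j - 2));
    b.addSub(A_Zb, i + 1, j - 2);
    b.setPair(i + 1, j - 2);
    out.push_back(b);
  }

  void branchesHairpin(int i, int j, std::vector<Branch>& out) const {
    Branch b;
    b.sc = w(t.hairpinE(i, j));
    out.push_back(b);
  }

  // internal loops and bulges of total size >= 2, by increasing size then
  // increasing 5' gap (leftmost decomposition first)
  void branchesIL(int i, int j, std::vector<Branch>& out) const {
    int x = t.ptype(i, j);
    int maxSize = std::min(t.maxInternal, j - i - 2 - (t.theta + 1));
    for (int size = 2; size <= maxSize; ++size) {
      for (int n1 = 0; n1 <= size; ++n1) {
        int n2 = size - n1;
        int k = i + n1 + 1, l = j - n2 - 1;
        if (l - k <= t.theta) continue;
        int y = t.ptype(k, l);
        if (!y) continue;
        double eloop = (n1 == 0 || n2 == 0) ? t.bu[size] : t.il[size];
        Branch b;
        b.sc = SR::mul(w(eloop + t.tau[x - 1] + t.tau[y - 1]), get(A_Zb, k, l));
        b.addSub(A_Zb, k, l);
        b.setPair(k, l);
        out.push_back(b);
      }
    }
  }

  // multiloop closed by (i,j), decomposed on the start k of the last branch
  void branchesML(int i, int j, std::vector<Branch>& out) const {
    int x = t.ptype(i, j);
    for (int k = i + 2; k <= j - 2; ++k) {
      double left = get(A_Zm, i + 1, k - 1);
      double right = get(A_Zm1, k, j - 1);
      if (left == SR::zero() || right == SR::zero()) continue;
      Branch b;
      b.sc = SR::mul(w(t.mlA + t.mlB + t.tau[x - 1]), SR::mul(left, right));
      b.addSub(A_Zm, i + 1, k - 1);
      b.addSub(A_Zm1, k, j - 1);
      out.push_back(b);
    }
  }

  // loop-closing branches (hairpin, size-1 bulges, internal/bulge >= 2,
  // multiloop): everything except the direct-stack continuation
  void branchesZnt(int i, int j, std::vector<Branch>& out) const {
    int x = t.ptype(i, j);
    if (!x || j - i <= t.theta) return;
    branchesHairpin(i, j, out);
    branchesZbl(i, j, out);
    branchesZbr(i, j, out);
    branchesIL(i, j, out);
    branchesML(i, j, out);
  }

  // flattened Zb branch list, deterministic tie-break order: hairpin,
  // triplet extension, size-1 bulges, NN stack at the stem end,
  // internal/bulge by increasing size, multiloop
  void branchesZb(int i, int j, std::vector<Branch>& out) const {
    int x = t.ptype(i, j);
    if (!x || j - i <= t.theta) return;
    branchesHairpin(i, j, out);
    std::vector<Branch> bb;
    branchesZbb(i, j, bb); // [triplet?, terminal stack]
    if (bb.size() == 2) out.push_back(bb[0]);
    branchesZbl(i, j, out);
    branchesZbr(i, j, out);
    if (!bb.empty()) out.push_back(bb.back());
    branchesIL(i, j, out);
    branchesML(i, j, out);
  }

  void branchesZm1(int i, int j, std::vector<Branch>& out) const {
    for (int k = i + t.theta + 1; k <= j; ++k) {
      int x = t.ptype(i, k);
      if (!x) continue;
      double zb = get(A_Zb, i, k);
      if (zb == SR::zero()) continue;
      Branch b;
      b.sc = SR::mul(w(t.mlB + t.tau[x - 1] + t.mlC * (j - k)), zb);
      b.addSub(A_Zb, i, k);
      b.setPair(i, k);
      out.push_back(b);
    }
  }

  void branchesZm(int i, int j, std::vector<Branch>& out) const {
    // decompose on the start k of the last branch
    for (int k = i; k <= j - t.theta - 1; ++k) {
      double z1 = get(A_Zm1, k, j);
      if (z1 == SR::zero()) continue;
      { // everything before k unpaired
        Branch b;
        b.sc = SR::mul(w(t.mlC * (k - i)), z1);
        b.addSub(A_Zm1, k, j);
        out.push_back(b);
      }
      if (k > i) { // at least one branch before k
        double left = get(A_Zm, i, k - 1);
        if (left != SR::zero()) {
          Branch b;
          b.sc = SR::mul(left, z1);
          b.addSub(A_Zm, i, k - 1);
          b.addSub(A_Zm1, k, j);
          out.push_back(b);
        }
      }
    }
  }

  void branchesZ(int i, int j, std::vector<Branch>& out) const {
    { // j unpaired
      Branch b;
      b.sc = get(A_Z, i, j - 1);
      if (j - 1 >= i) b.addSub(A_Z, i, j - 1);
      out.push_back(b);
    }
    for (int k = i; k <= j - t.theta - 1; ++k) { // j paired with k
      int x = t.ptype(k, j);
      if (!x) continue;
      double zb = get(A_Zb, k, j);
      if (zb == SR::zero()) continue;
      Branch b;
      b.sc = SR::mul(w(t.tau[x - 1]), zb);
      b.addSub(A_Zb, k, j);
      if (k > i) {
        b.sc = SR::mul(get(A_Z, i, k - 1), b.sc);
        b.addSub(A_Z, i, k - 1);
      }
      b.setPair(k, j);
      out.push_back(b);
    }
  }

  void branches(int a, int i, int j, std::vector<Branch>& out) const {
    out.clear();
    switch (a) {
      case A_Z: branchesZ(i, j, out); break;
      case A_Zb: branchesZb(i, j, out); break;
      case A_Zbb: branchesZbb(i, j, out); break;
      case A_Zbl: branchesZbl(i, j, out); break;
      case A_Zbr: branchesZbr(i, j, out); break;
      case A_Znt: branchesZnt(i, j, out); break;
      case A_Zm: branchesZm(i, j, out); break;
      case A_Zm1: branchesZm1(i, j, out); break;
    }
  }

  double reduce(const std::vector<Branch>& br) const {
    double v = SR::zero();
    for (const Branch& b : br) v = SR::add(v, b.sc);
    return v;
  }

  void fill() {
    std::vector<Branch> br;
    for (int span = 1; span <= n; ++span) {
      for (int i = 0; i + span - 1 < n; ++i) {
        int j = i + span - 1;
        if (span <= t.theta + 1) {
          set(A_Z, i, j, SR::one());
          continue;
        }
        branches(A_Zbb, i, j, br); set(A_Zbb, i, j, reduce(br));
        branches(A_Zbl, i, j, br); set(A_Zbl, i, j, reduce(br));
        branches(A_Zbr, i, j, br); set(A_Zbr, i, j, reduce(br));
        branches(A_Znt, i, j, br); set(A_Znt, i, j, reduce(br));
        set(A_Zb, i, j, SR::add(get(A_Zbb, i, j), get(A_Znt, i, j)));
        branches(A_Zm1, i, j, br); set(A_Zm1, i, j, reduce(br));
        branches(A_Zm, i, j, br); set(A_Zm, i, j, reduce(br));
        branches(A_Z, i, j, br); set(A_Z, i, j, reduce(br));
      }
    }
  }

  List asList() const {
    const char* nm[N_ARR] = {"Z", "Zb", "Zbb", "Zbl", "Zbr", "Znt", "Zm", "Zm1"};
    List out(N_ARR);
    CharacterVector names(N_ARR);
    for (int a = 0; a < N_ARR; ++a) {
      NumericMatrix m(n, n);
      for (int i = 0; i < n; ++i)
        for (int j = 0; j < n; ++j)
          m(i, j) = (j >= i) ? get(a, i, j) : SR::zero();
      out[a] = m;
      names[a] = nm[a];
    }
    out.attr("names") = names;
    return out;
  }

  void fromList(const List& arrays) {
    const char* nm[N_ARR] = {"Z", "Zb", "Zbb", "Zbl", "Zbr", "Znt", "Zm", "Zm1"};
    for (int a = 0; a < N_ARR; ++a) {
      NumericMatrix m = arrays[nm[a]];
      for (int i = 0; i < n; ++i)
        for (int j = 0; j < n; ++j)
          M[a][(size_t)i * n + j] = m(i, j);
    }
  }
};

// ------------------------------------------------------------- tracebacks

// deterministic MFE traceback: first branch (tie-break order) matching the
// stored optimum within a small absolute tolerance
static IntegerMatrix mfeTraceback(Engine<MinPlus>& eng) {
  const double EPS = 1e-7;
  std::vector<std::pair<int, int>> pairs;
  std::vector<Sub> stack;
  stack.push_back({A_Z, 0, eng.n - 1});
  std::vector<Branch> br;
  while (!stack.empty()) {
    Sub cur = stack.back();
    stack.pop_back();
    double v = eng.get(cur.arr, cur.i, cur.j);
    if (cur.arr == A_Z && (cur.j < cur.i || cur.j - cur.i <= eng.t.theta))
      continue;
    if (v == R_PosInf)
      stop("traceback reached an impossible cell");
    eng.branches(cur.arr, cur.i, cur.j, br);
    bool found = false;
    for (const Branch& b : br) {
      if (std::fabs(b.sc - v) <= EPS) {
        if (b.np) pairs.push_back({b.pi + 1, b.pj + 1});
        for (int s = 0; s < b.ns; ++s) stack.push_back(b.sub[s]);
        found = true;
        break;
      }
    }
    if (!found) stop("traceback found no matching branch (numerical issue)");
  }
  IntegerMatrix out(pairs.size(), 2);
  for (size_t r = 0; r < pairs.size(); ++r) {
    out(r, 0) = pairs[r].first;
    out(r, 1) = pairs[r].second;
  }
  return out;
}

// stochastic traceback in the sum-product (log) semiring; uses R's RNG
static IntegerMatrix sampleTraceback(Engine<LogSum>& eng) {
  std::vector<std::pair<int, int>> pairs;
  std::vector<Sub> stack;
  stack.push_back({A_Z, 0, eng.n - 1});
  std::vector<Branch> br;
  while (!stack.empty()) {
    Sub cur = stack.back();
    stack.pop_back();
    if (cur.arr == A_Z && (cur.j < cur.i || cur.j - cur.i <= eng.t.theta))
      continue;
    double v = eng.get(cur.arr, cur.i, cur.j);
    if (v == R_NegInf) stop("stochastic traceback reached an empty cell");
    eng.branches(cur.arr, cur.i, cur.j, br);
    double u = unif_rand(), acc = 0.0;
    const Branch* chosen = nullptr;
    for (const Branch& b : br) {
      if (b.sc == R_NegInf) continue;
      acc += std::exp(b.sc - v);
      if (u <= acc) { chosen = &b; break; }
    }
    if (!chosen) { // numerical slack: fall back to the last possible branch
      for (auto it = br.rbegin(); it != br.rend(); ++it)
        if (it->sc != R_NegInf) { chosen = &(*it); break; }
      if (!chosen) stop("stochastic traceback: no viable branch");
    }
    if (chosen->np) pairs.push_back({chosen->pi + 1, chosen->pj + 1});
    for (int s = 0; s < chosen->ns; ++s) stack.push_back(chosen->sub[s]);
  }
  IntegerMatrix out(pairs.size(), 2);
  for (size_t r = 0; r < pairs.size(); ++r) {
    out(r, 0) = pairs[r].first;
    out(r, 1) = pairs[r].second;
  }
  return out;
}

// ------------------------------------------------------------------ entry

// [[Rcpp::export(name = ".cpp_fill")]]
List cpp_fill(IntegerVector iseq, List tables, std::string semiring) {
  Tables t = buildTables(iseq, tables);
  if (semiring == "min-plus") {
    Engine<MinPlus> eng(t);
    eng.fill();
    return eng.asList();
  } else if (semiring == "sum-product") {
    Engine<LogSum> eng(t);
    eng.fill();
    return eng.asList();
  } else if (semiring == "count") {
    Engine<Count> eng(t);
    eng.fill();
    return eng.asList();
  }
  stop("unknown semiring: %s", semiring.c_str());
}

// [[Rcpp::export(name = ".cpp_mfe")]]
List cpp_mfe(IntegerVector iseq, List tables, bool keepArrays) {
  Tables t = buildTables(iseq, tables);
  Engine<MinPlus> eng(t);
  eng.fill();
  double mfe = eng.get(A_Z, 0, t.n - 1);
  IntegerMatrix pairs = mfeTraceback(eng);
  List out = List::create(_["energy"] = mfe, _["pairs"] = pairs);
  if (keepArrays) out["arrays"] = eng.asList();
  return out;
}

// [[Rcpp::export(name = ".cpp_sample")]]
List cpp_sample(IntegerVector iseq, List tables, List arrays, int m) {
  Tables t = buildTables(iseq, tables);
  Engine<LogSum> eng(t);
  eng.fromList(arrays);
  RNGScope scope;
  List out(m);
  for (int s = 0; s < m; ++s) out[s] = sampleTraceback(eng);
  return out;
}
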