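// Linear-time helpers for bar-bracket secondary structures:
//  - pair-table construction with validation,
//  - the motif-directed rule-usage decomposer specialised to the detailed
//    RNA grammar (26 nonterminals, 54 rules), used for training at
//    rRNA scale,
//  - ancestral (top-down) sampling from a stochastic grammar.

#include <Rcpp.h>
#include <string>
#include <vector>

using namespace Rcpp;

// Partner index (0-based) for every position, -1 for unpaired.
// Validates: characters, balance, minimum hairpin size 3, >= 1 pair.
// [[Rcpp::export]]
List pair_table_(std::string w, bool require_pair = true) {
  int n = w.size();
  IntegerVector partner(n, -1);
  std::vector<int> stack;
  std::vector<int> bars;   // unpaired count inside each open bracket
  std::vector<int> pairs;  // pair count inside each open bracket
  int npairs = 0;
  auto fail = [&](int pos, std::string msg) {
    return List::create(_["ok"] = false, _["partner"] = partner,
                        _["err_pos"] = pos + 1, _["err_msg"] = msg);
  };
  for (int i = 0; i < n; ++i) {
    char c = w[i];
    if (c == '(') {
      stack.push_back(i);
      bars.push_back(0);
      pairs.push_back(0);
    } else if (c == ')') {
      if (stack.empty()) return fail(i, "unbalanced: unmatched ')'");
      int j = stack.back();
      stack.pop_back();
      int b = bars.back(); bars.pop_back();
      int p = pairs.back(); pairs.pop_back();
      if (p == 0 && b < 3)
        return fail(i, "hairpin loop with fewer than 3 unpaired bases");
      partner[i] = j;
      partner[j] = i;
      ++npairs;
      if (!pairs.empty()) pairs.back() += 1;
    } else if (c == '|') {
      if (!bars.empty()) bars.back() += 1;
    } else {
      return fail(i, "character outside the {(,),|} alphabet");
    }
  }
  if (!stack.empty()) return fail(stack.back(), "unbalanced: unmatched '('");
  if (require_pair && npairs == 0)
    return fail(n > 0 ? n - 1 : 0, "completely unpaired structures are excluded");
  return List::create(_["ok"] = true, _["partner"] = partner,
                      _["err_pos"] = -1, _["err_msg"] = "");
}

// ---------------------------------------------------------------------------
// Rule-usage decomposer for the detailed grammar (Definition of the 54-rule
// SCFG over {S',E,S,T,C,A,L,G,D,B,F,H,P,Q,R,V,W,O,J,K,M,X,Y,Z,N,U}).
// counts is 1-based by rule id (1..54).

static inline void add(std::vector<double>& cnt, int rule, double k = 1) {
  cnt[rule] += k;
}

// bar-run nonterminals: first rule once, recursive rule (len-1) times
static inline void run_C(std::vector<double>& c, int len) { add(c, 8); add(c, 9, len - 1); }
static inline void run_B(std::vector<double>& c, int len) { add(c, 23); add(c, 24, len - 1); }
static inline void run_H(std::vector<double>& c, int len) { add(c, 28); add(c, 29, len - 1); }
static inline void run_J(std::vector<double>& c, int len) { add(c, 41); add(c, 42, len - 1); }
static inline void run_K(std::vector<double>& c, int len) { add(c, 43); add(c, 44, len - 1); }
static inline void run_U(std::vector<double>& c, int len) { add(c, 53); add(c, 54, len - 1); }

struct Decomp {
  const std::string& w;
  const IntegerVector& partner;
  std::vector<double>& cnt;
  Decomp(const std::string& w_, const IntegerVector& p_, std::vector<double>& c_)
      : w(w_), partner(p_), cnt(c_) {}

  // children pairs and bar-gaps of the region (i, j) exclusive
  void region(int i, int j, std::vector<int>& kids, std::vector<int>& gaps) {
    kids.clear();
    gaps.clear();
    int bars = 0;
    for (int k = i; k < j;) {
      if (w[k] == '|') { ++bars; ++k; }
      else { gaps.push_back(bars); bars = 0; kids.push_back(k); k = partner[k] + 1; }
    }
    gaps.push_back(bars);
  }

  // A -> (L), pair at (i, partner[i])
  void pair(int i) {
    int j = partner[i];
    add(cnt, 10);  // A -> (L)
    std::vector<int> kids, gaps;
    region(i + 1, j, kids, gaps);
    int k = kids.size();
    if (k == 0) {  // hairpin
      int b = gaps[0];
      add(cnt, 16);  // L -> F
      if (b == 3) add(cnt, 25);
      else if (b == 4) add(cnt, 26);
      else { add(cnt, 27); run_H(cnt, b - 4); }
    } else if (k == 1) {
      int l = gaps[0], r = gaps[1];
      if (l == 0 && r == 0) {        // stacked pair
        add(cnt, 11);                 // L -> A
      } else if (l == 0 || r == 0) {  // bulge
        add(cnt, 17);                 // L -> G
        int b = l + r;
        if (r > 0) {                  // bulge right: content A bars
          if (b == 1) add(cnt, 18);
          else { add(cnt, 19); add(cnt, 22); run_B(cnt, b - 1); }
        } else {                      // bulge left
          if (b == 1) add(cnt, 20);
          else { add(cnt, 21); add(cnt, 22); run_B(cnt, b - 1); }
        }
      } else {                        // interior loop, sides (l, r)
        if (l <= 2 && r <= 2) {
          add(cnt, 13);               // L -> P
          if (l == 1 && r == 1) add(cnt, 30);
          else if (l == 1 && r == 2) add(cnt, 31);
          else if (l == 2 && r == 1) add(cnt, 32);
          else add(cnt, 33);
        } else if (l == 2) {          // (2, r>=3): Q -> ||O||
          add(cnt, 14); add(cnt, 34); add(cnt, 40); run_K(cnt, r - 2);
        } else if (l >= 3 && r >= 2) {  // Q -> ||V|
          add(cnt, 14); add(cnt, 35); add(cnt, 38); run_J(cnt, l - 2);
          add(cnt, 40); run_K(cnt, r - 1);
        } else if (l == 1) {          // (1, r>=3): R -> |O||
          add(cnt, 15); add(cnt, 36); add(cnt, 40); run_K(cnt, r - 2);
        } else {                      // (l>=3, 1): R -> ||W|
          add(cnt, 15); add(cnt, 37); add(cnt, 39); run_J(cnt, l - 2);
        }
      }
    } else {                          // multiloop, degree k >= 2
      add(cnt, 12);                   // L -> M
      add(cnt, 45);                   // M -> XY
      // first branch: X -> A | UA
      if (gaps[0] == 0) add(cnt, 46);
      else { add(cnt, 47); run_U(cnt, gaps[0]); }
      add(cnt, 48);                   // Y -> Z
      for (int b = 1; b < k; ++b) {
        bool last = (b == k - 1);
        int trail = gaps[k];
        if (last && trail == 0) add(cnt, 49);   // Z -> X
        else add(cnt, 50);                      // Z -> XN
        if (gaps[b] == 0) add(cnt, 46);
        else { add(cnt, 47); run_U(cnt, gaps[b]); }
        if (!last) add(cnt, 51);                // N -> Z
        else if (trail > 0) { add(cnt, 52); run_U(cnt, trail); }  // N -> U
      }
    }
    for (int kid : kids) pair(kid);
  }

  void exterior() {
    add(cnt, 1);  // S' -> E
    std::vector<int> kids, gaps;
    region(0, w.size(), kids, gaps);
    int k = kids.size();
    // E over outer elements 1..t with trailing bars gaps[t]
    for (int t = k; t >= 1; --t) {
      int trail = gaps[t];
      if (trail > 0) { add(cnt, 3); run_C(cnt, trail); }  // E -> SC
      else add(cnt, 2);                                   // E -> S
      int lead = gaps[t - 1];
      if (t == 1) {
        if (lead == 0) add(cnt, 4);                        // S -> A
        else { add(cnt, 5); add(cnt, 7); run_C(cnt, lead); }  // S -> TA, T -> C
      } else {
        add(cnt, 5);  // S -> TA
        add(cnt, 6);  // T -> E (prefix still holds a pair)
      }
    }
    for (int kid : kids) pair(kid);
  }
};

// [[Rcpp::export]]
NumericVector gsto_rule_counts_(std::string w, IntegerVector partner) {
  std::vector<double> cnt(55, 0.0);
  Decomp d(w, partner, cnt);
  d.exterior();
  NumericVector out(54);
  for (int i = 1; i <= 54; ++i) out[i - 1] = cnt[i];
  return out;
}

// ---------------------------------------------------------------------------
// Ancestral sampler: expand the leftmost nonterminal according to the rule
// probabilities until only terminals remain.  Symbol coding: nonterminals
// 0..K-1, terminals -1 '(', -2 ')', -3 '|'.  Rules must be grouped by
// premise: grp[k]..grp[k+1]-1 index into (cumprob, rhs_off) for premise k.

// [[Rcpp::export]]
List scfg_sample_(int m, int axiom, IntegerVector grp, NumericVector cumprob,
                  IntegerVector rule_id, IntegerVector rhs_flat,
                  IntegerVector rhs_off, int nrules, double max_len) {
  CharacterVector words(m);
  NumericMatrix counts(m, nrules);
  std::vector<int> stack;
  for (int s = 0; s < m; ++s) {
    std::string out;
    stack.clear();
    stack.push_back(axiom);
    while (!stack.empty()) {
      int sym = stack.back();
      stack.pop_back();
      if (sym < 0) {
        out.push_back(sym == -1 ? '(' : (sym == -2 ? ')' : '|'));
        if ((double)out.size() > max_len)
          stop("sampled structure exceeds the configured length bound");
        continue;
      }
      double u = unif_rand();
      int lo = grp[sym], hi = grp[sym + 1];
      int pick = hi - 1;
      for (int r = lo; r < hi; ++r) {
        if (u <= cumprob[r]) { pick = r; break; }
      }
      counts(s, rule_id[pick] - 1) += 1;
      for (int t = rhs_off[pick + 1] - 1; t >= rhs_off[pick]; --t)
        stack.push_back(rhs_flat[t]);
    }
    words[s] = out;
  }
  return List::create(_["words"] = words, _["counts"] = counts);
}
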