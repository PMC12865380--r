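// Soft/hard Bayesian additive regression trees with Dirichlet-type
// split-selection priors (uniform, DART, longitudinal grouped LDART).
//
// Trees use probabilistic (logistic) gating: an observation is routed
// left at an internal node with probability psi((c - x_j)/b); b -> 0
// recovers the hard indicator partition.  Leaf parameters are
// marginalized in the Metropolis-Hastings structure moves and drawn
// from their conjugate normal full conditional afterwards.
//
// All randomness goes through R's RNG so set.seed() governs the fit.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const int MAX_DEPTH = 10;

static inline double expit(double u) { return 1.0 / (1.0 + std::exp(-u)); }

static inline double runif01() {
  double u = R::unif_rand();
  if (u <= 0.0) u = 1e-12;
  if (u >= 1.0) u = 1.0 - 1e-12;
  return u;
}

// ---------------------------------------------------------------------------
// tree representation
// ---------------------------------------------------------------------------

struct Node {
  int var;        // -1 for a leaf
  double cut;
  int left, right, parent;
  int depth;
  double leaf;
  bool used;
};

struct Tree {
  std::vector<Node> nodes;
  std::vector<int> free_ids;
  double b;          // bandwidth on the per-predictor-range scale
  arma::mat Phi;     // cached n x L leaf-weight matrix
  std::vector<int> leaf_ids;  // column order of Phi

  Tree() : b(0.1) {
    Node root{-1, 0.0, -1, -1, -1, 0, 0.0, true};
    nodes.push_back(root);
  }

  int n_used() const {
    int k = 0;
    for (const Node& nd : nodes) if (nd.used) ++k;
    return k;
  }

  std::vector<int> leaves() const {
    std::vector<int> out;
    for (size_t i = 0; i < nodes.size(); ++i)
      if (nodes[i].used && nodes[i].var < 0) out.push_back((int)i);
    return out;
  }

  // internal nodes with two leaf children (prunable)
  std::vector<int> nogs() const {
    std::vector<int> out;
    for (size_t i = 0; i < nodes.size(); ++i) {
      const Node& nd = nodes[i];
      if (nd.used && nd.var >= 0 &&
          nodes[nd.left].var < 0 && nodes[nd.right].var < 0)
        out.push_back((int)i);
    }
    return out;
  }

  int new_node() {
    if (!free_ids.empty()) {
      int id = free_ids.back();
      free_ids.pop_back();
      return id;
    }
    nodes.push_back(Node{-1, 0.0, -1, -1, -1, 0, 0.0, true});
    return (int)nodes.size() - 1;
  }
};

// leaf weights for every observation; soft gating unless hard=true
static void fill_weights(const Tree& tr, int node, const arma::mat& X,
                         const arma::vec& xmin, const arma::vec& xrange,
                         bool hard, arma::vec w, arma::mat& Phi,
                         std::vector<int>& leaf_ids) {
  const Node& nd = tr.nodes[node];
  if (nd.var < 0) {
    Phi.insert_cols(Phi.n_cols, w);
    leaf_ids.push_back(node);
    return;
  }
  const double* xj = X.colptr(nd.var);
  arma::vec pl(X.n_rows);
  if (hard || tr.b <= 0.0) {
    for (arma::uword i = 0; i < X.n_rows; ++i)
      pl(i) = (xj[i] <= nd.cut) ? 1.0 : 0.0;
  } else {
    double bw = tr.b * xrange(nd.var);
    if (bw < 1e-12) bw = 1e-12;
    for (arma::uword i = 0; i < X.n_rows; ++i)
      pl(i) = expit((nd.cut - xj[i]) / bw);
  }
  fill_weights(tr, nd.left, X, xmin, xrange, hard, w % pl, Phi, leaf_ids);
  fill_weights(tr, nd.right, X, xmin, xrange, hard, w % (1.0 - pl), Phi, leaf_ids);
}

static void rebuild_phi(Tree& tr, const arma::mat& X, const arma::vec& xmin,
                        const arma::vec& xrange, bool hard) {
  arma::mat Phi(X.n_rows, 0);
  std::vector<int> ids;
  arma::vec w(X.n_rows, arma::fill::ones);
  fill_weights(tr, 0, X, xmin, xrange, hard, w, Phi, ids);
  tr.Phi = Phi;
  tr.leaf_ids = ids;
}

// integrated log likelihood of residual r given leaf-weight matrix Phi,
// leaf prior N(0, smu2), residual variance sig2; terms not depending on
// the tree structure are dropped.
static double marginal_loglik(const arma::mat& Phi, const arma::vec& r,
                              double sig2, double smu2,
                              arma::mat* R_out = nullptr,
                              arma::vec* m_out = nullptr) {
  arma::uword L = Phi.n_cols;
  arma::mat A = Phi.t() * Phi / sig2;
  A.diag() += 1.0 / smu2;
  arma::vec bv = Phi.t() * r / sig2;
  arma::mat R;
  if (!arma::chol(R, A)) return -std::numeric_limits<double>::infinity();
  arma::vec z = arma::solve(arma::trimatl(R.t()), bv);
  double logdet = 2.0 * arma::accu(arma::log(R.diag()));
  double ll = -0.5 * (double)L * std::log(smu2) - 0.5 * logdet +
              0.5 * arma::dot(z, z);
  if (R_out) *R_out = R;
  if (m_out) *m_out = z;  // R^{-T} b ; posterior mean = R^{-1} z
  return ll;
}

static void draw_leaves(Tree& tr, const arma::vec& r, double sig2, double smu2) {
  arma::mat R;
  arma::vec z;
  double ll = marginal_loglik(tr.Phi, r, sig2, smu2, &R, &z);
  if (!std::isfinite(ll)) stop("singular leaf system");
  arma::uword L = tr.Phi.n_cols;
  arma::vec eps(L);
  for (arma::uword l = 0; l < L; ++l) eps(l) = R::norm_rand();
  arma::vec mu = arma::solve(arma::trimatu(R), z + eps);
  for (arma::uword l = 0; l < L; ++l) tr.nodes[tr.leaf_ids[l]].leaf = mu(l);
}

// ---------------------------------------------------------------------------
// split-selection prior state
// ---------------------------------------------------------------------------

struct PriorState {
  int type;                 // 0 uniform, 1 dart, 2 ldart
  int P;
  arma::vec q;
  // dart
  double alpha, rho, a0, b0;
  // ldart
  arma::ivec group;         // 0 = current, 1..G = past groups
  int G;
  double w, a_w, b_w;
  double eta;
  arma::vec vcur;           // over current-group predictors (within-group)
  arma::vec u;              // over past groups
  arma::vec phi_g;          // concentration per past group
  arma::vec alpha_g;        // concentration for u components
  arma::vec c_alpha;        // Beta(c_g, 1) hyperprior shape per past group
  double rho_alpha;         // rho for alpha_g (= t)
  std::vector<std::vector<int> > members;  // predictor ids per group (0..G)
};

static arma::vec rdirichlet(const arma::vec& a) {
  arma::vec g(a.n_elem);
  for (arma::uword i = 0; i < a.n_elem; ++i) {
    double sh = std::max(a(i), 1e-8);
    g(i) = R::rgamma(sh, 1.0);
    if (g(i) < 1e-300) g(i) = 1e-300;
  }
  return g / arma::accu(g);
}

// MH update (on logit of alpha/(alpha+rho)) for a Dirichlet concentration
// given a simplex draw v of dimension K with prior Dir(alpha/K,...,alpha/K)
// and hyperprior alpha/(alpha+rho) ~ Beta(a0, b0).
static double update_concentration(double alpha, double rho, double a0, double b0,
                                   const arma::vec& v, int n_steps = 5) {
  int K = (int)v.n_elem;
  if (K <= 1) return alpha;
  double slog = 0.0;
  for (int j = 0; j < K; ++j) slog += std::log(std::max(v(j), 1e-300));
  auto logpost = [&](double a) {
    double s = a / (a + rho);
    double lik = R::lgammafn(a) - K * R::lgammafn(a / K) + (a / K) * slog;
    double pri = (a0 - 1.0) * std::log(s) + (b0 - 1.0) * std::log1p(-s);
    double jac = std::log(s) + std::log1p(-s);  // theta = logit(s)
    return lik + pri + jac;
  };
  double s = alpha / (alpha + rho);
  double theta = std::log(s) - std::log1p(-s);
  double lp = logpost(alpha);
  for (int it = 0; it < n_steps; ++it) {
    double thn = theta + 1.0 * R::norm_rand();
    double sn = expit(thn);
    double an = rho * sn / (1.0 - sn);
    if (an < 1e-8 || !std::isfinite(an)) continue;
    double lpn = logpost(an);
    if (std::log(runif01()) < lpn - lp) {
      theta = thn;
      alpha = an;
      lp = lpn;
    }
  }
  return alpha;
}

// MH update for one component alpha_g of the grouped prior on u, where
// u ~ Dir(alpha_1/G, ..., alpha_G/G) and alpha_g/(alpha_g+rho) ~ Beta(c_g, 1).
static void update_alpha_group(PriorState& st) {
  int G = st.G;
  if (G < 1) return;
  auto logpost_all = [&](const arma::vec& al) {
    double A = arma::accu(al) / G;
    double out = R::lgammafn(A);
    for (int g = 0; g < G; ++g) {
      double ag = al(g) / G;
      out += -R::lgammafn(ag) +
             (ag - 1.0) * std::log(std::max(st.u(g), 1e-300));
      double s = al(g) / (al(g) + st.rho_alpha);
      out += (st.c_alpha(g) - 1.0) * std::log(s);  // Beta(c_g, 1) prior
      out += std::log(s) + std::log1p(-s);         // Jacobian
    }
    return out;
  };
  double lp = logpost_all(st.alpha_g);
  for (int g = 0; g < G; ++g) {
    arma::vec prop = st.alpha_g;
    double s = prop(g) / (prop(g) + st.rho_alpha);
    double theta = std::log(s) - std::log1p(-s) + 1.0 * R::norm_rand();
    double sn = expit(theta);
    double an = st.rho_alpha * sn / (1.0 - sn);
    if (an < 1e-8 || !std::isfinite(an)) continue;
    prop(g) = an;
    double lpn = logpost_all(prop);
    if (std::log(runif01()) < lpn - lp) {
      st.alpha_g = prop;
      lp = lpn;
    }
  }
}

struct LdartVks {
  std::vector<arma::vec> vk;  // within-group simplex per past group
};

static PriorState prior_init(List spec, int P) {
  PriorState st;
  st.P = P;
  std::string ty = as<std::string>(spec["type"]);
  st.type = (ty == "uniform") ? 0 : (ty == "dart") ? 1 : 2;
  st.q = arma::vec(P, arma::fill::value(1.0 / P));
  if (st.type == 1) {
    st.rho = as<double>(spec["rho"]);
    st.a0 = as<double>(spec["a"]);
    st.b0 = as<double>(spec["b"]);
    // start alpha at prior median of alpha/(alpha+rho)
    double s0 = 0.5;
    st.alpha = st.rho * s0 / (1.0 - s0);
  } else if (st.type == 2) {
    st.group = as<arma::ivec>(spec["group"]);
    st.G = (int)as<int>(spec["n_past"]);
    st.a_w = as<double>(spec["a_w"]);
    st.b_w = as<double>(spec["b_w"]);
    st.c_alpha = as<arma::vec>(spec["c_alpha"]);
    st.rho_alpha = as<double>(spec["rho_alpha"]);
    st.members.assign(st.G + 1, std::vector<int>());
    for (int j = 0; j < P; ++j) st.members[st.group(j)].push_back(j);
    int P0 = (int)st.members[0].size();
    st.w = (st.G == 0) ? 1.0 : 0.5;
    st.eta = (double)P0;  // alpha/(alpha+rho)=0.5 start
    st.vcur = arma::vec(P0, arma::fill::value(1.0 / std::max(P0, 1)));
    st.u = arma::vec(std::max(st.G, 1),
                     arma::fill::value(1.0 / std::max(st.G, 1)));
    st.phi_g = arma::vec(std::max(st.G, 1));
    st.alpha_g = arma::vec(std::max(st.G, 1));
    for (int g = 0; g < st.G; ++g) {
      int Pg = (int)st.members[g + 1].size();
      st.phi_g(g) = (double)std::max(Pg, 1);
      double c = st.c_alpha(g);
      double s0 = c / (c + 1.0);  // Beta(c,1) mean
      st.alpha_g(g) = st.rho_alpha * s0 / (1.0 - s0);
    }
  }
  return st;
}

// Gibbs/MH sweep of the split-selection prior given per-predictor split
// counts; recomputes st.q.
static void prior_update(PriorState& st, LdartVks& vks, const arma::vec& counts) {
  if (st.type == 0) return;
  if (st.type == 1) {
    arma::vec a = counts + st.alpha / st.P;
    st.q = rdirichlet(a);
    st.alpha = update_concentration(st.alpha, st.rho, st.a0, st.b0, st.q);
    return;
  }
  // LDART
  int G = st.G;
  const std::vector<int>& cur = st.members[0];
  int P0 = (int)cur.size();
  double Mc = 0.0;
  arma::vec Mg(std::max(G, 1), arma::fill::zeros);
  for (size_t j = 0; j < cur.size(); ++j) Mc += counts(cur[j]);
  for (int g = 1; g <= G; ++g)
    for (int id : st.members[g]) Mg(g - 1) += counts(id);
  double Mp = arma::accu(Mg);
  if (G > 0) st.w = R::rbeta(st.a_w + Mc, st.b_w + Mp);
  else st.w = 1.0;
  // v^t
  arma::vec ac(P0);
  for (int j = 0; j < P0; ++j) ac(j) = st.eta / P0 + counts(cur[j]);
  st.vcur = rdirichlet(ac);
  st.eta = update_concentration(st.eta, (double)P0, 0.5, 1.0, st.vcur);
  // u and v^k
  if (G > 0) {
    arma::vec au(G);
    for (int g = 0; g < G; ++g) au(g) = st.alpha_g(g) / G + Mg(g);
    st.u = rdirichlet(au);
    update_alpha_group(st);
    if ((int)vks.vk.size() != G) vks.vk.assign(G, arma::vec());
    for (int g = 0; g < G; ++g) {
      const std::vector<int>& mem = st.members[g + 1];
      int Pg = (int)mem.size();
      arma::vec ag(Pg);
      for (int j = 0; j < Pg; ++j) ag(j) = st.phi_g(g) / Pg + counts(mem[j]);
      vks.vk[g] = rdirichlet(ag);
      st.phi_g(g) = update_concentration(st.phi_g(g), (double)Pg, 0.5, 1.0,
                                         vks.vk[g]);
    }
  }
  // compose q
  arma::vec q(st.P, arma::fill::zeros);
  double wc = (G == 0) ? 1.0 : st.w;
  for (int j = 0; j < P0; ++j) q(cur[j]) = wc * st.vcur(j);
  for (int g = 0; g < G; ++g) {
    const std::vector<int>& mem = st.members[g + 1];
    for (size_t j = 0; j < mem.size(); ++j)
      q(mem[j]) = (1.0 - st.w) * st.u(g) * vks.vk[g](j);
  }
  st.q = q / arma::accu(q);
}

// ---------------------------------------------------------------------------
// stored posterior forests
// ---------------------------------------------------------------------------

struct FlatNode {
  int var;      // 0-based, -1 leaf
  double cut;
  double band;  // absolute bandwidth; 0 => hard
  int left, right;  // 0-based into flat array, -1 none
  double leaf;
};

struct ForestDraw {
  std::vector<std::vector<FlatNode> > trees;
  double mu0;
};

struct ForestDraws {
  std::vector<ForestDraw> draws;
  int P;
};

static std::vector<FlatNode> flatten_tree(const Tree& tr, const arma::vec& xrange,
                                          bool hard) {
  std::vector<FlatNode> out;
  std::vector<int> map(tr.nodes.size(), -1);
  // pre-order
  std::vector<int> stack{0};
  std::vector<int> order;
  while (!stack.empty()) {
    int id = stack.back();
    stack.pop_back();
    order.push_back(id);
    const Node& nd = tr.nodes[id];
    if (nd.var >= 0) {
      stack.push_back(nd.right);
      stack.push_back(nd.left);
    }
  }
  for (size_t i = 0; i < order.size(); ++i) map[order[i]] = (int)i;
  for (int id : order) {
    const Node& nd = tr.nodes[id];
    FlatNode fn;
    fn.var = nd.var;
    fn.cut = nd.cut;
    fn.band = (nd.var >= 0 && !hard) ? tr.b * xrange(nd.var) : 0.0;
    fn.left = nd.var >= 0 ? map[nd.left] : -1;
    fn.right = nd.var >= 0 ? map[nd.right] : -1;
    fn.leaf = nd.leaf;
    out.push_back(fn);
  }
  return out;
}

static void flat_weights(const std::vector<FlatNode>& tr, int node,
                         const arma::mat& X, arma::vec w, arma::vec& out) {
  const FlatNode& nd = tr[node];
  if (nd.var < 0) {
    out += w * nd.leaf;
    return;
  }
  const double* xj = X.colptr(nd.var);
  arma::vec pl(X.n_rows);
  if (nd.band <= 0.0) {
    for (arma::uword i = 0; i < X.n_rows; ++i)
      pl(i) = (xj[i] <= nd.cut) ? 1.0 : 0.0;
  } else {
    for (arma::uword i = 0; i < X.n_rows; ++i)
      pl(i) = expit((nd.cut - xj[i]) / nd.band);
  }
  flat_weights(tr, nd.left, X, w % pl, out);
  flat_weights(tr, nd.right, X, w % (1.0 - pl), out);
}

// ---------------------------------------------------------------------------
// main sampler
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List sbart_mcmc(arma::mat X, arma::vec y, int is_probit, List prior_spec,
                int B, int n_warmup, int n_save, int thin,
                double depth_gamma, double depth_beta,
                double sigma_mu, double band_mean, double nu, double lambda,
                int soft, double mu0) {
  int n = (int)X.n_rows;
  int P = (int)X.n_cols;
  bool hard = (soft == 0);
  bool probit = (is_probit == 1);

  arma::vec xmin = arma::min(X, 0).t();
  arma::vec xmax = arma::max(X, 0).t();
  arma::vec xrange = xmax - xmin;
  for (int j = 0; j < P; ++j) if (xrange(j) <= 0) xrange(j) = 1.0;

  PriorState pst = prior_init(prior_spec, P);
  LdartVks vks;
  double smu2 = sigma_mu * sigma_mu;

  std::vector<Tree> forest(B);
  arma::vec fit_total(n, arma::fill::zeros);
  std::vector<arma::vec> fits(B, arma::vec(n, arma::fill::zeros));
  for (int b = 0; b < B; ++b) rebuild_phi(forest[b], X, xmin, xrange, hard);

  // working response (latent scale for probit)
  arma::vec yw = y;
  double sig2 = probit ? 1.0 : arma::var(y);
  if (!std::isfinite(sig2) || sig2 <= 0) sig2 = 1e-6;

  ForestDraws* store = new ForestDraws();
  store->P = P;
  arma::vec sigma_draws(n_save);
  arma::mat q_draws(n_save, P);
  arma::mat count_draws(n_save, P);
  arma::vec w_draws(n_save, arma::fill::ones);
  int n_alpha = (pst.type == 2) ? std::max(pst.G, 1) : 1;
  arma::mat alpha_draws(n_save, n_alpha, arma::fill::zeros);
  int grow_acc = 0, grow_try = 0, band_acc = 0, band_try = 0;

  int n_iter = n_warmup + n_save * thin;
  int save_i = 0;

  for (int it = 0; it < n_iter; ++it) {
    if (probit) {
      // Albert-Chib latent draws
      for (int i = 0; i < n; ++i) {
        double m = mu0 + fit_total(i);
        double plo = R::pnorm(0.0, m, 1.0, 1, 0);  // P(z<0)
        double u;
        if (y(i) > 0.5) u = plo + runif01() * (1.0 - plo);
        else u = runif01() * plo;
        if (u < 1e-12) u = 1e-12;
        if (u > 1.0 - 1e-12) u = 1.0 - 1e-12;
        yw(i) = R::qnorm(u, m, 1.0, 1, 0) - mu0;
      }
      sig2 = 1.0;
    }
    arma::vec resid = yw - fit_total;

    for (int b = 0; b < B; ++b) {
      Tree& tr = forest[b];
      arma::vec rb = resid + fits[b];

      // --- structure move: grow or prune ---
      std::vector<int> lv = tr.leaves();
      std::vector<int> ng = tr.nogs();
      int L = (int)lv.size();
      bool single = (L == 1);
      double p_grow = single ? 1.0 : 0.5;
      bool do_grow = (runif01() < p_grow);
      double ll_cur = marginal_loglik(tr.Phi, rb, sig2, smu2);

      if (do_grow) {
        grow_try++;
        int leaf_id = lv[(int)(runif01() * L)];
        int d = tr.nodes[leaf_id].depth;
        if (d < MAX_DEPTH) {
          // var from q, cut uniform on observed range
          double uu = runif01(), cum = 0.0;
          int var = P - 1;
          for (int j = 0; j < P; ++j) {
            cum += pst.q(j);
            if (uu <= cum) { var = j; break; }
          }
          double cut = xmin(var) + runif01() * xrange(var);
          Tree prop = tr;
          int lid = prop.new_node();
          int rid = prop.new_node();
          prop.nodes[lid] = Node{-1, 0.0, -1, -1, leaf_id, d + 1, 0.0, true};
          prop.nodes[rid] = Node{-1, 0.0, -1, -1, leaf_id, d + 1, 0.0, true};
          prop.nodes[leaf_id].var = var;
          prop.nodes[leaf_id].cut = cut;
          prop.nodes[leaf_id].left = lid;
          prop.nodes[leaf_id].right = rid;
          rebuild_phi(prop, X, xmin, xrange, hard);
          double ll_new = marginal_loglik(prop.Phi, rb, sig2, smu2);
          double ps_d = depth_gamma * std::pow(1.0 + d, -depth_beta);
          double ps_d1 = depth_gamma * std::pow(2.0 + d, -depth_beta);
          double log_prior = std::log(ps_d) + 2.0 * std::log1p(-ps_d1) -
                             std::log1p(-ps_d);
          int n_nog_new = (int)prop.nogs().size();
          double p_prune_new = 0.5;  // proposed tree has >= 3 nodes
          double log_prop = std::log(p_prune_new / n_nog_new) -
                            std::log(p_grow / L);
          if (std::log(runif01()) < ll_new - ll_cur + log_prior + log_prop) {
            tr = prop;
            ll_cur = ll_new;
            grow_acc++;
          }
        }
      } else if (!ng.empty()) {
        int nog_id = ng[(int)(runif01() * ng.size())];
        int d = tr.nodes[nog_id].depth;
        Tree prop = tr;
        Node& pn = prop.nodes[nog_id];
        prop.nodes[pn.left].used = false;
        prop.nodes[pn.right].used = false;
        prop.free_ids.push_back(pn.left);
        prop.free_ids.push_back(pn.right);
        pn.var = -1;
        pn.left = pn.right = -1;
        rebuild_phi(prop, X, xmin, xrange, hard);
        double ll_new = marginal_loglik(prop.Phi, rb, sig2, smu2);
        double ps_d = depth_gamma * std::pow(1.0 + d, -depth_beta);
        double ps_d1 = depth_gamma * std::pow(2.0 + d, -depth_beta);
        double log_prior = -(std::log(ps_d) + 2.0 * std::log1p(-ps_d1) -
                             std::log1p(-ps_d));
        int L_new = L - 1;
        double p_grow_new = (prop.n_used() == 1) ? 1.0 : 0.5;
        double log_prop = std::log(p_grow_new / L_new) -
                          std::log(0.5 / (double)ng.size());
        if (std::log(runif01()) < ll_new - ll_cur + log_prior + log_prop) {
          tr = prop;
          ll_cur = ll_new;
        }
      }

      // --- bandwidth move (soft trees only, and only if tree splits) ---
      if (!hard && tr.n_used() > 1) {
        band_try++;
        double logb = std::log(tr.b) + 0.4 * R::norm_rand();
        double bn = std::exp(logb);
        if (bn > 1e-6 && bn < 10.0) {
          Tree prop = tr;
          prop.b = bn;
          rebuild_phi(prop, X, xmin, xrange, hard);
          double ll_new = marginal_loglik(prop.Phi, rb, sig2, smu2);
          // b ~ Exp(mean band_mean); log-scale RW Jacobian log(bn/b)
          double lr = ll_new - ll_cur + (tr.b - bn) / band_mean +
                      std::log(bn / tr.b);
          if (std::log(runif01()) < lr) {
            tr = prop;
            ll_cur = ll_new;
            band_acc++;
          }
        }
      }

      // --- leaf draw and fit refresh ---
      draw_leaves(tr, rb, sig2, smu2);
      arma::vec leafv(tr.Phi.n_cols);
      for (arma::uword l = 0; l < tr.Phi.n_cols; ++l)
        leafv(l) = tr.nodes[tr.leaf_ids[l]].leaf;
      fits[b] = tr.Phi * leafv;
      resid = rb - fits[b];
    }
    fit_total = yw - resid;

    // --- residual scale ---
    if (!probit) {
      double ss = arma::dot(resid, resid);
      sig2 = (nu * lambda + ss) / R::rchisq(nu + n);
    }

    // --- split-selection prior ---
    arma::vec counts(P, arma::fill::zeros);
    for (int b = 0; b < B; ++b)
      for (const Node& nd : forest[b].nodes)
        if (nd.used && nd.var >= 0) counts(nd.var) += 1.0;
    prior_update(pst, vks, counts);

    // --- save ---
    if (it >= n_warmup && ((it - n_warmup + 1) % thin == 0) && save_i < n_save) {
      sigma_draws(save_i) = std::sqrt(sig2);
      q_draws.row(save_i) = pst.q.t();
      count_draws.row(save_i) = counts.t();
      if (pst.type == 2) {
        w_draws(save_i) = pst.w;
        if (pst.G > 0) alpha_draws.row(save_i) = pst.alpha_g.t();
      } else if (pst.type == 1) {
        alpha_draws(save_i, 0) = pst.alpha;
      }
      ForestDraw fd;
      fd.mu0 = mu0;
      for (int b = 0; b < B; ++b)
        fd.trees.push_back(flatten_tree(forest[b], xrange, hard));
      store->draws.push_back(fd);
      save_i++;
    }
  }

  XPtr<ForestDraws> ptr(store, true);
  return List::create(
      _["ptr"] = ptr, _["sigma"] = sigma_draws, _["q"] = q_draws,
      _["counts"] = count_draws, _["w"] = w_draws, _["alpha"] = alpha_draws,
      _["grow_rate"] = grow_try > 0 ? (double)grow_acc / grow_try : 0.0,
      _["band_rate"] = band_try > 0 ? (double)band_acc / band_try : 0.0);
}

// ---------------------------------------------------------------------------
// prediction and serialization
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
arma::vec forest_predict_cpp(SEXP ptr_, arma::mat X, int draw) {
  XPtr<ForestDraws> ptr(ptr_);
  if (draw < 1 || draw > (int)ptr->draws.size()) stop("draw out of range");
  const ForestDraw& fd = ptr->draws[draw - 1];
  arma::vec out(X.n_rows, arma::fill::value(fd.mu0));
  arma::vec w(X.n_rows, arma::fill::ones);
  for (const auto& tr : fd.trees) flat_weights(tr, 0, X, w, out);
  return out;
}

// [[Rcpp::export]]
arma::mat forest_predict_draws_cpp(SEXP ptr_, arma::mat X, IntegerVector draws) {
  XPtr<ForestDraws> ptr(ptr_);
  arma::mat out(X.n_rows, draws.size());
  arma::vec w(X.n_rows, arma::fill::ones);
  for (int k = 0; k < draws.size(); ++k) {
    int d = draws[k];
    if (d < 1 || d > (int)ptr->draws.size()) stop("draw out of range");
    const ForestDraw& fd = ptr->draws[d - 1];
    arma::vec acc(X.n_rows, arma::fill::value(fd.mu0));
    for (const auto& tr : fd.trees) flat_weights(tr, 0, X, w, acc);
    out.col(k) = acc;
  }
  return out;
}

// [[Rcpp::export]]
int forest_n_draws_cpp(SEXP ptr_) {
  XPtr<ForestDraws> ptr(ptr_);
  return (int)ptr->draws.size();
}

// nodes matrix columns: var (1-based, 0 = leaf), cut, band, left, right
// (1-based, 0 = none), leaf
// [[Rcpp::export]]
List forest_dump_cpp(SEXP ptr_) {
  XPtr<ForestDraws> ptr(ptr_);
  List draws(ptr->draws.size());
  for (size_t d = 0; d < ptr->draws.size(); ++d) {
    const ForestDraw& fd = ptr->draws[d];
    List trees(fd.trees.size());
    for (size_t b = 0; b < fd.trees.size(); ++b) {
      const auto& tr = fd.trees[b];
      NumericMatrix m((int)tr.size(), 6);
      for (size_t i = 0; i < tr.size(); ++i) {
        m(i, 0) = tr[i].var + 1;
        m(i, 1) = tr[i].cut;
        m(i, 2) = tr[i].band;
        m(i, 3) = tr[i].left + 1;
        m(i, 4) = tr[i].right + 1;
        m(i, 5) = tr[i].leaf;
      }
      colnames(m) = CharacterVector::create("var", "cut", "band", "left",
                                            "right", "leaf");
      trees[b] = m;
    }
    draws[d] = List::create(_["mu0"] = fd.mu0, _["trees"] = trees);
  }
  return List::create(_["P"] = ptr->P, _["draws"] = draws);
}

// [[Rcpp::export]]
SEXP forest_load_cpp(List dump) {
  ForestDraws* store = new ForestDraws();
  store->P = as<int>(dump["P"]);
  List draws = dump["draws"];
  for (int d = 0; d < draws.size(); ++d) {
    List dl = draws[d];
    ForestDraw fd;
    fd.mu0 = as<double>(dl["mu0"]);
    List trees = dl["trees"];
    for (int b = 0; b < trees.size(); ++b) {
      NumericMatrix m = trees[b];
      std::vector<FlatNode> tr;
      for (int i = 0; i < m.nrow(); ++i) {
        FlatNode fn;
        fn.var = (int)m(i, 0) - 1;
        fn.cut = m(i, 1);
        fn.band = m(i, 2);
        fn.left = (int)m(i, 3) - 1;
        fn.right = (int)m(i, 4) - 1;
        fn.leaf = m(i, 5);
        tr.push_back(fn);
      }
      fd.trees.push_back(tr);
    }
    store->draws.push_back(fd);
  }
  return XPtr<ForestDraws>(store, true);
}

// leaf weights of a single flat tree for each row of X (n x L, leaves in
// the order they appear in the node matrix)
// [[Rcpp::export]]
arma::mat tree_leaf_weights_cpp(NumericMatrix nodes, arma::mat X) {
  std::vector<FlatNode> tr;
  for (int i = 0; i < nodes.nrow(); ++i) {
    FlatNode fn;
    fn.var = (int)nodes(i, 0) - 1;
    fn.cut = nodes(i, 1);
    fn.band = nodes(i, 2);
    fn.left = (int)nodes(i, 3) - 1;
    fn.right = (int)nodes(i, 4) - 1;
    fn.leaf = nodes(i, 5);
    tr.push_back(fn);
  }
  std::vector<int> leaf_rows;
  for (size_t i = 0; i < tr.size(); ++i)
    if (tr[i].var < 0) leaf_rows.push_back((int)i);
  arma::mat out(X.n_rows, leaf_rows.size(), arma::fill::zeros);
  // reuse flat_weights by temporarily setting unit leaf values
  for (size_t l = 0; l < leaf_rows.size(); ++l) {
    std::vector<FlatNode> tmp = tr;
    for (size_t i = 0; i < tmp.size(); ++i) tmp[i].leaf = 0.0;
    tmp[leaf_rows[l]].leaf = 1.0;
    arma::vec acc(X.n_rows, arma::fill::zeros);
    arma::vec w(X.n_rows, arma::fill::ones);
    flat_weights(tmp, 0, X, w, acc);
    out.col(l) = acc;
  }
  return out;
}

// Gibbs/MH sweeps of the split-selection prior given fixed split counts;
// returns per-sweep draws so the stationary distribution can be checked
// against closed forms and grid integration in tests.
// [[Rcpp::export]]
List split_prior_update_cpp(arma::vec counts, List prior_spec, int n_sweeps) {
  int P = (int)counts.n_elem;
  PriorState st = prior_init(prior_spec, P);
  LdartVks vks;
  arma::mat q_draws(n_sweeps, P);
  arma::vec w_draws(n_sweeps, arma::fill::ones);
  arma::vec alpha_draws(n_sweeps, arma::fill::zeros);
  int n_alpha = (st.type == 2) ? std::max(st.G, 1) : 1;
  arma::mat alpha_g_draws(n_sweeps, n_alpha, arma::fill::zeros);
  arma::mat u_draws(n_sweeps, std::max(st.type == 2 ? st.G : 1, 1),
                    arma::fill::zeros);
  for (int s = 0; s < n_sweeps; ++s) {
    prior_update(st, vks, counts);
    q_draws.row(s) = st.q.t();
    if (st.type == 1) alpha_draws(s) = st.alpha;
    if (st.type == 2) {
      w_draws(s) = st.w;
      if (st.G > 0) {
        alpha_g_draws.row(s) = st.alpha_g.t();
        u_draws.row(s) = st.u.t();
      }
    }
  }
  return List::create(_["q"] = q_draws, _["w"] = w_draws,
                      _["alpha"] = alpha_draws, _["alpha_g"] = alpha_g_draws,
                      _["u"] = u_draws);
}
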