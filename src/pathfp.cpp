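// Hashed subgraph fingerprint enumeration over a heavy-atom molecular graph
// in the style of the classic Daylight/RDKit path fingerprint: all connected
// subgraphs of 1..max_path bonds (linear and branched) are enumerated, each
// subgraph is reduced to a canonical fragment string (isomorphism-invariant)
// and hashed into a fixed-length bit vector. The atom set and fragment
// string behind every set bit are kept, so bits can be traced back to
// fragments and hash collisions reported.
#include <Rcpp.h>
#include <cstdint>
#include <algorithm>
#include <set>
using namespace Rcpp;

static inline uint32_t fnv1a32(const std::string& s) {
  uint32_t h = 2166136261u;
  for (unsigned char c : s) {
    h ^= c;
    h *= 16777619u;
  }
  return h;
}

struct Mol {
  int na;
  std::vector<std::string> acode;                 // atom codes
  std::vector<int> e1, e2;                        // 0-based endpoints
  std::vector<std::string> ecode;                 // bond codes
  std::vector<std::vector<int>> eadj;             // line-graph adjacency
  std::vector<std::vector<std::pair<int,int>>> aadj; // atom -> (nbr atom, edge id)
};

// --- canonical fragment string -------------------------------------------
// brute-force minimal DFS string over all roots and traversal orders;
// subgraphs are tiny (<= max_path bonds), so this stays cheap. Ring
// closures are emitted as "%d" markers in encounter order.

struct Frag {
  std::vector<int> atoms;                       // molecule atom ids, sorted
  std::vector<int> aidx;                        // map position -> molecule atom
  std::vector<std::vector<std::pair<int,int>>> adj; // local: (local nbr, local edge)
  std::vector<std::string> acode, ecode;
};

static void dfs_min(const Frag& f, int cur, int parent_edge,
                    std::vector<bool>& vis_atom, std::vector<bool>& vis_edge,
                    std::string& out, const std::string& best);

// generate the minimal string for the branch starting at cur
static void dfs_min(const Frag& f, int cur, int parent_edge,
                    std::vector<bool>& vis_atom, std::vector<bool>& vis_edge,
                    std::string& out, const std::string& best) {
  out += f.acode[cur];
  // collect unvisited edges from cur
  std::vector<std::pair<int,int>> nbrs;  // (local edge, local atom)
  for (auto& pr : f.adj[cur]) {
    if (pr.second != parent_edge && !vis_edge[pr.second]) {
      nbrs.push_back({pr.second, pr.first});
    }
  }
  if (nbrs.empty()) return;
  // try every ordering of the remaining branches, keep lexicographic minimum
  std::sort(nbrs.begin(), nbrs.end());
  std::string best_local;
  bool have = false;
  std::vector<int> perm(nbrs.size());
  for (size_t i = 0; i < nbrs.size(); ++i) perm[i] = (int)i;
  do {
    std::string cand;
    std::vector<bool> va = vis_atom, ve = vis_edge;
    bool ok = true;
    for (size_t k = 0; k < perm.size() && ok; ++k) {
      auto& pr = nbrs[perm[k]];
      if (ve[pr.first]) continue;  // consumed as ring closure already
      ve[pr.first] = true;
      bool last = true;
      for (size_t k2 = k + 1; k2 < perm.size(); ++k2)
        if (!ve[nbrs[perm[k2]].first]) { last = false; break; }
      std::string piece = f.ecode[pr.first];
      if (va[pr.second]) {
        piece += "&" + f.acode[pr.second];  // ring closure to a visited atom
      } else {
        va[pr.second] = true;
        std::string sub;
        dfs_min(f, pr.second, pr.first, va, ve, sub, "");
        piece += sub;
      }
      if (!last) cand += "(" + piece + ")"; else cand += piece;
    }
    if (!have || cand < best_local) { best_local = cand; have = true; }
  } while (std::next_permutation(perm.begin(), perm.end()));
  out += best_local;
}

static std::string canonical_fragment(const Mol& mol, const std::vector<int>& edges) {
  // build local fragment
  Frag f;
  std::set<int> aset;
  for (int e : edges) { aset.insert(mol.e1[e]); aset.insert(mol.e2[e]); }
  f.atoms.assign(aset.begin(), aset.end());
  std::vector<int> apos(mol.na, -1);
  for (size_t i = 0; i < f.atoms.size(); ++i) apos[f.atoms[i]] = (int)i;
  f.aidx = f.atoms;
  f.adj.resize(f.atoms.size());
  for (size_t i = 0; i < f.atoms.size(); ++i) f.acode.push_back(mol.acode[f.atoms[i]]);
  for (size_t k = 0; k < edges.size(); ++k) {
    int e = edges[k];
    int a = apos[mol.e1[e]], b = apos[mol.e2[e]];
    f.adj[a].push_back({b, (int)k});
    f.adj[b].push_back({a, (int)k});
    f.ecode.push_back(mol.ecode[e]);
  }
  std::string best;
  bool have = false;
  for (size_t root = 0; root < f.atoms.size(); ++root) {
    std::vector<bool> va(f.atoms.size(), false), ve(edges.size(), false);
    va[root] = true;
    std::string s;
    dfs_min(f, (int)root, -1, va, ve, s, best);
    if (!have || s < best) { best = s; have = true; }
  }
  return best;
}

// --- ESU enumeration of connected edge sets -------------------------------

struct Collector {
  const Mol* mol;
  int n_bits;
  std::vector<int> bit;
  std::vector<std::string> frag;
  std::vector<std::vector<int>> atom_sets;
  void emit(const std::vector<int>& edges) {
    std::string canon = canonical_fragment(*mol, edges);
    std::set<int> aset;
    for (int e : edges) { aset.insert(mol->e1[e]); aset.insert(mol->e2[e]); }
    std::vector<int> av;
    for (int a : aset) av.push_back(a + 1);
    // two bits per fragment (double hashing), as in the classic
    // Daylight/RDKit scheme with nBitsPerHash = 2
    uint32_t h = fnv1a32(canon);
    uint32_t h2 = h * 2654435761u + 0x9e3779b9u;
    bit.push_back((int)(h % (uint32_t)n_bits));
    frag.push_back(canon);
    atom_sets.push_back(av);
    bit.push_back((int)(h2 % (uint32_t)n_bits));
    frag.push_back(canon);
    atom_sets.push_back(av);
  }
};

static void extend_subgraph(const Mol& mol, std::vector<int>& sg,
                            std::vector<int> ext, int v, int max_edges,
                            std::vector<bool>& in_sg_or_ext, Collector& col) {
  col.emit(sg);
  if ((int)sg.size() == max_edges) return;
  while (!ext.empty()) {
    int w = ext.back();
    ext.pop_back();
    std::vector<int> ext2 = ext;
    std::vector<int> added;
    for (int u : mol.eadj[w]) {
      if (u > v && !in_sg_or_ext[u]) {
        ext2.push_back(u);
        in_sg_or_ext[u] = true;
        added.push_back(u);
      }
    }
    sg.push_back(w);
    extend_subgraph(mol, sg, ext2, v, max_edges, in_sg_or_ext, col);
    sg.pop_back();
    for (int u : added) in_sg_or_ext[u] = false;
  }
}

// atoms: per-atom code ("C", "c", "O", ...); bonds: m x 2 matrix of 1-based
// atom indices; bond_codes: per-bond code ("-", "=", "#", ":").
// Enumerates every connected subgraph of 1..max_path bonds once and returns
// list(bit, fragment, atoms) with one element per subgraph occurrence.
// [[Rcpp::export]]
List enumerate_subgraph_bits(CharacterVector atoms, IntegerMatrix bonds,
                             CharacterVector bond_codes, int max_path, int n_bits) {
  Mol mol;
  mol.na = atoms.size();
  int m = bonds.nrow();
  for (int i = 0; i < mol.na; ++i) mol.acode.push_back(as<std::string>(atoms[i]));
  mol.e1.resize(m); mol.e2.resize(m); mol.ecode.resize(m);
  mol.aadj.resize(mol.na);
  for (int b = 0; b < m; ++b) {
    mol.e1[b] = bonds(b, 0) - 1;
    mol.e2[b] = bonds(b, 1) - 1;
    mol.ecode[b] = as<std::string>(bond_codes[b]);
    mol.aadj[mol.e1[b]].push_back({mol.e2[b], b});
    mol.aadj[mol.e2[b]].push_back({mol.e1[b], b});
  }
  mol.eadj.resize(m);
  for (int a = 0; a < mol.na; ++a) {
    for (size_t i = 0; i < mol.aadj[a].size(); ++i)
      for (size_t j = i + 1; j < mol.aadj[a].size(); ++j) {
        int ei = mol.aadj[a][i].second, ej = mol.aadj[a][j].second;
        mol.eadj[ei].push_back(ej);
        mol.eadj[ej].push_back(ei);
      }
  }
  Collector col;
  col.mol = &mol;
  col.n_bits = n_bits;
  std::vector<bool> in_sg_or_ext(m, false);
  for (int v = 0; v < m; ++v) {
    std::vector<int> sg = {v};
    std::vector<int> ext;
    in_sg_or_ext[v] = true;
    for (int u : mol.eadj[v]) {
      if (u > v && !in_sg_or_ext[u]) { ext.push_back(u); in_sg_or_ext[u] = true; }
    }
    extend_subgraph(mol, sg, ext, v, max_path, in_sg_or_ext, col);
    std::fill(in_sg_or_ext.begin(), in_sg_or_ext.end(), false);
  }
  int np = (int)col.bit.size();
  IntegerVector bit(np);
  CharacterVector frag(np);
  List atom_sets(np);
  for (int i = 0; i < np; ++i) {
    bit[i] = col.bit[i];
    frag[i] = col.frag[i];
    atom_sets[i] = IntegerVector(col.atom_sets[i].begin(), col.atom_sets[i].end());
  }
  return List::create(_["bit"] = bit, _["path"] = frag, _["atoms"] = atom_sets);
}
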