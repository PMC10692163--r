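#include <Rcpp.h>
#include <cstdint>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// ---- 64-bit mixing (splitmix64 finalizer) ----------------------------------
// Stable across platforms; used for fingerprint hashing and for the
// reproducible per-molecule noise streams of the scoring oracles.

static inline uint64_t mix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline uint64_t hash_combine(uint64_t h, uint64_t v) {
  return mix64(h ^ (v + 0x9E3779B97F4A7C15ULL + (h << 6) + (h >> 2)));
}

static uint64_t hash_string(const char *s, uint64_t h0) {
  uint64_t h = h0;
  for (; *s; ++s) h = hash_combine(h, (uint64_t)(unsigned char)(*s));
  return h;
}

// [[Rcpp::export]]
NumericVector cpp_hash_unit(CharacterVector ids, int seed, int salt) {
  // Deterministic uniform(0,1) deviate per id, independent of global RNG.
  // The 11 most significant bits are dropped to build a double in (0,1);
  // offset by 2^-54 keeps the value strictly inside the open interval.
  int n = ids.size();
  NumericVector out(n);
  uint64_t base = hash_combine(mix64((uint64_t)(uint32_t)seed),
                               (uint64_t)(uint32_t)salt);
  for (int i = 0; i < n; ++i) {
    uint64_t h = hash_string(CHAR(STRING_ELT(ids, i)), base);
    out[i] = (double)(h >> 11) / 9007199254740992.0 + 1.0 / 18014398509481984.0;
  }
  return out;
}

// ---- molecular graphs -------------------------------------------------------
// A graph is passed as parallel integer vectors:
//   z[i]      atomic number
//   charge[i] formal charge
//   nh[i]     implicit+explicit hydrogen count
//   inring[i] 1 if the atom is a ring member
//   bfrom/bto 1-based atom indices of each bond
//   border    bond order (kekulized: 1, 2, 3)

struct Graph {
  std::vector<int> z, charge, nh, inring;
  std::vector<int> bfrom, bto, border; // 0-based after construction
  int natoms() const { return (int)z.size(); }
  int nbonds() const { return (int)bfrom.size(); }
};

static Graph graph_from_vectors(const IntegerVector &z, const IntegerVector &charge,
                                const IntegerVector &nh, const IntegerVector &inring,
                                const IntegerVector &bfrom, const IntegerVector &bto,
                                const IntegerVector &border) {
  Graph g;
  g.z = std::vector<int>(z.begin(), z.end());
  g.charge = std::vector<int>(charge.begin(), charge.end());
  g.nh = std::vector<int>(nh.begin(), nh.end());
  g.inring = std::vector<int>(inring.begin(), inring.end());
  int nb = bfrom.size();
  g.bfrom.resize(nb); g.bto.resize(nb); g.border.resize(nb);
  for (int b = 0; b < nb; ++b) {
    g.bfrom[b] = bfrom[b] - 1;
    g.bto[b] = bto[b] - 1;
    g.border[b] = border[b];
  }
  return g;
}

// Circular (Morgan-style) fingerprint: iteratively hash each atom's
// neighbourhood out to `radius` bonds; every environment identifier at every
// radius sets one bit (id mod nbits). Neighbour contributions are combined in
// sorted order, so the result is invariant to atom numbering.
static void fp_bits_of_graph(const Graph &g, int radius, int nbits,
                             std::vector<int> &bits) {
  int n = g.natoms();
  std::vector<std::vector<std::pair<int,int> > > nbr(n); // (bond order, atom)
  for (int b = 0; b < g.nbonds(); ++b) {
    nbr[g.bfrom[b]].push_back(std::make_pair(g.border[b], g.bto[b]));
    nbr[g.bto[b]].push_back(std::make_pair(g.border[b], g.bfrom[b]));
  }
  std::vector<uint64_t> id(n), nid(n);
  bits.clear();
  for (int i = 0; i < n; ++i) {
    uint64_t h = mix64(0xA5A5A5A5ULL);
    h = hash_combine(h, (uint64_t)g.z[i]);
    h = hash_combine(h, (uint64_t)(g.charge[i] + 16));
    h = hash_combine(h, (uint64_t)g.nh[i]);
    h = hash_combine(h, (uint64_t)g.inring[i]);
    h = hash_combine(h, (uint64_t)nbr[i].size());
    id[i] = h;
    bits.push_back((int)(h % (uint64_t)nbits));
  }
  std::vector<std::pair<uint64_t,uint64_t> > env;
  for (int r = 1; r <= radius; ++r) {
    for (int i = 0; i < n; ++i) {
      env.clear();
      for (size_t k = 0; k < nbr[i].size(); ++k)
        env.push_back(std::make_pair((uint64_t)nbr[i][k].first, id[nbr[i][k].second]));
      std::sort(env.begin(), env.end());
      uint64_t h = mix64(0xC3C3C3C3ULL + (uint64_t)r);
      h = hash_combine(h, id[i]);
      for (size_t k = 0; k < env.size(); ++k) {
        h = hash_combine(h, env[k].first);
        h = hash_combine(h, env[k].second);
      }
      nid[i] = h;
      bits.push_back((int)(h % (uint64_t)nbits));
    }
    std::swap(id, nid);
  }
  std::sort(bits.begin(), bits.end());
  bits.erase(std::unique(bits.begin(), bits.end()), bits.end());
}

// [[Rcpp::export]]
IntegerVector cpp_fp_bits(IntegerVector z, IntegerVector charge, IntegerVector nh,
                          IntegerVector inring, IntegerVector bfrom, IntegerVector bto,
                          IntegerVector border, int radius, int nbits) {
  Graph g = graph_from_vectors(z, charge, nh, inring, bfrom, bto, border);
  std::vector<int> bits;
  fp_bits_of_graph(g, radius, nbits, bits);
  return IntegerVector(bits.begin(), bits.end());
}

// Bond-in-ring test: a bond is a ring bond iff its endpoints stay connected
// after removing it. O(bonds * atoms) — molecules are small.
static std::vector<bool> ring_bonds(const Graph &g) {
  int n = g.natoms(), nb = g.nbonds();
  std::vector<std::vector<int> > adj(n); // bond indices
  for (int b = 0; b < nb; ++b) {
    adj[g.bfrom[b]].push_back(b);
    adj[g.bto[b]].push_back(b);
  }
  std::vector<bool> ring(nb, false);
  std::vector<int> stack, seen(n, -1);
  for (int b = 0; b < nb; ++b) {
    int src = g.bfrom[b], dst = g.bto[b];
    stack.clear(); stack.push_back(src); seen[src] = b;
    bool found = false;
    while (!stack.empty() && !found) {
      int v = stack.back(); stack.pop_back();
      for (size_t k = 0; k < adj[v].size(); ++k) {
        int e = adj[v][k];
        if (e == b) continue;
        int w = (g.bfrom[e] == v) ? g.bto[e] : g.bfrom[e];
        if (w == dst) { found = true; break; }
        if (seen[w] != b) { seen[w] = b; stack.push_back(w); }
      }
    }
    ring[b] = found;
  }
  return ring;
}

// [[Rcpp::export]]
List cpp_ring_info(IntegerVector z, IntegerVector charge, IntegerVector nh,
                   IntegerVector inring, IntegerVector bfrom, IntegerVector bto,
                   IntegerVector border) {
  Graph g = graph_from_vectors(z, charge, nh, inring, bfrom, bto, border);
  std::vector<bool> ring = ring_bonds(g);
  LogicalVector bond_ring(g.nbonds());
  LogicalVector atom_ring(g.natoms());
  for (int b = 0; b < g.nbonds(); ++b) {
    bond_ring[b] = ring[b];
    if (ring[b]) { atom_ring[g.bfrom[b]] = true; atom_ring[g.bto[b]] = true; }
  }
  return List::create(_["bond_ring"] = bond_ring, _["atom_ring"] = atom_ring);
}

static int rotatable_of_graph(const Graph &g) {
  // Single, non-ring bonds between heavy atoms where neither end is terminal,
  // excluding amide C-N (carbon double-bonded to oxygen).
  int n = g.natoms(), nb = g.nbonds();
  std::vector<int> degree(n, 0);
  std::vector<bool> has_dbO(n, false);
  for (int b = 0; b < nb; ++b) {
    degree[g.bfrom[b]]++; degree[g.bto[b]]++;
    if (g.border[b] == 2) {
      if (g.z[g.bfrom[b]] == 6 && g.z[g.bto[b]] == 8) has_dbO[g.bfrom[b]] = true;
      if (g.z[g.bto[b]] == 6 && g.z[g.bfrom[b]] == 8) has_dbO[g.bto[b]] = true;
    }
  }
  std::vector<bool> ring = ring_bonds(g);
  int count = 0;
  for (int b = 0; b < nb; ++b) {
    if (g.border[b] != 1 || ring[b]) continue;
    int i = g.bfrom[b], j = g.bto[b];
    if (degree[i] < 2 || degree[j] < 2) continue;
    bool amide = (g.z[i] == 6 && has_dbO[i] && g.z[j] == 7) ||
                 (g.z[j] == 6 && has_dbO[j] && g.z[i] == 7);
    if (amide) continue;
    ++count;
  }
  return count;
}

// [[Rcpp::export]]
int cpp_rotatable_count(IntegerVector z, IntegerVector charge, IntegerVector nh,
                        IntegerVector inring, IntegerVector bfrom, IntegerVector bto,
                        IntegerVector border) {
  Graph g = graph_from_vectors(z, charge, nh, inring, bfrom, bto, border);
  return rotatable_of_graph(g);
}

// ---- synthon library assembly ----------------------------------------------
// Fragments arrive as a list of graphs plus junction annotations:
//   acyl_c  index (1-based) of the carboxyl carbon usable for acylation (0 = none)
//   acyl_o  index of the hydroxyl oxygen removed on amide formation
//   amine_n index of the primary amine nitrogen usable as coupling partner
// A product row (a, b, c) couples a's acid to b's amine and b's acid to c's
// amine; b = 0 denotes a two-component a-c amide.

struct FragSet {
  std::vector<Graph> frags;
  std::vector<int> acyl_c, acyl_o, amine_n; // 0-based, -1 = absent
};

static FragSet fragset_from_list(List fragments) {
  FragSet fs;
  int nf = fragments.size();
  fs.frags.resize(nf);
  fs.acyl_c.resize(nf); fs.acyl_o.resize(nf); fs.amine_n.resize(nf);
  for (int f = 0; f < nf; ++f) {
    List fr = fragments[f];
    fs.frags[f] = graph_from_vectors(fr["z"], fr["charge"], fr["nh"], fr["inring"],
                                     fr["bfrom"], fr["bto"], fr["border"]);
    fs.acyl_c[f] = as<int>(fr["acyl_c"]) - 1;
    fs.acyl_o[f] = as<int>(fr["acyl_o"]) - 1;
    fs.amine_n[f] = as<int>(fr["amine_n"]) - 1;
  }
  return fs;
}

// Append fragment `f` to graph `g`. If as_acyl, drop the carboxyl OH oxygen
// (the atom leaves as water); if as_amine, the amine nitrogen loses one H.
// Returns the new 0-based indices of the fragment's junction atoms.
static void append_fragment(Graph &g, const Graph &fr, int acyl_o,
                            bool amine_end, int amine_n,
                            std::vector<int> &newidx) {
  int n = fr.natoms();
  newidx.assign(n, -1);
  int base = g.natoms();
  for (int i = 0; i < n; ++i) {
    if (i == acyl_o) continue; // removed with the leaving water
    newidx[i] = (int)g.z.size();
    g.z.push_back(fr.z[i]);
    g.charge.push_back(fr.charge[i]);
    int nh = fr.nh[i];
    if (amine_end && i == amine_n) nh -= 1;
    g.nh.push_back(nh);
    g.inring.push_back(fr.inring[i]);
  }
  (void)base;
  for (int b = 0; b < fr.nbonds(); ++b) {
    int i = fr.bfrom[b], j = fr.bto[b];
    if (i == acyl_o || j == acyl_o) continue;
    g.bfrom.push_back(newidx[i]);
    g.bto.push_back(newidx[j]);
    g.border.push_back(fr.border[b]);
  }
}

static Graph assemble_product(const FragSet &fs, int a, int b, int c) {
  Graph g;
  std::vector<int> idxA, idxB, idxC;
  append_fragment(g, fs.frags[a], fs.acyl_o[a], false, -1, idxA);
  int left_acyl = idxA[fs.acyl_c[a]];
  if (b >= 0) {
    append_fragment(g, fs.frags[b], fs.acyl_o[b], true, fs.amine_n[b], idxB);
    g.bfrom.push_back(left_acyl);
    g.bto.push_back(idxB[fs.amine_n[b]]);
    g.border.push_back(1);
    left_acyl = idxB[fs.acyl_c[b]];
  }
  append_fragment(g, fs.frags[c], -1, true, fs.amine_n[c], idxC);
  g.bfrom.push_back(left_acyl);
  g.bto.push_back(idxC[fs.amine_n[c]]);
  g.border.push_back(1);
  return g;
}

// [[Rcpp::export]]
List cpp_assemble_graph(List fragments, int a, int b, int c) {
  FragSet fs = fragset_from_list(fragments);
  Graph g = assemble_product(fs, a - 1, b - 1, c - 1); // b = 0 -> -1 (pair)
  int nb = g.nbonds();
  IntegerVector bfrom(nb), bto(nb);
  for (int k = 0; k < nb; ++k) { bfrom[k] = g.bfrom[k] + 1; bto[k] = g.bto[k] + 1; }
  return List::create(
    _["z"] = IntegerVector(g.z.begin(), g.z.end()),
    _["charge"] = IntegerVector(g.charge.begin(), g.charge.end()),
    _["nh"] = IntegerVector(g.nh.begin(), g.nh.end()),
    _["inring"] = IntegerVector(g.inring.begin(), g.inring.end()),
    _["bfrom"] = bfrom, _["bto"] = bto,
    _["border"] = IntegerVector(g.border.begin(), g.border.end()));
}

// Batch fingerprints for library molecules: returns sparse triplets
// (row = molecule, col = bit + 1) for building a dgCMatrix.
// [[Rcpp::export]]
List cpp_library_fp(List fragments, IntegerMatrix comp, int radius, int nbits) {
  FragSet fs = fragset_from_list(fragments);
  int n = comp.nrow();
  std::vector<int> rows, cols, bits;
  rows.reserve(n * 64); cols.reserve(n * 64);
  for (int m = 0; m < n; ++m) {
    Graph g = assemble_product(fs, comp(m, 0) - 1, comp(m, 1) - 1, comp(m, 2) - 1);
    fp_bits_of_graph(g, radius, nbits, bits);
    for (size_t k = 0; k < bits.size(); ++k) {
      rows.push_back(m + 1);
      cols.push_back(bits[k] + 1);
    }
  }
  return List::create(_["i"] = IntegerVector(rows.begin(), rows.end()),
                      _["j"] = IntegerVector(cols.begin(), cols.end()));
}

// Batch rotatable-bond counts for library molecules.
// [[Rcpp::export]]
IntegerVector cpp_library_rotatable(List fragments, IntegerMatrix comp) {
  FragSet fs = fragset_from_list(fragments);
  int n = comp.nrow();
  IntegerVector out(n);
  for (int m = 0; m < n; ++m) {
    Graph g = assemble_product(fs, comp(m, 0) - 1, comp(m, 1) - 1, comp(m, 2) - 1);
    out[m] = rotatable_of_graph(g);
  }
  return out;
}

// ---- Tanimoto / leader selection -------------------------------------------

static double tanimoto_sorted(const std::vector<int> &a, const std::vector<int> &b) {
  if (a.empty() && b.empty()) return 0.0; // 0/0 defined as 0
  size_t i = 0, j = 0, inter = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] == b[j]) { ++inter; ++i; ++j; }
    else if (a[i] < b[j]) ++i;
    else ++j;
  }
  size_t uni = a.size() + b.size() - inter;
  return (double)inter / (double)uni;
}

// [[Rcpp::export]]
double cpp_tanimoto(IntegerVector a, IntegerVector b) {
  std::vector<int> va(a.begin(), a.end()), vb(b.begin(), b.end());
  std::sort(va.begin(), va.end()); std::sort(vb.begin(), vb.end());
  return tanimoto_sorted(va, vb);
}

// Leader (sphere-exclusion) selection over the given order: keep a record iff
// its maximum Tanimoto similarity to all previously kept records is below
// `threshold`. max_keep <= 0 means no cap.
// [[Rcpp::export]]
IntegerVector cpp_leader_select(List fps, double threshold, int max_keep) {
  int n = fps.size();
  std::vector<std::vector<int> > sets(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = fps[i];
    sets[i] = std::vector<int>(v.begin(), v.end());
    std::sort(sets[i].begin(), sets[i].end());
  }
  std::vector<int> kept;
  for (int i = 0; i < n; ++i) {
    bool ok = true;
    for (size_t k = 0; k < kept.size(); ++k) {
      if (tanimoto_sorted(sets[i], sets[kept[k]]) >= threshold) { ok = false; break; }
    }
    if (ok) {
      kept.push_back(i);
      if (max_keep > 0 && (int)kept.size() >= max_keep) break;
    }
  }
  IntegerVector out(kept.size());
  for (size_t k = 0; k < kept.size(); ++k) out[k] = kept[k] + 1;
  return out;
}

// Leader selection against a pre-existing reference set: a candidate is kept
// iff its maximum Tanimoto to every reference fingerprint AND every
// previously kept candidate stays below `threshold`.
// [[Rcpp::export]]
IntegerVector cpp_leader_select_ref(List fps, List ref, double threshold,
                                    int max_keep) {
  int n = fps.size(), m = ref.size();
  std::vector<std::vector<int> > sets(n), refsets(m);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = fps[i];
    sets[i] = std::vector<int>(v.begin(), v.end());
    std::sort(sets[i].begin(), sets[i].end());
  }
  for (int i = 0; i < m; ++i) {
    IntegerVector v = ref[i];
    refsets[i] = std::vector<int>(v.begin(), v.end());
    std::sort(refsets[i].begin(), refsets[i].end());
  }
  std::vector<int> kept;
  for (int i = 0; i < n; ++i) {
    bool ok = true;
    for (int k = 0; k < m && ok; ++k) {
      if (tanimoto_sorted(sets[i], refsets[k]) >= threshold) ok = false;
    }
    for (size_t k = 0; k < kept.size() && ok; ++k) {
      if (tanimoto_sorted(sets[i], sets[kept[k]]) >= threshold) ok = false;
    }
    if (ok) {
      kept.push_back(i);
      if (max_keep > 0 && (int)kept.size() >= max_keep) break;
    }
  }
  IntegerVector out(kept.size());
  for (size_t k = 0; k < kept.size(); ++k) out[k] = kept[k] + 1;
  return out;
}
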