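#include <Rcpp.h>
using namespace Rcpp;

// The population genotype store is a pair of raw matrices with loci as rows
// and individuals as columns, so that every per-individual operation
// (gamete formation, newborn writes, migrant transfer) touches contiguous
// memory.  Allele states are coded 0 (reference / recipient-diagnostic),
// 1 (alternate / source-diagnostic), 2 (mutant, absorbing).

namespace {

// Byte-mask stream: Mendelian transmission needs one fair bit per locus per
// gamete (~10^6 per simulated year at full scale), far too many to draw one
// at a time from R's RNG.  A xorshift64* generator is therefore seeded from
// R's RNG once per offspring batch — keeping every run fully reproducible
// from the R seed — and its words are expanded to 0x00/0xFF selector bytes.
struct MaskStream {
  uint64_t state;
  MaskStream() {
    const uint64_t hi = static_cast<uint64_t>(unif_rand() * 4294967296.0);
    const uint64_t lo = static_cast<uint64_t>(unif_rand() * 4294967296.0);
    state = (hi << 32) ^ lo;
    if (state == 0) state = 0x9E3779B97F4A7C15ULL;
  }
  inline uint64_t next_word() {
    uint64_t x = state;
    x ^= x >> 12;
    x ^= x << 25;
    x ^= x >> 27;
    state = x;
    return x * 0x2545F4914F6CDD1DULL;
  }
  void fill(unsigned char* buf, int n) {
    int i = 0;
    while (i < n) {
      uint64_t w = next_word();
      const int take = (n - i < 64) ? n - i : 64;
      for (int k = 0; k < take; ++k) {
        buf[i + k] = static_cast<unsigned char>(-(int)(w & 1u));
        w >>= 1;
      }
      i += take;
    }
  }
};

inline Rbyte* col_ptr(RawMatrix& g, int col) {
  return RAW(g) + (R_xlen_t)col * g.nrow();
}
inline const Rbyte* col_ptr(const RawMatrix& g, int col) {
  return RAW(g) + (R_xlen_t)col * g.nrow();
}

void check_cols(const IntegerVector& cols, int nc, const char* what) {
  for (int i = 0; i < cols.size(); ++i)
    if (cols[i] < 1 || cols[i] > nc) stop("%s out of range", what);
}

}  // namespace

// Draw founder allele copies in place: for every listed individual column,
// locus j gets state 1 with probability p[j] (p == 0 rows left at the
// reference state, p == 1 rows set deterministically).
// [[Rcpp::export(name = ".fill_founder_alleles")]]
void fill_founder_alleles(RawMatrix g, const IntegerVector& ind_cols,
                          const NumericVector& p) {
  const int L = g.nrow();
  if (p.size() != L) stop("p must have one entry per locus");
  check_cols(ind_cols, g.ncol(), "individual column");
  for (int i = 0; i < ind_cols.size(); ++i) {
    Rbyte* col = col_ptr(g, ind_cols[i] - 1);
    for (int j = 0; j < L; ++j) {
      if (p[j] <= 0) col[j] = 0;
      else if (p[j] >= 1) col[j] = 1;
      else col[j] = unif_rand() < p[j] ? 1 : 0;
    }
  }
}

// Mendelian offspring, written in place: offspring k receives one gamete
// from mother_cols[k] into g1[, dest_cols[k]] and one from father_cols[k]
// into g2[, dest_cols[k]]; at every locus the transmitted copy is chosen
// from the parent's two copies by a fair coin, independently across loci.
// [[Rcpp::export(name = ".make_offspring")]]
void make_offspring(RawMatrix g1, RawMatrix g2,
                    const IntegerVector& mother_cols,
                    const IntegerVector& father_cols,
                    const IntegerVector& dest_cols) {
  const int L = g1.nrow();
  const int b = dest_cols.size();
  if (mother_cols.size() != b || father_cols.size() != b)
    stop("parent and destination lists must have equal length");
  if (g2.nrow() != L || g2.ncol() != g1.ncol())
    stop("allele matrices must have identical dimensions");
  check_cols(mother_cols, g1.ncol(), "mother column");
  check_cols(father_cols, g1.ncol(), "father column");
  check_cols(dest_cols, g1.ncol(), "destination column");
  std::vector<unsigned char> mask(L);
  MaskStream ms;
  for (int k = 0; k < b; ++k) {
    const int dest = dest_cols[k] - 1;
    for (int side = 0; side < 2; ++side) {
      const int par = (side == 0 ? mother_cols[k] : father_cols[k]) - 1;
      const Rbyte* c1 = col_ptr(g1, par);
      const Rbyte* c2 = col_ptr(g2, par);
      Rbyte* out = col_ptr(side == 0 ? g1 : g2, dest);
      ms.fill(mask.data(), L);
      for (int j = 0; j < L; ++j)
        out[j] = c1[j] ^ (mask[j] & (c1[j] ^ c2[j]));
    }
  }
}

// Per-locus allele-state tallies over an individual subset: allele-copy
// counts per state (3 x L), counts of individuals carrying exactly one copy
// of each state (3 x L, the Weir-Cockerham heterozygote frequencies), and
// heterozygous-individual counts (L).
// [[Rcpp::export(name = ".locus_state_counts", rng = false)]]
List locus_state_counts(const RawMatrix& g1, const RawMatrix& g2,
                        const IntegerVector& ind_cols,
                        const IntegerVector& locus_rows) {
  const int n = ind_cols.size();
  const int L = locus_rows.size();
  check_cols(ind_cols, g1.ncol(), "individual column");
  for (int j = 0; j < L; ++j)
    if (locus_rows[j] < 1 || locus_rows[j] > g1.nrow())
      stop("locus row out of range");
  IntegerMatrix cnt(3, L), het1(3, L);
  IntegerVector nhet(L);
  // accumulate individual-by-individual: each pass reads two contiguous
  // columns and updates small L1-resident flat counter arrays
  std::vector<int> cs(3 * (size_t)L, 0), hs(3 * (size_t)L, 0), hh(L, 0);
  for (int i = 0; i < n; ++i) {
    const Rbyte* a = col_ptr(g1, ind_cols[i] - 1);
    const Rbyte* b = col_ptr(g2, ind_cols[i] - 1);
    for (int j = 0; j < L; ++j) {
      const int r = locus_rows[j] - 1;
      const unsigned int x = a[r];
      const unsigned int y = b[r];
      if (x > 2 || y > 2) stop("allele states must be 0, 1 or 2");
      ++cs[(size_t)x * L + j];
      ++cs[(size_t)y * L + j];
      if (x != y) {
        ++hh[j];
        ++hs[(size_t)x * L + j];
        ++hs[(size_t)y * L + j];
      }
    }
  }
  for (int j = 0; j < L; ++j) {
    for (int s = 0; s < 3; ++s) {
      cnt(s, j) = cs[(size_t)s * L + j];
      het1(s, j) = hs[(size_t)s * L + j];
    }
    nhet[j] = hh[j];
  }
  return List::create(_["cnt"] = cnt, _["het1"] = het1,
                      _["nhet"] = nhet, _["n"] = n);
}

// Per-individual mutant load over a locus subset: mutated allele copies and
// homozygous-mutant loci.
// [[Rcpp::export(name = ".mutant_load_counts", rng = false)]]
IntegerMatrix mutant_load(const RawMatrix& g1, const RawMatrix& g2,
                          const IntegerVector& ind_cols,
                          const IntegerVector& locus_rows) {
  const int n = ind_cols.size();
  const int L = locus_rows.size();
  check_cols(ind_cols, g1.ncol(), "individual column");
  IntegerMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    const Rbyte* a = col_ptr(g1, ind_cols[i] - 1);
    const Rbyte* b = col_ptr(g2, ind_cols[i] - 1);
    int copies = 0, hom = 0;
    for (int j = 0; j < L; ++j) {
      const int r = locus_rows[j] - 1;
      const bool m1 = a[r] == 2;
      const bool m2 = b[r] == 2;
      copies += (m1 ? 1 : 0) + (m2 ? 1 : 0);
      if (m1 && m2) ++hom;
    }
    out(i, 0) = copies;
    out(i, 1) = hom;
  }
  return out;
}

// In-place column copy between stores (migrant transfer: genotypes move
// verbatim).
// [[Rcpp::export(name = ".copy_columns", rng = false)]]
void copy_columns(const RawMatrix& src, const IntegerVector& src_cols,
                  RawMatrix dst, const IntegerVector& dst_cols) {
  const int L = src.nrow();
  if (dst.nrow() != L) stop("stores have differing locus counts");
  const int k = src_cols.size();
  if (dst_cols.size() != k) stop("column lists must have equal length");
  check_cols(src_cols, src.ncol(), "source column");
  check_cols(dst_cols, dst.ncol(), "destination column");
  for (int i = 0; i < k; ++i)
    std::copy(col_ptr(src, src_cols[i] - 1), col_ptr(src, src_cols[i] - 1) + L,
              col_ptr(dst, dst_cols[i] - 1));
}

// In-place scatter write g[locus_rows[i], ind_cols[i]] <- value (mutation).
// [[Rcpp::export(name = ".set_cells", rng = false)]]
void set_cells(RawMatrix g, const IntegerVector& locus_rows,
               const IntegerVector& ind_cols, int value) {
  const int k = locus_rows.size();
  if (ind_cols.size() != k) stop("index vectors must have equal length");
  check_cols(ind_cols, g.ncol(), "individual column");
  for (int i = 0; i < k; ++i) {
    const int r = locus_rows[i] - 1;
    if (r < 0 || r >= g.nrow()) stop("locus row out of range");
    col_ptr(g, ind_cols[i] - 1)[r] = static_cast<Rbyte>(value);
  }
}
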