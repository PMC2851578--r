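#include <Rcpp.h>
#include <cstring>
#include <cstdint>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Forward-in-time drift phase.
//
// Haplotypes are bit-packed (64 loci per word) during the drift loop:
// a recombinant gamete is (A & ~M) | (B & M) where the strand mask M is
// built by toggling a suffix mask at every crossover, mutation is a bit
// flip, and per-individual heterozygosity is popcount(A ^ B).  All
// randomness goes through R's RNG so that set.seed() in R gives
// bit-identical populations.

namespace {

inline int popcount64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
    return __builtin_popcountll(x);
#else
    int c = 0;
    while (x) { x &= x - 1; ++c; }
    return c;
#endif
}

struct Layout {
    int n_chrom, lpc;          // loci per chromosome
    int wpc;                   // words per chromosome
    int W;                     // words per haplotype
    Layout(int nc, int l) : n_chrom(nc), lpc(l),
        wpc((l + 63) / 64), W(nc * ((l + 63) / 64)) {}
};

// Toggle all bits of chromosome block `m` from bit position `cut` on.
inline void toggle_suffix(uint64_t* m, int wpc, int cut) {
    int w = cut >> 6, b = cut & 63;
    if (w >= wpc) return;
    m[w] ^= ~0ULL << b;
    for (int k = w + 1; k < wpc; ++k) m[k] = ~m[k];
}

// Sample one gamete from a parent's two haplotypes into `out`.
// Per chromosome: crossover count Poisson(1) (chromosomes are 1 Morgan),
// positions uniform with no interference, starting strand Bernoulli(0.5);
// the strand switches at the first locus with genetic position > p.
inline void sample_gamete_bits(const uint64_t* hapA, const uint64_t* hapB,
                               const Layout& lay, uint64_t* out,
                               uint64_t* mask_buf) {
    for (int c = 0; c < lay.n_chrom; ++c) {
        const int off = c * lay.wpc;
        uint64_t* m = mask_buf;
        std::memset(m, 0, lay.wpc * sizeof(uint64_t));
        int ncx = (int) R::rpois(1.0);
        for (int k = 0; k < ncx; ++k) {
            int cut = (int) std::floor(unif_rand() * lay.lpc) + 1;
            if (cut < lay.lpc) toggle_suffix(m, lay.wpc, cut);
        }
        if (unif_rand() < 0.5)                 // start on strand B
            for (int k = 0; k < lay.wpc; ++k) m[k] = ~m[k];
        const uint64_t* A = hapA + off;
        const uint64_t* B = hapB + off;
        uint64_t* o = out + off;
        for (int k = 0; k < lay.wpc; ++k)
            o[k] = (A[k] & ~m[k]) | (B[k] & m[k]);
    }
}

// Flip alleles at a Poisson(u*L) number of uniform positions.
inline void mutate_bits(uint64_t* hap, const Layout& lay, double u) {
    if (u <= 0.0) return;
    const double L = (double) lay.n_chrom * lay.lpc;
    int nmut = (int) R::rpois(u * L);
    for (int k = 0; k < nmut; ++k) {
        int pos = (int) std::floor(unif_rand() * L);
        if (pos >= (int) L) pos = (int) L - 1;
        int c = pos / lay.lpc, l = pos % lay.lpc;
        hap[c * lay.wpc + (l >> 6)] ^= 1ULL << (l & 63);
    }
}

inline void pack_row(const IntegerMatrix& m, int row, const Layout& lay,
                     uint64_t* out) {
    std::memset(out, 0, lay.W * sizeof(uint64_t));
    for (int c = 0; c < lay.n_chrom; ++c)
        for (int l = 0; l < lay.lpc; ++l)
            if (m(row, c * lay.lpc + l))
                out[c * lay.wpc + (l >> 6)] |= 1ULL << (l & 63);
}

inline void unpack_row(const uint64_t* hap, const Layout& lay,
                       IntegerMatrix& m, int row) {
    for (int c = 0; c < lay.n_chrom; ++c)
        for (int l = 0; l < lay.lpc; ++l)
            m(row, c * lay.lpc + l) =
                (hap[c * lay.wpc + (l >> 6)] >> (l & 63)) & 1ULL;
}

} // namespace

// [[Rcpp::export]]
List drift_phase_cpp(IntegerMatrix base_alleles, int n_generations,
                     double mutation_rate, int n_chromosomes,
                     int loci_per_chromosome, bool allow_selfing) {
    const int H = base_alleles.nrow();      // haplotypes (2N)
    const int L = base_alleles.ncol();
    const int N = H / 2;                    // individuals
    if (H % 2 != 0) stop("haplotype count must be even");
    if (L != n_chromosomes * loci_per_chromosome)
        stop("locus count does not match chromosome layout");
    const Layout lay(n_chromosomes, loci_per_chromosome);

    std::vector<uint64_t> cur((size_t) H * lay.W), nxt((size_t) H * lay.W);
    for (int h = 0; h < H; ++h)
        pack_row(base_alleles, h, lay, cur.data() + (size_t) h * lay.W);
    std::vector<uint64_t> mask_buf(lay.wpc);

    // ordering of haplotypes within the current generation: haplotypes
    // 2i, 2i+1 of individual i live at cur + ord[2i]*W, ord[2i+1]*W
    std::vector<int> ord(H), nord(H);
    for (int h = 0; h < H; ++h) ord[h] = h;

    NumericVector het(n_generations);

    for (int g = 0; g < n_generations; ++g) {
        // each parent contributes exactly two gametes
        for (int i = 0; i < N; ++i) {
            const uint64_t* hapA = cur.data() + (size_t) ord[2 * i] * lay.W;
            const uint64_t* hapB = cur.data() + (size_t) ord[2 * i + 1] * lay.W;
            for (int k = 0; k < 2; ++k) {
                uint64_t* out = nxt.data() + (size_t)(2 * i + k) * lay.W;
                sample_gamete_bits(hapA, hapB, lay, out, mask_buf.data());
                mutate_bits(out, lay, mutation_rate);
            }
        }
        // random union of the 2N gametes into N offspring (Fisher-Yates
        // with R's RNG); gamete 2i+k descends from parent i
        for (int h = 0; h < H; ++h) nord[h] = h;
        for (int h = H - 1; h > 0; --h) {
            int j = (int) std::floor(unif_rand() * (h + 1));
            if (j > h) j = h;
            std::swap(nord[h], nord[j]);
        }
        if (!allow_selfing) {
            // repair pairs whose two gametes share a parent
            for (int i = 0; i < N; ++i) {
                int guard = 0;
                while (nord[2 * i] / 2 == nord[2 * i + 1] / 2 && guard++ < 1000) {
                    int j = (int) std::floor(unif_rand() * H);
                    if (j >= H) j = H - 1;
                    if (j == 2 * i || j == 2 * i + 1) continue;
                    std::swap(nord[2 * i + 1], nord[j]);
                }
            }
        }
        cur.swap(nxt);
        std::swap(ord, nord);

        // mean observed heterozygosity of the new generation
        double tot = 0.0;
        for (int i = 0; i < N; ++i) {
            const uint64_t* a = cur.data() + (size_t) ord[2 * i] * lay.W;
            const uint64_t* b = cur.data() + (size_t) ord[2 * i + 1] * lay.W;
            int cnt = 0;
            for (int w = 0; w < lay.W; ++w) cnt += popcount64(a[w] ^ b[w]);
            tot += cnt;
        }
        het[g] = tot / ((double) N * (double) L);
        if (g % 256 == 0) Rcpp::checkUserInterrupt();
    }

    IntegerMatrix out(H, L);
    for (int h = 0; h < H; ++h)
        unpack_row(cur.data() + (size_t) ord[h] * lay.W, lay, out, h);
    return List::create(_["alleles"] = out, _["heterozygosity"] = het);
}

// Mean per-individual heterozygosity (fraction of loci where the two
// haplotypes of an individual differ).  Rows 2i-1, 2i belong to individual i.
// [[Rcpp::export]]
double observed_het_cpp(IntegerMatrix alleles) {
    const int H = alleles.nrow(), L = alleles.ncol();
    if (H % 2 != 0) stop("haplotype count must be even");
    const int N = H / 2;
    double tot = 0.0;
    for (int i = 0; i < N; ++i) {
        int cnt = 0;
        for (int l = 0; l < L; ++l)
            cnt += (alleles(2 * i, l) != alleles(2 * i + 1, l));
        tot += cnt;
    }
    return tot / ((double) N * (double) L);
}
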