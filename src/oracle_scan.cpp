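#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

// Exhaustive ungapped alignment of fixed-length reads against a small genome.
// Guarantees recovery of every placement with <= max_mismatch substitutions:
// a placement with <= k mismatches must contain at least one of k+1 disjoint
// seeds with zero mismatches (pigeonhole), so exact seed lookups followed by
// full Hamming verification enumerate all valid placements. Falls back to a
// full scan when reads are too short to carve k+1 seeds of length >= 2.

static inline int base2code(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1; // N and friends: never matches
    }
}

static inline char revcomp_base(char c) {
    switch (c) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': return 'A';
    default: return 'N';
    }
}

static std::string revcomp(const std::string& s) {
    std::string r(s.rbegin(), s.rend());
    for (size_t i = 0; i < r.size(); ++i) r[i] = revcomp_base(r[i]);
    return r;
}

// Hamming distance with early exit once limit is exceeded; returns limit + 1
// if the true distance is larger than limit. Non-ACGT positions always
// mismatch.
static inline int hamming_capped(const char* g, const char* r, int w, int limit) {
    int m = 0;
    for (int i = 0; i < w; ++i) {
        if (g[i] != r[i]) {
            if (++m > limit) return limit + 1;
        }
    }
    return m;
}

struct SeedIndex {
    int s;                  // seed length
    std::vector<std::vector<int> > buckets; // 4^s position lists
    bool valid;
};

static SeedIndex build_index(const std::string& genome, int s) {
    SeedIndex idx;
    idx.s = s;
    idx.valid = (s >= 2 && s <= 12 && (int)genome.size() >= s);
    if (!idx.valid) return idx;
    size_t nb = (size_t)1 << (2 * s);
    idx.buckets.assign(nb, std::vector<int>());
    int L = (int)genome.size();
    // rolling 2-bit code; restart after non-ACGT
    uint32_t code = 0, mask = (uint32_t)(nb - 1);
    int run = 0;
    for (int i = 0; i < L; ++i) {
        int b = base2code(genome[i]);
        if (b < 0) { run = 0; code = 0; continue; }
        code = ((code << 2) | (uint32_t)b) & mask;
        if (++run >= s) idx.buckets[code].push_back(i - s + 1);
    }
    return idx;
}

struct Placement {
    int pos;      // 0-based start on forward genome
    bool fwd;
    int nm;
};

// collect all placements with <= k mismatches of one oriented read sequence
static void scan_oriented(const std::string& genome, const SeedIndex& idx,
                          const std::string& seq, int k, bool fwd,
                          std::vector<int>& stamp, int tick,
                          int& best, std::vector<Placement>& hits) {
    int L = (int)genome.size();
    int w = (int)seq.size();
    if (w > L) return;
    const char* g = genome.c_str();
    const char* r = seq.c_str();
    int maxpos = L - w;

    if (!idx.valid || idx.s * (k + 1) > w) {
        // full scan fallback; only placements at the running best mismatch
        // count can become reported co-optimal placements, so cap there
        for (int p = 0; p <= maxpos; ++p) {
            int limit = best < k ? best : k;
            int m = hamming_capped(g + p, r, w, limit);
            if (m <= limit) {
                if (m < best) best = m;
                hits.push_back(Placement{p, fwd, m});
            }
        }
        return;
    }

    int s = idx.s;
    uint32_t mask = ((uint32_t)1 << (2 * s)) - 1;
    int nseeds = k + 1;
    for (int j = 0; j < nseeds; ++j) {
        int off = j * s;
        uint32_t code = 0;
        bool ok = true;
        for (int i = 0; i < s; ++i) {
            int b = base2code(r[off + i]);
            if (b < 0) { ok = false; break; }
            code = (code << 2) | (uint32_t)b;
        }
        if (!ok) continue;
        const std::vector<int>& bucket = idx.buckets[code & mask];
        for (size_t h = 0; h < bucket.size(); ++h) {
            int p = bucket[h] - off;
            if (p < 0 || p > maxpos) continue;
            // encode strand in the stamp key so forward/reverse dedupe separately
            int key = fwd ? p : (p + L + 1);
            if (stamp[key] == tick) continue;
            stamp[key] = tick;
            int limit = best < k ? best : k;
            int m = hamming_capped(g + p, r, w, limit);
            if (m <= limit) {
                if (m < best) best = m;
                hits.push_back(Placement{p, fwd, m});
            }
        }
    }
}

// [[Rcpp::export(name = ".oracle_scan_cpp")]]
List oracle_scan_cpp(CharacterVector reads, std::string genome, int max_mismatch) {
    int n = reads.size();
    int L = (int)genome.size();
    if (L == 0) stop("empty genome sequence");

    // seed length from the shortest read
    int minw = INT32_MAX;
    for (int i = 0; i < n; ++i) {
        int w = LENGTH(STRING_ELT(reads, i));
        if (w < minw) minw = w;
        if (w > L)
            stop("read %d is longer (%d bp) than the genome (%d bp)", i + 1, w, L);
    }
    if (n == 0) minw = 0;
    int s = (max_mismatch >= 0 && n > 0) ? minw / (max_mismatch + 1) : 0;
    if (s > 12) s = 12;
    SeedIndex idx = build_index(genome, s);

    std::vector<int> stamp(2 * (size_t)L + 2, -1);

    std::vector<int> out_read, out_pos, out_nm, out_nh;
    std::vector<int> out_fwd;

    for (int i = 0; i < n; ++i) {
        std::string seq = as<std::string>(reads[i]);
        std::string rc = revcomp(seq);
        int best = max_mismatch + 1;
        std::vector<Placement> hits;
        scan_oriented(genome, idx, seq, max_mismatch, true, stamp, 2 * i, best, hits);
        scan_oriented(genome, idx, rc, max_mismatch, false, stamp, 2 * i + 1, best, hits);
        if (hits.empty()) {
            out_read.push_back(i + 1);
            out_pos.push_back(NA_INTEGER);
            out_fwd.push_back(NA_INTEGER);
            out_nm.push_back(NA_INTEGER);
            out_nh.push_back(0);
            continue;
        }
        int nh = 0;
        for (size_t h = 0; h < hits.size(); ++h)
            if (hits[h].nm == best) ++nh;
        for (size_t h = 0; h < hits.size(); ++h) {
            if (hits[h].nm != best) continue;
            out_read.push_back(i + 1);
            out_pos.push_back(hits[h].pos + 1); // 1-based
            out_fwd.push_back(hits[h].fwd ? 1 : 0);
            out_nm.push_back(best);
            out_nh.push_back(nh);
        }
    }

    return List::create(
        _["read"] = wrap(out_read),
        _["pos"] = wrap(out_pos),
        _["forward"] = wrap(out_fwd),
        _["nm"] = wrap(out_nm),
        _["nh"] = wrap(out_nh));
}
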