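#ifndef SMEMCACHE_CORE_H
#define SMEMCACHE_CORE_H

#include <cstdint>
#include <vector>
#include <string>
#include <memory>
#include <unordered_map>
#include <stdexcept>

namespace smem {

// Bidirectional suffix-array interval: k = SA start for pattern P,
// l = SA start for revcomp(P), s = interval size (occurrence count).
// s == -1 marks an UNKNOWN (lazily filled) trie node.
struct BiInterval {
    int64_t k, l, s;
};

struct Segment {
    int64_t text_start;  // start of segment in forward half of index text
    int64_t orig_start;  // start in original concatenated reference coords
    int64_t len;
};

// FMD-style FM-index over segments + their reverse complements.
// Text alphabet: 0 sentinel (final, unique), 1 separator (after every
// segment in both halves), 2..5 = A,C,G,T. Patterns over A..T can never
// span a separator, so interval sizes equal strand-aware occurrence counts.
class FmdIndex {
public:
    static const int CP = 128;           // occurrence checkpoint spacing

    int64_t n = 0;                        // total text length (2*half + 1)
    int64_t half = 0;                     // length of forward half
    int d = 32;                           // SA sampling interval (text positions)
    int64_t ref_len = 0;                  // original concatenated reference length
    std::vector<uint8_t> bwt;             // BWT symbols (0..5)
    std::vector<int64_t> ckpt;            // 6 counts per checkpoint row
    int64_t C[7] = {0};                   // C[c] = # symbols < c in text
    std::vector<uint8_t> samp_mark;       // rank is sampled
    std::vector<int64_t> samp_pos;        // SA value at sampled ranks (-1 elsewhere)
    std::vector<Segment> segs;

    void build(const std::vector<std::string>& seg_seqs,
               const std::vector<int64_t>& orig_starts,
               int64_t ref_len_, int d_);
    void finish();  // rebuild ckpt + C from bwt (used by build and restore)

    static int comp4(int b) { return 3 - b; }  // A<->T, C<->G over codes 0..3

    BiInterval whole() const { return BiInterval{0, 0, n}; }
    BiInterval base_interval(int b) const {
        return BiInterval{C[b + 2], C[comp4(b) + 2], C[b + 3] - C[b + 2]};
    }

    void occ6(int64_t pos, int64_t out[6]) const;
    int64_t occ1(uint8_t c, int64_t pos) const;

    BiInterval extend_back(const BiInterval& iv, int b) const;  // P -> bP
    BiInterval extend_fwd(const BiInterval& iv, int b) const;   // P -> Pb

    int64_t sal(int64_t rank) const;  // text position of rank-th suffix
    // Map an occurrence (text position, match length) to forward-strand
    // coordinates in the original reference. Returns true for reverse strand.
    bool map_occ(int64_t tpos, int64_t len, int64_t* orig_pos) const;
};

struct OpCounters {
    int64_t bwt_queries = 0, bwt_real = 0;
    int64_t sal_queries = 0, sal_real = 0;
};

struct SeedingParams {
    int min_intv = 1;         // initial SAI-size threshold
    int min_seed_len = 19;    // minimum seed length kept
    double reseed_r = 1.5;    // re-seeding trigger factor
    int64_t max_occ = 500;    // per-match SAL cap
    int batch_size = 512;     // reads per cache batch
};

struct SstNode {
    int32_t ch[4];
    int32_t parent;
    int8_t label;             // base code on edge from parent
    BiInterval iv;            // s == -1 => UNKNOWN
};

// Forward + backward SMEM search tries. Forward trie nodes spell the
// pattern root->node (child edge = forward extension). Backward trie
// nodes spell the reverse of the root->node path (child edge = backward
// extension, i.e. prepending the edge base).
class Sst {
public:
    const FmdIndex* idx = nullptr;
    OpCounters* cnt = nullptr;
    std::vector<SstNode> fwd, bwd;

    void init(const FmdIndex* idx_, OpCounters* cnt_) {
        idx = idx_; cnt = cnt_; reset();
    }
    void reset();

    // Extend pattern of `node` rightwards by base b; cache miss touches the
    // FM-index once. Returns child handle; *out gets the child interval.
    int32_t forward_query(int32_t node, int b, BiInterval* out);
    // Insert match string (len bases) in reverse character order; terminal
    // interval set from `iv` (known from the forward stage). No FM access.
    int32_t backward_insert(const uint8_t* s, int len, const BiInterval& iv);
    // Prepend base b to pattern of `node`; resolves UNKNOWN nodes lazily.
    int32_t backward_query(int32_t node, int b, BiInterval* out);
    void resolve_backward(int32_t node);  // fill UNKNOWN via known ancestor

private:
    int32_t new_node(std::vector<SstNode>& pool, int32_t parent, int8_t label);
};

struct SmemRec {
    int qbeg, qend;
    BiInterval iv;
    bool from_reseed;
};

struct SeedRec {
    int qbeg, qend;
    int64_t rbeg;
    int64_t intv_size;
    bool rev;
    bool from_reseed;
};

// Extension provider: SuperMEM1 talks to the index only through this, so
// the SST (or a plain pass-through) can interpose.
struct Handle {
    BiInterval iv;
    int32_t node;
};

class Accessor {
public:
    virtual ~Accessor() {}
    virtual Handle fwd_root(int b) = 0;                       // single-base start
    virtual Handle fwd_child(const Handle& h, int b) = 0;     // append b
    virtual Handle bwd_start(const uint8_t* s, int len,
                             const BiInterval& iv) = 0;       // locate match
    virtual Handle bwd_child(const Handle& h, int b) = 0;     // prepend b
};

class DirectAccessor : public Accessor {
public:
    const FmdIndex* idx;
    OpCounters* cnt;
    DirectAccessor(const FmdIndex* i, OpCounters* c) : idx(i), cnt(c) {}
    Handle fwd_root(int b) override { return Handle{idx->base_interval(b), -1}; }
    Handle fwd_child(const Handle& h, int b) override {
        cnt->bwt_queries++; cnt->bwt_real++;
        return Handle{idx->extend_fwd(h.iv, b), -1};
    }
    Handle bwd_start(const uint8_t*, int, const BiInterval& iv) override {
        return Handle{iv, -1};
    }
    Handle bwd_child(const Handle& h, int b) override {
        cnt->bwt_queries++; cnt->bwt_real++;
        return Handle{idx->extend_back(h.iv, b), -1};
    }
};

class SstAccessor : public Accessor {
public:
    Sst* sst;
    explicit SstAccessor(Sst* s) : sst(s) {}
    Handle fwd_root(int b) override {
        return Handle{sst->fwd[b + 1].iv, b + 1};
    }
    Handle fwd_child(const Handle& h, int b) override {
        BiInterval iv;
        int32_t c = sst->forward_query(h.node, b, &iv);
        return Handle{iv, c};
    }
    Handle bwd_start(const uint8_t* s, int len, const BiInterval& iv) override {
        int32_t nd = sst->backward_insert(s, len, iv);
        return Handle{sst->bwd[nd].iv, nd};
    }
    Handle bwd_child(const Handle& h, int b) override {
        BiInterval iv;
        int32_t c = sst->backward_query(h.node, b, &iv);
        return Handle{iv, c};
    }
};

class Seeder {
public:
    const FmdIndex* idx = nullptr;
    SeedingParams p;
    bool use_sst = true;
    bool sal_merge = true;
    OpCounters cnt;
    Sst sst;
    std::unordered_map<int64_t, int64_t> sal_memo;
    std::unique_ptr<Accessor> acc;
    int64_t reads_done = 0;
    int64_t batches_reset = 0;

    void init(const FmdIndex* idx_, const SeedingParams& p_,
              bool use_sst_, bool sal_merge_);

    std::vector<SmemRec> super_mem1(const uint8_t* q, int len, int pivot,
                                    int64_t min_intv);
    // Full per-read SMEM collection: sweep + re-seeding + dedup + length
    // filter; `q` may contain code 4 (N): split into segments internally.
    std::vector<SmemRec> collect_read(const uint8_t* q, int len);
    std::vector<SeedRec> seed_read(const uint8_t* q, int len,
                                   std::vector<SmemRec>* smems_out = nullptr);
    int64_t sal_lookup(int64_t rank);
    void end_read();  // batch accounting + cache reset at batch boundary

private:
    void collect_segment(const uint8_t* seg, int len, int off,
                         std::vector<SmemRec>& pool);
};

int base_code(char c);          // ACGT(acgt) -> 0..3, N/other -> 4
char code_base(int b);

}  // namespace smem

#endif
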