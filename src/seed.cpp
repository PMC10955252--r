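#include "core.h"
#include <algorithm>
#include <set>

namespace smem {

// ---------------------------------------------------------------- Sst

int32_t Sst::new_node(std::vector<SstNode>& pool, int32_t parent, int8_t label) {
    SstNode nd;
    nd.ch[0] = nd.ch[1] = nd.ch[2] = nd.ch[3] = -1;
    nd.parent = parent;
    nd.label = label;
    nd.iv = BiInterval{0, 0, -1};
    pool.push_back(nd);
    return (int32_t)pool.size() - 1;
}

void Sst::reset() {
    fwd.clear();
    bwd.clear();
    for (std::vector<SstNode>* pool : {&fwd, &bwd}) {
        int32_t root = new_node(*pool, -1, -1);
        (*pool)[root].iv = idx->whole();
        for (int b = 0; b < 4; ++b) {
            int32_t c = new_node(*pool, root, (int8_t)b);
            (*pool)[root].ch[b] = c;
            (*pool)[c].iv = idx->base_interval(b);
        }
    }
}

int32_t Sst::forward_query(int32_t node, int b, BiInterval* out) {
    cnt->bwt_queries++;
    int32_t c = fwd[node].ch[b];
    if (c >= 0 && fwd[c].iv.s >= 0) {
        *out = fwd[c].iv;  // cache hit
        return c;
    }
    if (c < 0) {
        c = new_node(fwd, node, (int8_t)b);
        fwd[node].ch[b] = c;
    }
    cnt->bwt_real++;
    fwd[c].iv = idx->extend_fwd(fwd[node].iv, b);
    *out = fwd[c].iv;
    return c;
}

int32_t Sst::backward_insert(const uint8_t* s, int len, const BiInterval& iv) {
    int32_t cur = 0;
    for (int j = len - 1; j >= 0; --j) {
        int b = s[j];
        int32_t c = bwd[cur].ch[b];
        if (c < 0) {
            c = new_node(bwd, cur, (int8_t)b);
            bwd[cur].ch[b] = c;
        }
        cur = c;
    }
    if (bwd[cur].iv.s < 0) bwd[cur].iv = iv;
    return cur;
}

void Sst::resolve_backward(int32_t node) {
    if (bwd[node].iv.s >= 0) return;
    // climb to the nearest known ancestor, then fill top-down; each fill
    // is one real backward BWT-extend.
    std::vector<int32_t> path;
    int32_t a = node;
    while (bwd[a].iv.s < 0) {
        path.push_back(a);
        a = bwd[a].parent;
    }
    for (auto it = path.rbegin(); it != path.rend(); ++it) {
        int32_t nd = *it;
        cnt->bwt_real++;
        bwd[nd].iv = idx->extend_back(bwd[bwd[nd].parent].iv, bwd[nd].label);
    }
}

int32_t Sst::backward_query(int32_t node, int b, BiInterval* out) {
    cnt->bwt_queries++;
    resolve_backward(node);
    int32_t c = bwd[node].ch[b];
    if (c >= 0 && bwd[c].iv.s >= 0) {
        *out = bwd[c].iv;
        return c;
    }
    if (c < 0) {
        c = new_node(bwd, node, (int8_t)b);
        bwd[node].ch[b] = c;
    }
    cnt->bwt_real++;
    bwd[c].iv = idx->extend_back(bwd[node].iv, b);
    *out = bwd[c].iv;
    return c;
}

// ---------------------------------------------------------------- Seeder

void Seeder::init(const FmdIndex* idx_, const SeedingParams& p_,
                  bool use_sst_, bool sal_merge_) {
    idx = idx_;
    p = p_;
    use_sst = use_sst_;
    sal_merge = sal_merge_;
    if (use_sst) {
        sst.init(idx, &cnt);
        acc.reset(new SstAccessor(&sst));
    } else {
        acc.reset(new DirectAccessor(idx, &cnt));
    }
}

std::vector<SmemRec> Seeder::super_mem1(const uint8_t* q, int len, int pivot,
                                        int64_t min_intv) {
    std::vector<SmemRec> out;
    if (min_intv < 1) min_intv = 1;
    if (pivot < 0 || pivot >= len || q[pivot] > 3) return out;

    Handle cur = acc->fwd_root(q[pivot]);
    if (cur.iv.s < min_intv) return out;

    // Forward stage: extend right from the pivot base, recording an exact
    // match each time the interval size changes; stop below min_intv or at
    // the read end.
    struct Cand { Handle h; int qend; };
    std::vector<Cand> cands;
    int i;
    for (i = pivot + 1; i < len; ++i) {
        if (q[i] > 3) { cands.push_back(Cand{cur, i}); break; }  // defensive
        Handle nx = acc->fwd_child(cur, q[i]);
        if (nx.iv.s != cur.iv.s) {
            cands.push_back(Cand{cur, i});
            if (nx.iv.s < min_intv) break;
        }
        cur = nx;
    }
    if (i == len) cands.push_back(Cand{cur, len});
    std::reverse(cands.begin(), cands.end());  // longest first

    // Backward stage: extend all retained matches leftwards in lockstep,
    // emitting a match when it can no longer extend and no longer match
    // survived the same step (containment rule).
    struct BState { Handle h; int qend; };
    std::vector<BState> prev, curn;
    prev.reserve(cands.size());
    for (auto& c : cands)
        prev.push_back(BState{acc->bwd_start(q + pivot, c.qend - pivot, c.h.iv),
                              c.qend});
    int last_qbeg = -1;
    bool have_mem = false;
    for (i = pivot - 1; i >= -1; --i) {
        int b = (i >= 0 && q[i] <= 3) ? q[i] : -1;
        curn.clear();
        for (auto& st : prev) {
            Handle ext;
            bool ok = false;
            if (b >= 0) {
                ext = acc->bwd_child(st.h, b);
                ok = ext.iv.s >= min_intv;
            }
            if (!ok) {
                if (curn.empty() && (!have_mem || i + 1 < last_qbeg)) {
                    out.push_back(SmemRec{i + 1, st.qend, st.h.iv, false});
                    have_mem = true;
                    last_qbeg = i + 1;
                }
            } else if (curn.empty() || ext.iv.s != curn.back().h.iv.s) {
                curn.push_back(BState{ext, st.qend});
            }
        }
        if (curn.empty()) break;
        std::swap(prev, curn);
    }
    return out;
}

void Seeder::collect_segment(const uint8_t* seg, int len, int off,
                             std::vector<SmemRec>& pool) {
    // Pass 1: sweep the segment with the initial min_intv; next pivot is
    // one past the right end of the longest SMEM of the round.
    std::vector<SmemRec> first;
    int x = 0;
    while (x < len) {
        std::vector<SmemRec> sm = super_mem1(seg, len, x, p.min_intv);
        if (sm.empty()) { ++x; continue; }
        int best = 0;
        for (size_t j = 1; j < sm.size(); ++j)
            if (sm[j].qend - sm[j].qbeg > sm[best].qend - sm[best].qbeg)
                best = (int)j;
        int next_x = sm[best].qend;
        for (auto& m : sm)
            if (m.qend - m.qbeg >= p.min_seed_len) first.push_back(m);
        x = next_x > x ? next_x : x + 1;
    }
    // Pass 2: re-seed ultra-long SMEMs at their middle base with a raised
    // min_intv to recover occurrences hidden inside them.
    std::vector<SmemRec> extra;
    for (auto& m : first) {
        if ((double)(m.qend - m.qbeg) >= p.min_seed_len * p.reseed_r) {
            int mid = (m.qbeg + m.qend) / 2;
            std::vector<SmemRec> rs = super_mem1(seg, len, mid, m.iv.s + 1);
            for (auto& r : rs)
                if (r.qend - r.qbeg >= p.min_seed_len) {
                    r.from_reseed = true;
                    extra.push_back(r);
                }
        }
    }
    for (auto& m : first) { m.qbeg += off; m.qend += off; pool.push_back(m); }
    for (auto& m : extra) { m.qbeg += off; m.qend += off; pool.push_back(m); }
}

std::vector<SmemRec> Seeder::collect_read(const uint8_t* q, int len) {
    std::vector<SmemRec> pool;
    int i = 0;
    while (i < len) {
        if (q[i] > 3) { ++i; continue; }
        int j = i;
        while (j < len && q[j] <= 3) ++j;
        collect_segment(q + i, j - i, i, pool);
        i = j;
    }
    // dedup by (qbeg, qend); first occurrence (sweep before re-seed) wins
    std::sort(pool.begin(), pool.end(), [](const SmemRec& a, const SmemRec& b) {
        if (a.qbeg != b.qbeg) return a.qbeg < b.qbeg;
        if (a.qend != b.qend) return a.qend < b.qend;
        return a.from_reseed < b.from_reseed;
    });
    std::vector<SmemRec> out;
    for (auto& m : pool)
        if (out.empty() || out.back().qbeg != m.qbeg || out.back().qend != m.qend)
            out.push_back(m);
    return out;
}

int64_t Seeder::sal_lookup(int64_t rank) {
    cnt.sal_queries++;
    if (sal_merge) {
        auto it = sal_memo.find(rank);
        if (it != sal_memo.end()) return it->second;
        cnt.sal_real++;
        int64_t pos = idx->sal(rank);
        sal_memo.emplace(rank, pos);
        return pos;
    }
    cnt.sal_real++;
    return idx->sal(rank);
}

std::vector<SeedRec> Seeder::seed_read(const uint8_t* q, int len,
                                       std::vector<SmemRec>* smems_out) {
    std::vector<SmemRec> smems = collect_read(q, len);
    if (smems_out) *smems_out = smems;
    std::vector<SeedRec> seeds;
    for (auto& m : smems) {
        if (m.iv.s > p.max_occ) continue;  // over-occurring match skipped
        int64_t mlen = m.qend - m.qbeg;
        for (int64_t r = m.iv.k; r < m.iv.k + m.iv.s; ++r) {
            int64_t tpos = sal_lookup(r);
            int64_t orig;
            bool rev = idx->map_occ(tpos, mlen, &orig);
            seeds.push_back(SeedRec{m.qbeg, m.qend, orig, m.iv.s, rev,
                                    m.from_reseed});
        }
    }
    std::sort(seeds.begin(), seeds.end(), [](const SeedRec& a, const SeedRec& b) {
        if (a.qbeg != b.qbeg) return a.qbeg < b.qbeg;
        if (a.rbeg != b.rbeg) return a.rbeg < b.rbeg;
        if (a.qend != b.qend) return a.qend < b.qend;
        return a.rev < b.rev;
    });
    return seeds;
}

void Seeder::end_read() {
    reads_done++;
    if ((use_sst || sal_merge) && reads_done % p.batch_size == 0) {
        if (use_sst) sst.reset();
        sal_memo.clear();
        batches_reset++;
    }
}

}  // namespace smem
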