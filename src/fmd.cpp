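#include "core.h"
#include <algorithm>

namespace smem {

int base_code(char c) {
    switch (c) {
        case 'A': case 'a': return 0;
        case 'C': case 'c': return 1;
        case 'G': case 'g': return 2;
        case 'T': case 't': return 3;
        default: return 4;
    }
}

char code_base(int b) {
    static const char* bases = "ACGT";
    return (b >= 0 && b < 4) ? bases[b] : 'N';
}

// Prefix-doubling suffix array; fine at the scales this package targets.
static std::vector<int64_t> suffix_array(const std::vector<uint8_t>& t) {
    int64_t n = (int64_t)t.size();
    std::vector<int64_t> sa(n), rnk(n), tmp(n);
    for (int64_t i = 0; i < n; ++i) { sa[i] = i; rnk[i] = t[i]; }
    for (int64_t k = 1;; k <<= 1) {
        auto cmp = [&](int64_t a, int64_t b) {
            if (rnk[a] != rnk[b]) return rnk[a] < rnk[b];
            int64_t ra = a + k < n ? rnk[a + k] : -1;
            int64_t rb = b + k < n ? rnk[b + k] : -1;
            return ra < rb;
        };
        std::sort(sa.begin(), sa.end(), cmp);
        tmp[sa[0]] = 0;
        for (int64_t i = 1; i < n; ++i)
            tmp[sa[i]] = tmp[sa[i - 1]] + (cmp(sa[i - 1], sa[i]) ? 1 : 0);
        rnk = tmp;
        if (rnk[sa[n - 1]] == n - 1) break;
    }
    return sa;
}

void FmdIndex::build(const std::vector<std::string>& seg_seqs,
                     const std::vector<int64_t>& orig_starts,
                     int64_t ref_len_, int d_) {
    if (seg_seqs.empty())
        throw std::runtime_error("no indexable (non-N) sequence in reference");
    if (d_ < 1) throw std::runtime_error("sa_sample_interval must be >= 1");
    d = d_;
    ref_len = ref_len_;
    segs.clear();

    // forward half: seg1 SEP seg2 SEP ... segm SEP
    std::vector<uint8_t> text;
    int64_t total = 0;
    for (const auto& s : seg_seqs) total += (int64_t)s.size();
    half = total + (int64_t)seg_seqs.size();
    n = 2 * half + 1;
    text.reserve(n);
    for (size_t i = 0; i < seg_seqs.size(); ++i) {
        Segment sg;
        sg.text_start = (int64_t)text.size();
        sg.orig_start = orig_starts[i];
        sg.len = (int64_t)seg_seqs[i].size();
        if (sg.len == 0)
            throw std::runtime_error("empty reference segment");
        segs.push_back(sg);
        for (char c : seg_seqs[i]) {
            int b = base_code(c);
            if (b > 3) throw std::runtime_error("non-ACGT base inside segment");
            text.push_back((uint8_t)(b + 2));
        }
        text.push_back(1);  // separator
    }
    // reverse half: reverse complement of the forward half (separators fixed)
    for (int64_t i = half - 1; i >= 0; --i) {
        uint8_t c = text[i];
        text.push_back(c >= 2 ? (uint8_t)(7 - c) : c);  // complement base symbols
    }
    text.push_back(0);  // sentinel

    std::vector<int64_t> sa = suffix_array(text);
    bwt.assign(n, 0);
    samp_mark.assign(n, 0);
    samp_pos.assign(n, -1);
    for (int64_t i = 0; i < n; ++i) {
        int64_t p = sa[i];
        bwt[i] = text[(p + n - 1) % n];
        if (p % d == 0) { samp_mark[i] = 1; samp_pos[i] = p; }
    }
    finish();
}

void FmdIndex::finish() {
    int64_t rows = n / CP + 1;
    ckpt.assign(rows * 6, 0);
    int64_t run[6] = {0};
    for (int64_t i = 0; i < n; ++i) {
        if (i % CP == 0)
            for (int c = 0; c < 6; ++c) ckpt[(i / CP) * 6 + c] = run[c];
        run[bwt[i]]++;
    }
    if (n % CP == 0)
        for (int c = 0; c < 6; ++c) ckpt[(n / CP) * 6 + c] = run[c];
    C[0] = 0;
    for (int c = 0; c < 6; ++c) C[c + 1] = C[c] + run[c];
}

void FmdIndex::occ6(int64_t pos, int64_t out[6]) const {
    int64_t cp = pos / CP;
    for (int c = 0; c < 6; ++c) out[c] = ckpt[cp * 6 + c];
    for (int64_t i = cp * CP; i < pos; ++i) out[bwt[i]]++;
}

int64_t FmdIndex::occ1(uint8_t c, int64_t pos) const {
    int64_t cp = pos / CP;
    int64_t o = ckpt[cp * 6 + c];
    for (int64_t i = cp * CP; i < pos; ++i)
        if (bwt[i] == c) o++;
    return o;
}

BiInterval FmdIndex::extend_back(const BiInterval& iv, int b) const {
    int64_t ok[6], ol[6], cnt[6];
    occ6(iv.k, ok);
    occ6(iv.k + iv.s, ol);
    for (int a = 0; a < 6; ++a) cnt[a] = ol[a] - ok[a];
    // Intervals of revcomp(P)x partition [l, l+s) in follower order
    // sentinel/separator < A < C < G < T; follower x pairs with prepended
    // base comp(x), and |revcomp(P)x| = |comp(x)P| = cnt[comp(x)].
    int64_t l0 = iv.l + cnt[0] + cnt[1];
    int64_t ls[4];
    ls[3] = l0;                 // prepend T (follower A)
    ls[2] = ls[3] + cnt[5];     // prepend G (follower C)
    ls[1] = ls[2] + cnt[4];     // prepend C (follower G)
    ls[0] = ls[1] + cnt[3];     // prepend A (follower T)
    int sym = b + 2;
    return BiInterval{C[sym] + ok[sym], ls[b], cnt[sym]};
}

BiInterval FmdIndex::extend_fwd(const BiInterval& iv, int b) const {
    BiInterval sw{iv.l, iv.k, iv.s};
    BiInterval r = extend_back(sw, comp4(b));
    return BiInterval{r.l, r.k, r.s};
}

int64_t FmdIndex::sal(int64_t rank) const {
    if (rank < 0 || rank >= n)
        throw std::runtime_error("suffix array rank out of range");
    int64_t r = rank, t = 0;
    while (!samp_mark[r]) {
        uint8_t c = bwt[r];
        r = C[c] + occ1(c, r);
        ++t;
    }
    return samp_pos[r] + t;
}

bool FmdIndex::map_occ(int64_t tpos, int64_t len, int64_t* orig_pos) const {
    bool rev = tpos >= half;
    int64_t f = rev ? (2 * half - tpos - len) : tpos;
    // binary search for segment containing f
    size_t lo = 0, hi = segs.size();
    while (hi - lo > 1) {
        size_t mid = (lo + hi) / 2;
        if (segs[mid].text_start <= f) lo = mid; else hi = mid;
    }
    const Segment& sg = segs[lo];
    if (f < sg.text_start || f + len > sg.text_start + sg.len)
        throw std::runtime_error("occurrence does not map inside a segment");
    *orig_pos = sg.orig_start + (f - sg.text_start);
    return rev;
}

}  // namespace smem
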