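#include <Rcpp.h>
#include "core.h"

using namespace Rcpp;
using smem::FmdIndex;
using smem::BiInterval;
using smem::Seeder;
using smem::SeedingParams;

static BiInterval as_interval(const NumericVector& iv) {
    if (iv.size() != 3) stop("interval must be a numeric vector (k, l, s)");
    return BiInterval{(int64_t)iv[0], (int64_t)iv[1], (int64_t)iv[2]};
}

static NumericVector wrap_interval(const BiInterval& iv) {
    NumericVector out = NumericVector::create(
        _["k"] = (double)iv.k, _["l"] = (double)iv.l, _["s"] = (double)iv.s);
    return out;
}

static std::vector<uint8_t> encode_read(const std::string& s) {
    std::vector<uint8_t> q(s.size());
    for (size_t i = 0; i < s.size(); ++i) q[i] = (uint8_t)smem::base_code(s[i]);
    return q;
}

// [[Rcpp::export]]
SEXP fmd_build_cpp(CharacterVector segs, NumericVector orig_starts,
                   double ref_len, int sa_interval) {
    std::vector<std::string> ss;
    std::vector<int64_t> os;
    for (int i = 0; i < segs.size(); ++i) {
        ss.push_back(as<std::string>(segs[i]));
        os.push_back((int64_t)orig_starts[i]);
    }
    XPtr<FmdIndex> xp(new FmdIndex(), true);
    xp->build(ss, os, (int64_t)ref_len, sa_interval);
    return xp;
}

// [[Rcpp::export]]
List fmd_info_cpp(SEXP xp_) {
    XPtr<FmdIndex> xp(xp_);
    return List::create(_["n"] = (double)xp->n, _["half"] = (double)xp->half,
                        _["sa_interval"] = xp->d,
                        _["n_segments"] = (int)xp->segs.size(),
                        _["ref_len"] = (double)xp->ref_len);
}

// [[Rcpp::export]]
NumericVector fmd_whole_cpp(SEXP xp_) {
    XPtr<FmdIndex> xp(xp_);
    return wrap_interval(xp->whole());
}

// [[Rcpp::export]]
NumericVector fmd_base_interval_cpp(SEXP xp_, int base) {
    XPtr<FmdIndex> xp(xp_);
    if (base < 0 || base > 3) stop("base code must be 0..3");
    return wrap_interval(xp->base_interval(base));
}

// [[Rcpp::export]]
NumericVector fmd_extend_cpp(SEXP xp_, NumericVector interval, int base,
                             bool forward) {
    XPtr<FmdIndex> xp(xp_);
    if (base < 0 || base > 3) stop("base code must be 0..3");
    BiInterval iv = as_interval(interval);
    if (iv.s < 0) stop("cannot extend an interval with negative size");
    BiInterval r = forward ? xp->extend_fwd(iv, base) : xp->extend_back(iv, base);
    return wrap_interval(r);
}

// [[Rcpp::export]]
NumericVector fmd_sal_cpp(SEXP xp_, NumericVector ranks) {
    XPtr<FmdIndex> xp(xp_);
    NumericVector out(ranks.size());
    for (int i = 0; i < ranks.size(); ++i)
        out[i] = (double)xp->sal((int64_t)ranks[i]);
    return out;
}

// [[Rcpp::export]]
List fmd_map_cpp(SEXP xp_, NumericVector tpos, NumericVector len) {
    XPtr<FmdIndex> xp(xp_);
    int m = tpos.size();
    NumericVector pos(m);
    LogicalVector rev(m);
    for (int i = 0; i < m; ++i) {
        int64_t op;
        rev[i] = xp->map_occ((int64_t)tpos[i], (int64_t)len[i], &op);
        pos[i] = (double)op;
    }
    return List::create(_["pos"] = pos, _["rev"] = rev);
}

// [[Rcpp::export]]
List fmd_sampled_cpp(SEXP xp_) {
    XPtr<FmdIndex> xp(xp_);
    std::vector<double> rk, pv;
    for (int64_t i = 0; i < xp->n; ++i)
        if (xp->samp_mark[i]) { rk.push_back((double)i); pv.push_back((double)xp->samp_pos[i]); }
    return List::create(_["rank"] = wrap(rk), _["pos"] = wrap(pv));
}

// [[Rcpp::export]]
List fmd_dump_cpp(SEXP xp_) {
    XPtr<FmdIndex> xp(xp_);
    RawVector bw(xp->n);
    for (int64_t i = 0; i < xp->n; ++i) bw[i] = xp->bwt[i];
    std::vector<double> rk, pv;
    for (int64_t i = 0; i < xp->n; ++i)
        if (xp->samp_mark[i]) { rk.push_back((double)i); pv.push_back((double)xp->samp_pos[i]); }
    int m = (int)xp->segs.size();
    NumericVector ts(m), os(m), ln(m);
    for (int i = 0; i < m; ++i) {
        ts[i] = (double)xp->segs[i].text_start;
        os[i] = (double)xp->segs[i].orig_start;
        ln[i] = (double)xp->segs[i].len;
    }
    return List::create(
        _["n"] = (double)xp->n, _["half"] = (double)xp->half,
        _["sa_interval"] = xp->d, _["ref_len"] = (double)xp->ref_len,
        _["bwt"] = bw, _["samp_rank"] = wrap(rk), _["samp_pos"] = wrap(pv),
        _["seg_text_start"] = ts, _["seg_orig_start"] = os, _["seg_len"] = ln);
}

// [[Rcpp::export]]
SEXP fmd_restore_cpp(List dump) {
    XPtr<FmdIndex> xp(new FmdIndex(), true);
    xp->n = (int64_t)as<double>(dump["n"]);
    xp->half = (int64_t)as<double>(dump["half"]);
    xp->d = as<int>(dump["sa_interval"]);
    xp->ref_len = (int64_t)as<double>(dump["ref_len"]);
    RawVector bw = dump["bwt"];
    if ((int64_t)bw.size() != xp->n || xp->n != 2 * xp->half + 1 || xp->n < 3)
        stop("corrupt index payload: inconsistent text length");
    xp->bwt.resize(xp->n);
    int64_t counts[6] = {0};
    for (int64_t i = 0; i < xp->n; ++i) {
        if (bw[i] > 5) stop("corrupt index payload: invalid BWT symbol");
        xp->bwt[i] = bw[i];
        counts[bw[i]]++;
    }
    if (counts[0] != 1) stop("corrupt index payload: sentinel count != 1");
    NumericVector rk = dump["samp_rank"], pv = dump["samp_pos"];
    if (rk.size() != pv.size() || rk.size() == 0)
        stop("corrupt index payload: bad suffix-array samples");
    xp->samp_mark.assign(xp->n, 0);
    xp->samp_pos.assign(xp->n, -1);
    for (int i = 0; i < rk.size(); ++i) {
        int64_t r = (int64_t)rk[i], p = (int64_t)pv[i];
        if (r < 0 || r >= xp->n || p < 0 || p >= xp->n || p % xp->d != 0)
            stop("corrupt index payload: bad suffix-array sample entry");
        xp->samp_mark[r] = 1;
        xp->samp_pos[r] = p;
    }
    NumericVector ts = dump["seg_text_start"], os = dump["seg_orig_start"],
                  ln = dump["seg_len"];
    if (ts.size() == 0) stop("corrupt index payload: no segments");
    for (int i = 0; i < ts.size(); ++i)
        xp->segs.push_back(smem::Segment{(int64_t)ts[i], (int64_t)os[i],
                                         (int64_t)ln[i]});
    xp->finish();
    return xp;
}

// ------------------------------------------------------------- seeder

// The seeder holds a raw pointer into the index; the R wrapper object keeps
// the index XPtr alive alongside the seeder XPtr.

// [[Rcpp::export]]
SEXP seeder_new_cpp(SEXP xp_idx, List params, bool cache, bool sal_merge) {
    XPtr<FmdIndex> xi(xp_idx);
    SeedingParams p;
    p.min_intv = as<int>(params["min_intv"]);
    p.min_seed_len = as<int>(params["min_seed_len"]);
    p.reseed_r = as<double>(params["reseed_r"]);
    p.max_occ = (int64_t)as<double>(params["max_occ"]);
    p.batch_size = as<int>(params["batch_size"]);
    if (p.reseed_r <= 1.0) stop("reseed_r must be > 1");
    if (p.min_seed_len < 1) stop("min_seed_len must be >= 1");
    if (p.batch_size < 1) stop("batch_size must be >= 1");
    if (p.min_intv < 1) stop("min_intv must be >= 1");
    XPtr<Seeder> xp(new Seeder(), true);
    xp->init(xi.get(), p, cache, sal_merge);
    return xp;
}

// [[Rcpp::export]]
List seeder_counters_cpp(SEXP xp_) {
    XPtr<Seeder> xp(xp_);
    return List::create(
        _["bwt_queries"] = (double)xp->cnt.bwt_queries,
        _["bwt_real"] = (double)xp->cnt.bwt_real,
        _["sal_queries"] = (double)xp->cnt.sal_queries,
        _["sal_real"] = (double)xp->cnt.sal_real,
        _["reads_done"] = (double)xp->reads_done,
        _["batches_reset"] = (double)xp->batches_reset);
}

// [[Rcpp::export]]
void seeder_reset_batch_cpp(SEXP xp_) {
    XPtr<Seeder> xp(xp_);
    if (xp->use_sst) xp->sst.reset();
    xp->sal_memo.clear();
}

static DataFrame smems_df(const std::vector<smem::SmemRec>& sm) {
    int m = (int)sm.size();
    IntegerVector qb(m), qe(m);
    NumericVector k(m), l(m), s(m);
    CharacterVector org(m);
    for (int i = 0; i < m; ++i) {
        qb[i] = sm[i].qbeg; qe[i] = sm[i].qend;
        k[i] = (double)sm[i].iv.k; l[i] = (double)sm[i].iv.l;
        s[i] = (double)sm[i].iv.s;
        org[i] = sm[i].from_reseed ? "reseed" : "smem";
    }
    return DataFrame::create(_["qbeg"] = qb, _["qend"] = qe, _["k"] = k,
                             _["l"] = l, _["s"] = s, _["origin"] = org,
                             _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
DataFrame seeder_supermem1_cpp(SEXP xp_, std::string read, int pivot,
                               double min_intv) {
    XPtr<Seeder> xp(xp_);
    std::vector<uint8_t> q = encode_read(read);
    if (pivot < 0 || pivot >= (int)q.size()) stop("pivot outside the read");
    std::vector<smem::SmemRec> sm =
        xp->super_mem1(q.data(), (int)q.size(), pivot, (int64_t)min_intv);
    return smems_df(sm);
}

// [[Rcpp::export]]
DataFrame seeder_collect_cpp(SEXP xp_, std::string read) {
    XPtr<Seeder> xp(xp_);
    std::vector<uint8_t> q = encode_read(read);
    return smems_df(xp->collect_read(q.data(), (int)q.size()));
}

// [[Rcpp::export]]
List seeder_run_cpp(SEXP xp_, CharacterVector reads) {
    XPtr<Seeder> xp(xp_);
    std::vector<int> rid;
    std::vector<int> qb, qe;
    std::vector<double> rb, iv;
    std::vector<bool> rev, rsd;
    for (int i = 0; i < reads.size(); ++i) {
        std::vector<uint8_t> q = encode_read(as<std::string>(reads[i]));
        std::vector<smem::SeedRec> seeds = xp->seed_read(q.data(), (int)q.size());
        for (auto& sd : seeds) {
            rid.push_back(i + 1);
            qb.push_back(sd.qbeg);
            qe.push_back(sd.qend);
            rb.push_back((double)sd.rbeg);
            iv.push_back((double)sd.intv_size);
            rev.push_back(sd.rev);
            rsd.push_back(sd.from_reseed);
        }
        xp->end_read();
        if (i % 1024 == 0) Rcpp::checkUserInterrupt();
    }
    DataFrame df = DataFrame::create(
        _["read"] = wrap(rid), _["qbeg"] = wrap(qb), _["qend"] = wrap(qe),
        _["rbeg"] = wrap(rb), _["intv_size"] = wrap(iv), _["rev"] = wrap(rev),
        _["reseed"] = wrap(rsd), _["stringsAsFactors"] = false);
    return List::create(_["seeds"] = df);
}

// ------------------------------------------------------------- SST hooks

// [[Rcpp::export]]
List sst_forward_query_cpp(SEXP xp_, int node, int base) {
    XPtr<Seeder> xp(xp_);
    if (!xp->use_sst) stop("seeder was created with cache = FALSE");
    BiInterval iv;
    int32_t c = xp->sst.forward_query(node, base, &iv);
    return List::create(_["node"] = (int)c, _["interval"] = wrap_interval(iv));
}

// [[Rcpp::export]]
int sst_backward_insert_cpp(SEXP xp_, std::string match, NumericVector interval) {
    XPtr<Seeder> xp(xp_);
    if (!xp->use_sst) stop("seeder was created with cache = FALSE");
    std::vector<uint8_t> q = encode_read(match);
    for (uint8_t b : q) if (b > 3) stop("match string must be over ACGT");
    return (int)xp->sst.backward_insert(q.data(), (int)q.size(),
                                        as_interval(interval));
}

// [[Rcpp::export]]
List sst_backward_query_cpp(SEXP xp_, int node, int base) {
    XPtr<Seeder> xp(xp_);
    if (!xp->use_sst) stop("seeder was created with cache = FALSE");
    BiInterval iv;
    int32_t c = xp->sst.backward_query(node, base, &iv);
    return List::create(_["node"] = (int)c, _["interval"] = wrap_interval(iv));
}

// [[Rcpp::export]]
DataFrame sst_nodes_cpp(SEXP xp_, bool backward) {
    XPtr<Seeder> xp(xp_);
    if (!xp->use_sst) stop("seeder was created with cache = FALSE");
    const std::vector<smem::SstNode>& pool = backward ? xp->sst.bwd : xp->sst.fwd;
    int m = (int)pool.size();
    IntegerVector id(m), parent(m), ca(m), cc(m), cg(m), ct(m);
    CharacterVector label(m);
    NumericVector k(m), l(m), s(m);
    for (int i = 0; i < m; ++i) {
        id[i] = i;
        parent[i] = pool[i].parent;
        label[i] = pool[i].label < 0 ? "" : std::string(1, smem::code_base(pool[i].label));
        ca[i] = pool[i].ch[0]; cc[i] = pool[i].ch[1];
        cg[i] = pool[i].ch[2]; ct[i] = pool[i].ch[3];
        k[i] = (double)pool[i].iv.k; l[i] = (double)pool[i].iv.l;
        s[i] = (double)pool[i].iv.s;
    }
    return DataFrame::create(_["id"] = id, _["parent"] = parent,
                             _["label"] = label, _["k"] = k, _["l"] = l,
                             _["s"] = s, _["child_A"] = ca, _["child_C"] = cc,
                             _["child_G"] = cg, _["child_T"] = ct,
                             _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
double sal_resolve_cpp(SEXP xp_, double rank) {
    XPtr<Seeder> xp(xp_);
    return (double)xp->sal_lookup((int64_t)rank);
}
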