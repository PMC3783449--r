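#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for LDA.
//
// docs: integer vector of 0-based word ids, concatenated over documents
// docStart: 0-based start offset of each document; docLen: its length
// Uses R's RNG (unif_rand) so determinism is governed by set.seed() on the
// R side.  Returns the final-sweep assignment count matrices.
// [[Rcpp::export(name = ".gibbsLda")]]
List gibbsLda(IntegerVector docs, IntegerVector docStart,
              IntegerVector docLen, int K, int V,
              double alpha, double beta, int nIter) {
    int D = docStart.size();
    int N = docs.size();
    IntegerVector z(N);
    IntegerMatrix cdt(D, K);   // doc-topic counts
    IntegerMatrix cwt(V, K);   // word-topic counts
    IntegerVector ct(K);       // topic totals
    double Vbeta = V * beta;

    RNGScope scope;

    // random initialization
    for (int d = 0; d < D; ++d) {
        for (int i = 0; i < docLen[d]; ++i) {
            int idx = docStart[d] + i;
            int t = (int)(unif_rand() * K);
            if (t == K) t = K - 1;
            z[idx] = t;
            cdt(d, t)++;
            cwt(docs[idx], t)++;
            ct[t]++;
        }
    }

    std::vector<double> prob(K);
    for (int iter = 0; iter < nIter; ++iter) {
        for (int d = 0; d < D; ++d) {
            for (int i = 0; i < docLen[d]; ++i) {
                int idx = docStart[d] + i;
                int w = docs[idx];
                int t = z[idx];
                cdt(d, t)--; cwt(w, t)--; ct[t]--;
                double tot = 0.0;
                for (int k = 0; k < K; ++k) {
                    tot += (cdt(d, k) + alpha) *
                           (cwt(w, k) + beta) / (ct[k] + Vbeta);
                    prob[k] = tot;
                }
                double u = unif_rand() * tot;
                int tnew = 0;
                while (tnew < K - 1 && u > prob[tnew]) ++tnew;
                z[idx] = tnew;
                cdt(d, tnew)++; cwt(w, tnew)++; ct[tnew]++;
            }
        }
        if (iter % 50 == 0) Rcpp::checkUserInterrupt();
    }

    // collapsed joint log-likelihood of the final state, used to select
    // among restarts (merge/split local modes score far lower)
    double ll = 0.0;
    for (int k = 0; k < K; ++k) {
        ll += R::lgammafn(Vbeta) - V * R::lgammafn(beta);
        for (int w = 0; w < V; ++w)
            if (cwt(w, k) > 0)
                ll += R::lgammafn(cwt(w, k) + beta) - R::lgammafn(beta);
        ll -= R::lgammafn(ct[k] + Vbeta) - R::lgammafn(Vbeta);
    }
    double Kalpha = K * alpha;
    for (int d = 0; d < D; ++d) {
        for (int k = 0; k < K; ++k)
            if (cdt(d, k) > 0)
                ll += R::lgammafn(cdt(d, k) + alpha) - R::lgammafn(alpha);
        ll -= R::lgammafn(docLen[d] + Kalpha) - R::lgammafn(Kalpha);
    }

    return List::create(_["wordTopic"] = cwt, _["docTopic"] = cdt,
                        _["topicTotals"] = ct, _["logLik"] = ll);
}
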