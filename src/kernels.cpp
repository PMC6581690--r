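#include <Rcpp.h>
#include <string>
#include <algorithm>

using namespace Rcpp;

// Ungapped register scan and longest-common-substring kernels used by the
// specificity screens. Sequences arrive validated ({A,C,G,T}) from R.

static std::string revcomp(const std::string& s) {
    std::string out(s.rbegin(), s.rend());
    for (auto& c : out) {
        switch (c) {
        case 'A': c = 'T'; break;
        case 'C': c = 'G'; break;
        case 'G': c = 'C'; break;
        case 'T': c = 'A'; break;
        default: stop("non-ACGT character in sequence");
        }
    }
    return out;
}

// Best ungapped register of probe along one subject strand. Registers may
// overhang either subject end; identity is matches / probe length, so
// overhanging positions count as mismatches. Ties keep the smaller offset.
static void best_register(const std::string& probe, const std::string& subject,
                          int& best_matches, int& best_offset) {
    const int L = probe.size(), M = subject.size();
    best_matches = -1;
    best_offset = 0;
    for (int off = -(L - 1); off <= M - 1; ++off) {
        int i0 = std::max(0, -off);
        int i1 = std::min(L, M - off);
        int m = 0;
        for (int i = i0; i < i1; ++i)
            if (probe[i] == subject[off + i]) ++m;
        if (m > best_matches) {
            best_matches = m;
            best_offset = off;
        }
    }
}

// [[Rcpp::export(name = ".best_identity_cpp")]]
List best_identity_cpp(std::string probe, std::string subject) {
    if (probe.empty() || subject.empty())
        stop("empty sequence");
    int fwd_m, fwd_off, rev_m, rev_off;
    best_register(probe, subject, fwd_m, fwd_off);
    std::string rc = revcomp(subject);
    best_register(probe, rc, rev_m, rev_off);
    bool use_rev = rev_m > fwd_m; // forward strand wins ties
    int m = use_rev ? rev_m : fwd_m;
    int off = use_rev ? rev_off : fwd_off;
    return List::create(
        _["identity_pct"] = 100.0 * m / probe.size(),
        _["matches"] = m,
        _["subject_offset"] = off,
        _["strand"] = use_rev ? "-" : "+");
}

static int lcs_one_strand(const std::string& a, const std::string& b) {
    const int L = a.size(), M = b.size();
    std::vector<int> prev(M + 1, 0), cur(M + 1, 0);
    int best = 0;
    for (int i = 1; i <= L; ++i) {
        for (int j = 1; j <= M; ++j) {
            cur[j] = (a[i - 1] == b[j - 1]) ? prev[j - 1] + 1 : 0;
            if (cur[j] > best) best = cur[j];
        }
        std::swap(prev, cur);
    }
    return best;
}

// [[Rcpp::export(name = ".longest_stretch_cpp")]]
int longest_stretch_cpp(std::string probe, std::string subject,
                        bool both_strands = true) {
    if (probe.empty() || subject.empty())
        stop("empty sequence");
    int best = lcs_one_strand(probe, subject);
    if (both_strands)
        best = std::max(best, lcs_one_strand(probe, revcomp(subject)));
    return best;
}

// Extract the subject window aligned to the probe at a given register on a
// given strand; overhanging positions are filled with '-' (treated as
// mismatches by the free-energy model).
// [[Rcpp::export(name = ".aligned_window_cpp")]]
std::string aligned_window_cpp(std::string probe, std::string subject,
                               int offset, std::string strand) {
    const int L = probe.size();
    std::string subj = (strand == "-") ? revcomp(subject) : subject;
    const int M = subj.size();
    std::string out(L, '-');
    for (int i = 0; i < L; ++i) {
        int j = offset + i;
        if (j >= 0 && j < M) out[i] = subj[j];
    }
    return out;
}
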