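#include <Rcpp.h>
using namespace Rcpp;

// Mismatches between read and ref[off .. off+rl-1]; bails out once the count
// exceeds cap. Byte comparison: references are N-free by contract, so an 'N'
// in a read can never match and is charged as a mismatch automatically.
static inline int mismatches_at(const char *read, int rl, const char *ref,
                                int off, int cap) {
  int mm = 0;
  for (int i = 0; i < rl; ++i) {
    if (read[i] != ref[off + i]) {
      if (++mm > cap) return mm;
    }
  }
  return mm;
}

// All ungapped placements of one read (and optionally its reverse complement)
// within each reference at <= max_mismatch mismatches. Rows are emitted in the
// matcher's tie-break order: reference input order, then offset, then '+'
// before '-' at the same offset. strand is 0 for '+', 1 for '-'.
// [[Rcpp::export]]
DataFrame hits_one_read_cpp(std::string read, std::string read_rc,
                            std::vector<std::string> refs, int max_mismatch,
                            bool both_strands) {
  std::vector<int> ref_idx, offset, strand, mism;
  const int rl = (int)read.size();
  if (rl > 0) {
    for (size_t r = 0; r < refs.size(); ++r) {
      const std::string &ref = refs[r];
      const int last = (int)ref.size() - rl;
      for (int off = 0; off <= last; ++off) {
        int mm = mismatches_at(read.c_str(), rl, ref.c_str(), off, max_mismatch);
        if (mm <= max_mismatch) {
          ref_idx.push_back((int)r + 1);
          offset.push_back(off);
          strand.push_back(0);
          mism.push_back(mm);
        }
        if (both_strands) {
          mm = mismatches_at(read_rc.c_str(), rl, ref.c_str(), off, max_mismatch);
          if (mm <= max_mismatch) {
            ref_idx.push_back((int)r + 1);
            offset.push_back(off);
            strand.push_back(1);
            mism.push_back(mm);
          }
        }
      }
    }
  }
  return DataFrame::create(_["ref_idx"] = ref_idx, _["offset"] = offset,
                           _["strand"] = strand, _["mismatches"] = mism);
}

// For each read: does it place anywhere in any reference at <= max_mismatch?
// Early exit on the first hit.
// [[Rcpp::export]]
LogicalVector any_hit_cpp(std::vector<std::string> reads,
                          std::vector<std::string> reads_rc,
                          std::vector<std::string> refs, int max_mismatch,
                          bool both_strands) {
  const size_t n = reads.size();
  LogicalVector out(n);
  for (size_t i = 0; i < n; ++i) {
    const std::string &read = reads[i];
    const int rl = (int)read.size();
    bool found = false;
    if (rl > 0) {
      for (size_t r = 0; r < refs.size() && !found; ++r) {
        const std::string &ref = refs[r];
        const int last = (int)ref.size() - rl;
        for (int off = 0; off <= last && !found; ++off) {
          if (mismatches_at(read.c_str(), rl, ref.c_str(), off, max_mismatch) <=
              max_mismatch)
            found = true;
          else if (both_strands &&
                   mismatches_at(reads_rc[i].c_str(), rl, ref.c_str(), off,
                                 max_mismatch) <= max_mismatch)
            found = true;
        }
      }
    }
    out[i] = found;
  }
  return out;
}

// Best-mode read-level assignment: for each read, the reference of the first
// placement (in tie-break order) achieving the minimum mismatch count over
// all placements. ref 0 / mismatches NA when the read places nowhere.
// A 0-mismatch hit cannot be beaten, so the scan stops there.
// [[Rcpp::export]]
List best_ref_cpp(std::vector<std::string> reads,
                  std::vector<std::string> reads_rc,
                  std::vector<std::string> refs, int max_mismatch,
                  bool both_strands) {
  const size_t n = reads.size();
  IntegerVector best_ref(n, 0);
  IntegerVector best_mm(n, NA_INTEGER);
  for (size_t i = 0; i < n; ++i) {
    const std::string &read = reads[i];
    const int rl = (int)read.size();
    int bmm = max_mismatch + 1, bref = 0;
    if (rl > 0) {
      for (size_t r = 0; r < refs.size() && bmm > 0; ++r) {
        const std::string &ref = refs[r];
        const int last = (int)ref.size() - rl;
        for (int off = 0; off <= last && bmm > 0; ++off) {
          int mm = mismatches_at(read.c_str(), rl, ref.c_str(), off, bmm - 1);
          if (mm < bmm) {
            bmm = mm;
            bref = (int)r + 1;
          }
          if (both_strands && bmm > 0) {
            mm = mismatches_at(reads_rc[i].c_str(), rl, ref.c_str(), off,
                               bmm - 1);
            if (mm < bmm) {
              bmm = mm;
              bref = (int)r + 1;
            }
          }
        }
      }
    }
    if (bref > 0) {
      best_ref[i] = bref;
      best_mm[i] = bmm;
    }
  }
  return List::create(_["ref"] = best_ref, _["mismatches"] = best_mm);
}

// 3' adapter scan: leftmost offset p where the adapter prefix of length
// L = min(len(adapter), len(read) - p), L >= min_overlap, matches the read
// at p with mismatches/L <= max_error_rate. start is 0-based, NA when no
// acceptable offset exists.
// [[Rcpp::export]]
List trim_scan_cpp(std::vector<std::string> reads, std::string adapter,
                   int min_overlap, double max_error_rate) {
  const size_t n = reads.size();
  const int alen = (int)adapter.size();
  IntegerVector start(n, NA_INTEGER);
  IntegerVector errors(n, NA_INTEGER);
  for (size_t i = 0; i < n; ++i) {
    const std::string &read = reads[i];
    const int rl = (int)read.size();
    for (int p = 0; p <= rl - min_overlap; ++p) {
      const int L = std::min(alen, rl - p);
      if (L < min_overlap) break;
      const int cap = (int)(L * max_error_rate + 1e-9);
      const int mm = mismatches_at(adapter.c_str(), L, read.c_str(), p, cap);
      if (mm <= cap) {
        start[i] = p;
        errors[i] = mm;
        break;
      }
    }
  }
  return List::create(_["start"] = start, _["errors"] = errors);
}
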