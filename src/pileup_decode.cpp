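#include <Rcpp.h>
using namespace Rcpp;

// Decode the base-string column of one samtools-dialect pileup record.
//
// Symbols counted as read symbols (one aligned read each): . , ACGTacgt Nn * > <
// Attachments that do not consume a read symbol: +N<seq> -N<seq> (indel on the
// previous read), ^X (read start; X is the mapping-quality byte), $ (read end).
//
// Returns per-base substitution counts (case-collapsed), the deletion-coverage
// count (*), and the decoded indel events with their sequences.
// [[Rcpp::export]]
List decode_pileup_bases(const std::string& bases) {
  int n_symbols = 0, n_ref = 0, n_star = 0, n_skip = 0;
  // A C G T N
  IntegerVector sub(5);
  std::vector<int> ins_len, del_len;
  std::vector<std::string> ins_seq, del_seq;

  const size_t n = bases.size();
  size_t i = 0;
  while (i < n) {
    char c = bases[i];
    switch (c) {
    case '.': case ',':
      ++n_symbols; ++n_ref; ++i; break;
    case '*':
      ++n_symbols; ++n_star; ++i; break;
    case '>': case '<':
      ++n_symbols; ++n_skip; ++i; break;
    case 'A': case 'a': ++n_symbols; ++sub[0]; ++i; break;
    case 'C': case 'c': ++n_symbols; ++sub[1]; ++i; break;
    case 'G': case 'g': ++n_symbols; ++sub[2]; ++i; break;
    case 'T': case 't': ++n_symbols; ++sub[3]; ++i; break;
    case 'N': case 'n': ++n_symbols; ++sub[4]; ++i; break;
    case '^':
      if (i + 1 >= n) stop("truncated pileup base string: '^' with no mapping-quality byte");
      i += 2; break;  // ^ consumes exactly one following character
    case '$':
      ++i; break;
    case '+': case '-': {
      size_t j = i + 1, len = 0;
      while (j < n && bases[j] >= '0' && bases[j] <= '9') {
        len = len * 10 + (bases[j] - '0');
        ++j;
      }
      if (j == i + 1)
        stop("malformed pileup base string: '%s' not followed by a length at byte %d",
             std::string(1, c), (int)(i + 1));
      if (len == 0 || j + len > n)
        stop("dangling indel in pileup base string: %s%d at byte %d runs past the end",
             std::string(1, c), (int)len, (int)(i + 1));
      std::string s = bases.substr(j, len);
      for (size_t k = 0; k < len; ++k) {
        char b = toupper(s[k]);
        if (b != 'A' && b != 'C' && b != 'G' && b != 'T' && b != 'N')
          stop("non-nucleotide byte '%s' inside indel sequence at byte %d",
               std::string(1, s[k]), (int)(j + k + 1));
        s[k] = b;
      }
      if (c == '+') { ins_len.push_back((int)len); ins_seq.push_back(s); }
      else          { del_len.push_back((int)len); del_seq.push_back(s); }
      i = j + len;
      break;
    }
    default:
      stop("unknown pileup symbol '%s' (byte %d)", std::string(1, c), (int)(i + 1));
    }
  }

  sub.names() = CharacterVector::create("A", "C", "G", "T", "N");
  return List::create(
    _["n_symbols"] = n_symbols,
    _["n_ref"] = n_ref,
    _["n_star"] = n_star,
    _["n_skip"] = n_skip,
    _["sub"] = sub,
    _["ins_len"] = wrap(ins_len),
    _["ins_seq"] = wrap(ins_seq),
    _["del_len"] = wrap(del_len),
    _["del_seq"] = wrap(del_seq));
}

// Hamming distance between the first `len` bases of `seq` and `primer`;
// returns len + 1 if seq is shorter than len.
static int prefix_mismatches(const std::string& seq, const std::string& primer,
                             int len, int cap) {
  if ((int)seq.size() < len) return len + 1;
  int mm = 0;
  for (int k = 0; k < len; ++k) {
    if (seq[k] != primer[k]) {
      if (++mm > cap) return mm;
    }
  }
  return mm;
}

// Match each read prefix against a primer table.  Returns the 1-based index of
// the unique primer whose first match_len bases are within max_mismatch of the
// read's 5' prefix, 0 for no match, -1 for an ambiguous match (two primers in
// range -- impossible for a collision-validated pool).
// [[Rcpp::export]]
IntegerVector match_primers_cpp(const CharacterVector& reads,
                                const CharacterVector& primers,
                                const IntegerVector& match_len,
                                int max_mismatch) {
  const int n = reads.size(), p = primers.size();
  std::vector<std::string> prim(p);
  for (int j = 0; j < p; ++j) prim[j] = as<std::string>(primers[j]);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string r = as<std::string>(reads[i]);
    int hit = 0;
    for (int j = 0; j < p; ++j) {
      int mm = prefix_mismatches(r, prim[j], match_len[j], max_mismatch);
      if (mm <= max_mismatch) {
        if (hit) { hit = -1; break; }
        hit = j + 1;
      }
    }
    out[i] = hit;
  }
  return out;
}
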