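#include <Rcpp.h>
#include <cstring>
#include <cstdlib>
#include <fstream>
#include <string>
#include <vector>
using namespace Rcpp;

// Shared CIGAR machinery. Ops follow the SAM spec; '=' and 'X' are treated as 'M'
// for coordinate arithmetic. All contig coordinates are 0-based half-open.

struct CigOp { char op; int len; };

static std::vector<CigOp> parse_cigar(const char *c) {
  std::vector<CigOp> ops;
  int len = 0;
  for (const char *p = c; *p; ++p) {
    if (*p >= '0' && *p <= '9') {
      len = len * 10 + (*p - '0');
    } else {
      if (len <= 0 && *p != '*') stop("invalid CIGAR '%s'", c);
      if (*p == '*') return ops;
      ops.push_back({*p, len});
      len = 0;
    }
  }
  return ops;
}

static inline bool consumes_ref(char op)  { return op=='M'||op=='='||op=='X'||op=='D'||op=='N'; }
static inline bool consumes_read(char op) { return op=='M'||op=='='||op=='X'||op=='I'||op=='S'; }

//' @noRd
// [[Rcpp::export(name = ".cigar_layout")]]
DataFrame cigar_layout(CharacterVector cigar) {
  int n = cigar.size();
  IntegerVector span(n), qlen(n), clip_left(n), clip_right(n), nmatch(n);
  for (int i = 0; i < n; ++i) {
    std::vector<CigOp> ops = parse_cigar(CHAR(STRING_ELT(cigar, i)));
    int sp = 0, ql = 0, cl = 0, cr = 0, nm = 0;
    int m = (int)ops.size();
    for (int j = 0; j < m; ++j) {
      char op = ops[j].op; int l = ops[j].len;
      if (consumes_ref(op)) sp += l;
      if (consumes_read(op) || op=='H') ql += l;
      if (op=='M'||op=='='||op=='X') nm += l;
      if ((op=='S'||op=='H')) {
        bool leading = true;
        for (int k = 0; k < j; ++k) if (ops[k].op!='S'&&ops[k].op!='H') { leading = false; break; }
        if (leading) cl += l; else cr += l;
      }
    }
    span[i]=sp; qlen[i]=ql; clip_left[i]=cl; clip_right[i]=cr; nmatch[i]=nm;
  }
  return DataFrame::create(_["span"]=span, _["qlen"]=qlen,
                           _["clip_left"]=clip_left, _["clip_right"]=clip_right,
                           _["aligned_bases"]=nmatch);
}

//' Large within-alignment indels: D runs (read skips contig sequence -> expansion)
//' and I runs (read carries extra sequence -> collapse).
//' @noRd
// [[Rcpp::export(name = ".cigar_indels")]]
DataFrame cigar_indels(CharacterVector cigar, IntegerVector start0, int min_size) {
  std::vector<int> seg, pos, size;
  std::vector<std::string> kind;
  int n = cigar.size();
  for (int i = 0; i < n; ++i) {
    std::vector<CigOp> ops = parse_cigar(CHAR(STRING_ELT(cigar, i)));
    int rpos = start0[i];
    for (size_t j = 0; j < ops.size(); ++j) {
      char op = ops[j].op; int l = ops[j].len;
      if (op=='D' && l >= min_size) {
        seg.push_back(i+1); kind.push_back("expansion"); pos.push_back(rpos); size.push_back(l);
      } else if (op=='I' && l >= min_size) {
        seg.push_back(i+1); kind.push_back("collapse"); pos.push_back(rpos); size.push_back(l);
      }
      if (consumes_ref(op)) rpos += l;
    }
  }
  return DataFrame::create(_["seg"]=wrap(seg), _["kind"]=wrap(kind),
                           _["pos"]=wrap(pos), _["size"]=wrap(size),
                           _["stringsAsFactors"]=false);
}

static inline int base_idx(char b) {
  switch (b) { case 'A': case 'a': return 0; case 'C': case 'c': return 1;
               case 'G': case 'g': return 2; case 'T': case 't': return 3; }
  return -1;
}

//' Pileup counts over one contig. Returns per-position spanning-read depth,
//' per-base counts, small-deletion counts (per deleted column) and
//' small-insertion counts (per anchor: the contig base preceding the insertion).
//' Indel ops of length >= small_max are structural-scale and excluded from the
//' del/ins tallies (their columns still count as spanned).
//' @noRd
// [[Rcpp::export(name = ".pileup_core")]]
List pileup_core(std::string contig, IntegerVector start0, CharacterVector cigar,
                 CharacterVector seq, int small_max) {
  int L = (int)contig.size();
  IntegerVector depth(L), del(L), ins(L);
  IntegerMatrix bases(4, L);
  int n = cigar.size();
  for (int i = 0; i < n; ++i) {
    std::vector<CigOp> ops = parse_cigar(CHAR(STRING_ELT(cigar, i)));
    const char *s = CHAR(STRING_ELT(seq, i));
    int slen = (int)std::strlen(s);
    int rpos = start0[i], qpos = 0;
    for (size_t j = 0; j < ops.size(); ++j) {
      char op = ops[j].op; int l = ops[j].len;
      if (op=='M'||op=='='||op=='X') {
        for (int k = 0; k < l; ++k) {
          int rp = rpos + k;
          if (rp < 0 || rp >= L) continue;
          depth[rp]++;
          if (qpos + k < slen) {
            int bi = base_idx(s[qpos + k]);
            if (bi >= 0) bases(bi, rp)++;
          }
        }
        rpos += l; qpos += l;
      } else if (op=='D' || op=='N') {
        for (int k = 0; k < l; ++k) {
          int rp = rpos + k;
          if (rp < 0 || rp >= L) continue;
          depth[rp]++;
          if (op=='D' && l < small_max) del[rp]++;
        }
        rpos += l;
      } else if (op=='I') {
        if (l < small_max) {
          int anchor = rpos - 1;
          if (anchor >= start0[i] && anchor < L) ins[anchor]++;
        }
        qpos += l;
      } else if (op=='S') {
        qpos += l;
      } // H consumes neither SEQ nor ref
    }
  }
  return List::create(_["depth"]=depth, _["bases"]=bases, _["del"]=del, _["ins"]=ins);
}

//' Collect inserted sequences anchored at a set of candidate positions
//' (second pass; cand0 must be sorted ascending, 0-based).
//' @noRd
// [[Rcpp::export(name = ".insertion_events")]]
DataFrame insertion_events(IntegerVector start0, CharacterVector cigar,
                           CharacterVector seq, IntegerVector cand0, int small_max) {
  std::vector<int> outpos;
  std::vector<std::string> outseq;
  int nc = cand0.size();
  if (nc == 0)
    return DataFrame::create(_["pos"]=IntegerVector(0), _["seq"]=CharacterVector(0));
  int n = cigar.size();
  for (int i = 0; i < n; ++i) {
    std::vector<CigOp> ops = parse_cigar(CHAR(STRING_ELT(cigar, i)));
    const char *s = CHAR(STRING_ELT(seq, i));
    int slen = (int)std::strlen(s);
    int rpos = start0[i], qpos = 0;
    for (size_t j = 0; j < ops.size(); ++j) {
      char op = ops[j].op; int l = ops[j].len;
      if (op=='I' && l < small_max) {
        int anchor = rpos - 1;
        // binary search candidate set
        int lo = 0, hi = nc - 1; bool found = false;
        while (lo <= hi) { int mid=(lo+hi)/2;
          if (cand0[mid]==anchor){found=true;break;}
          if (cand0[mid]<anchor) lo=mid+1; else hi=mid-1; }
        if (found && qpos + l <= slen) {
          outpos.push_back(anchor);
          outseq.push_back(std::string(s + qpos, (size_t)l));
        }
      }
      if (consumes_ref(op)) rpos += l;
      if (consumes_read(op)) qpos += l;
    }
  }
  return DataFrame::create(_["pos"]=wrap(outpos), _["seq"]=wrap(outseq),
                           _["stringsAsFactors"]=false);
}

//' Per-position coverage from aligned segment intervals (difference array).
//' @noRd
// [[Rcpp::export(name = ".interval_depth")]]
IntegerVector interval_depth(int L, IntegerVector start0, IntegerVector end0) {
  std::vector<int> diff((size_t)L + 1, 0);
  int n = start0.size();
  for (int i = 0; i < n; ++i) {
    int s = std::max(0, start0[i]), e = std::min(L, end0[i]);
    if (s < e) { diff[s]++; diff[e]--; }
  }
  IntegerVector out(L);
  int acc = 0;
  for (int i = 0; i < L; ++i) { acc += diff[i]; out[i] = acc; }
  return out;
}

//' Map contig positions to offsets within a segment's SEQ field (contig
//' orientation). Positions must fall inside [start0, start0+span); positions
//' inside deletions map to the next aligned read base. Returns 0-based offsets,
//' or -1 when the position precedes the first aligned base.
//' @noRd
// [[Rcpp::export(name = ".contig_to_seq_offset")]]
IntegerVector contig_to_seq_offset(std::string cigar, int start0, IntegerVector pos0) {
  std::vector<CigOp> ops = parse_cigar(cigar.c_str());
  int np = pos0.size();
  IntegerVector out(np, -1);
  for (int i = 0; i < np; ++i) {
    int target = pos0[i];
    int rpos = start0, qpos = 0;
    if (target < start0) { out[i] = -1; continue; }
    for (size_t j = 0; j < ops.size(); ++j) {
      char op = ops[j].op; int l = ops[j].len;
      if (op=='M'||op=='='||op=='X') {
        if (target < rpos + l) { out[i] = qpos + (target - rpos); break; }
        rpos += l; qpos += l;
      } else if (op=='D' || op=='N') {
        if (target < rpos + l) { out[i] = qpos; break; }
        rpos += l;
      } else if (op=='I' || op=='S') {
        qpos += l;
      }
    }
  }
  return out;
}

static int parse_int(const char *s) {
  int v = 0; bool neg = false;
  if (*s == '-') { neg = true; ++s; }
  for (; *s >= '0' && *s <= '9'; ++s) v = v * 10 + (*s - '0');
  return neg ? -v : v;
}

//' Minimal SAM text parser: the eleven mandatory fields of mapped records.
//' @noRd
// [[Rcpp::export(name = ".parse_sam_core")]]
List parse_sam_core(std::string path) {
  std::ifstream in(path.c_str());
  if (!in) stop("cannot open '%s'", path.c_str());
  std::vector<std::string> qname, rname, cigar, seq;
  std::vector<int> flag, pos, mapq;
  std::string line;
  while (std::getline(in, line)) {
    if (line.empty() || line[0] == '@') continue;
    // split first 10 tab fields
    const char *fields[11];
    size_t nf = 0, start = 0;
    fields[nf++] = line.c_str();
    for (size_t i = 0; i < line.size() && nf < 11; ++i) {
      if (line[i] == '\t') { line[i] = '\0'; fields[nf++] = line.c_str() + i + 1; }
    }
    (void)start;
    if (nf < 11) continue;
    int fl = parse_int(fields[1]);
    if (fl & 4) continue;            // unmapped
    qname.push_back(fields[0]);
    flag.push_back(fl);
    rname.push_back(fields[2]);
    pos.push_back(parse_int(fields[3]));
    mapq.push_back(parse_int(fields[4]));
    cigar.push_back(fields[5]);
    seq.push_back(fields[9]);
  }
  return List::create(_["qname"]=wrap(qname), _["flag"]=wrap(flag),
                      _["rname"]=wrap(rname), _["pos"]=wrap(pos),
                      _["mapq"]=wrap(mapq), _["cigar"]=wrap(cigar),
                      _["seq"]=wrap(seq));
}

static const char *BASES = "ACGT";

//' Random DNA string using R's RNG.
//' @noRd
// [[Rcpp::export(name = ".random_dna")]]
std::string random_dna(int n) {
  std::string s((size_t)n, 'A');
  for (int i = 0; i < n; ++i) s[(size_t)i] = BASES[(int)(R::unif_rand() * 4) & 3];
  return s;
}

//' Long-read sampler with an i.i.d. per-base error model (R RNG).
//' Lengths ~ Normal(len_mean, len_sd) truncated at len_min; starts uniform;
//' strand random; errors split substitution / 1-bp insertion / 1-bp deletion.
//' Stops once cumulative sampled bases reach target_bases.
//' @noRd
// [[Rcpp::export(name = ".sim_reads_core")]]
List sim_reads_core(std::string hap, double target_bases, double len_mean,
                    double len_sd, int len_min, double e_sub, double e_ins,
                    double e_del) {
  int L = (int)hap.size();
  std::vector<std::string> seqs;
  std::vector<int> starts, lens;
  std::vector<bool> strands;
  double cum = 0.0;
  double p_any = e_sub + e_ins + e_del;
  while (cum < target_bases) {
    int len = (int)std::lround(R::rnorm(len_mean, len_sd));
    if (len < len_min) len = len_min;
    if (len > L) len = L;
    int start = (int)(R::unif_rand() * (double)(L - len + 1));
    if (start < 0) start = 0;
    if (start > L - len) start = L - len;
    bool fwd = R::unif_rand() < 0.5;
    std::string out;
    out.reserve((size_t)(len * (1.0 + e_ins) + 8));
    for (int k = 0; k < len; ++k) {
      char b = hap[(size_t)(start + k)];
      double u = p_any > 0 ? R::unif_rand() : 1.0;
      if (u < e_sub) {
        char nb = b;
        while (nb == b) nb = BASES[(int)(R::unif_rand() * 4) & 3];
        out.push_back(nb);
      } else if (u < e_sub + e_ins) {
        out.push_back(b);
        out.push_back(BASES[(int)(R::unif_rand() * 4) & 3]);
      } else if (u < p_any) {
        // deletion: emit nothing
      } else {
        out.push_back(b);
      }
    }
    if (!fwd) { // reverse complement
      std::string rc(out.rbegin(), out.rend());
      for (size_t k = 0; k < rc.size(); ++k) {
        switch (rc[k]) {
          case 'A': rc[k]='T'; break; case 'T': rc[k]='A'; break;
          case 'C': rc[k]='G'; break; case 'G': rc[k]='C'; break;
          default: break;
        }
      }
      out.swap(rc);
    }
    seqs.push_back(out);
    starts.push_back(start);
    lens.push_back(len);
    strands.push_back(fwd);
    cum += (double)len;
  }
  return List::create(_["seq"]=wrap(seqs), _["start"]=wrap(starts),
                      _["len"]=wrap(lens), _["forward"]=wrap(strands));
}
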