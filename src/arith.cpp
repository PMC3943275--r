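// Adaptive order-0 arithmetic coder and CRC-32.
//
// Symbols are coded with one adaptive frequency model per context (the
// codec uses one context per distinct sub-band word length).  Counts start
// at 1 (Laplace), are bumped by ADAPT_INC per coded symbol, and are halved
// when the context total reaches MAX_TOTAL, so the models track the window
// statistics without transmitting any tables.  The coder is the classic
// shift-and-emit arithmetic coder with 40 bits of state and explicit
// pending-bit carry handling; output is bit-packed MSB first.  A CRC-32 of
// the symbol stream is appended to every payload so that truncated or
// mismatched payloads fail loudly instead of decoding to silent garbage.

#include <Rcpp.h>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------- CRC-32
static uint32_t crc_table[256];
static bool crc_ready = false;

static void crc_init() {
  for (uint32_t i = 0; i < 256; ++i) {
    uint32_t c = i;
    for (int k = 0; k < 8; ++k)
      c = (c & 1) ? 0xEDB88320u ^ (c >> 1) : c >> 1;
    crc_table[i] = c;
  }
  crc_ready = true;
}

static uint32_t crc32_update(uint32_t crc, const uint8_t* buf, size_t len) {
  if (!crc_ready) crc_init();
  crc ^= 0xFFFFFFFFu;
  for (size_t i = 0; i < len; ++i)
    crc = crc_table[(crc ^ buf[i]) & 0xFFu] ^ (crc >> 8);
  return crc ^ 0xFFFFFFFFu;
}

static uint32_t crc32_symbols(const IntegerVector& syms) {
  if (!crc_ready) crc_init();
  uint32_t crc = 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < syms.size(); ++i) {
    uint32_t v = (uint32_t)syms[i];
    for (int b = 0; b < 4; ++b) {
      uint8_t byte = (v >> (8 * b)) & 0xFFu;
      crc = crc_table[(crc ^ byte) & 0xFFu] ^ (crc >> 8);
    }
  }
  return crc ^ 0xFFFFFFFFu;
}

// [[Rcpp::export(name = ".cpp_crc32")]]
double cpp_crc32(RawVector bytes) {
  uint32_t c = crc32_update(0u, RAW(bytes), bytes.size());
  return (double)c;  // returned as double: R has no unsigned 32-bit type
}

// ------------------------------------------------- adaptive Fenwick model
static const int32_t ADAPT_INC = 32;
static const int64_t MAX_TOTAL = (int64_t)1 << 17;

struct Model {
  int n;                       // alphabet size
  std::vector<int32_t> tree;   // Fenwick tree over symbol counts
  int64_t total;

  explicit Model(int alphabet) : n(alphabet), tree(alphabet + 1, 0), total(0) {
    for (int s = 0; s < n; ++s) add(s, 1);
  }
  void add(int s, int32_t delta) {
    for (int i = s + 1; i <= n; i += i & (-i)) tree[i] += delta;
    total += delta;
  }
  // cumulative count of symbols < s
  int64_t cum_below(int s) const {
    int64_t c = 0;
    for (int i = s; i > 0; i -= i & (-i)) c += tree[i];
    return c;
  }
  // count of symbol s
  int32_t freq(int s) const { return (int32_t)(cum_below(s + 1) - cum_below(s)); }
  // largest s with cum_below(s) <= target, i.e. the symbol covering target
  int find(int64_t target) const {
    int pos = 0;
    int64_t rem = target;
    int logn = 1;
    while ((1 << logn) <= n) ++logn;
    for (int pw = 1 << logn; pw > 0; pw >>= 1) {
      int nxt = pos + pw;
      if (nxt <= n && tree[nxt] <= rem) {
        rem -= tree[nxt];
        pos = nxt;
      }
    }
    return pos;  // 0-based symbol
  }
  void update(int s) {
    add(s, ADAPT_INC);
    if (total >= MAX_TOTAL) rescale();
  }
  void rescale() {
    std::vector<int32_t> counts(n);
    for (int s = 0; s < n; ++s) counts[s] = freq(s);
    std::fill(tree.begin(), tree.end(), 0);
    total = 0;
    for (int s = 0; s < n; ++s) add(s, (counts[s] + 1) >> 1);
  }
};

// -------------------------------------------------------- bit-level I/O
struct BitWriter {
  std::vector<uint8_t> bytes;
  uint8_t cur = 0;
  int nbits = 0;
  void put(int bit) {
    cur = (uint8_t)((cur << 1) | (bit & 1));
    if (++nbits == 8) { bytes.push_back(cur); cur = 0; nbits = 0; }
  }
  void flush() {
    while (nbits != 0) put(0);
  }
};

struct BitReader {
  const uint8_t* buf;
  size_t len;
  size_t pos = 0;  // bit position
  BitReader(const uint8_t* b, size_t n) : buf(b), len(n) {}
  // past the payload the reader yields zeros: the encoder's flush
  // guarantees enough real bits, and the CRC catches true truncation
  int get() {
    if (pos >= 8 * len) { ++pos; return 0; }
    int bit = (buf[pos >> 3] >> (7 - (pos & 7))) & 1;
    ++pos;
    return bit;
  }
};

// ------------------------------------------------------ arithmetic coder
static const int CODE_BITS = 40;
static const uint64_t TOP_VAL = ((uint64_t)1 << CODE_BITS) - 1;
static const uint64_t HALF = (uint64_t)1 << (CODE_BITS - 1);
static const uint64_t QTR = (uint64_t)1 << (CODE_BITS - 2);

struct Encoder {
  uint64_t low = 0, high = TOP_VAL;
  int64_t pending = 0;
  BitWriter out;

  void emit(int bit) {
    out.put(bit);
    while (pending > 0) { out.put(!bit); --pending; }
  }
  void encode(int64_t cum_lo, int64_t cum_hi, int64_t tot) {
    uint64_t span = high - low + 1;
    high = low + span * (uint64_t)cum_hi / (uint64_t)tot - 1;
    low  = low + span * (uint64_t)cum_lo / (uint64_t)tot;
    for (;;) {
      if (high < HALF) {
        emit(0);
      } else if (low >= HALF) {
        emit(1); low -= HALF; high -= HALF;
      } else if (low >= QTR && high < 3 * QTR) {
        ++pending; low -= QTR; high -= QTR;
      } else break;
      low <<= 1;
      high = (high << 1) | 1;
    }
  }
  void finish() {
    ++pending;
    emit(low >= QTR ? 1 : 0);
    out.flush();
  }
};

struct Decoder {
  uint64_t low = 0, high = TOP_VAL, value = 0;
  BitReader in;
  Decoder(const uint8_t* b, size_t n) : in(b, n) {
    for (int i = 0; i < CODE_BITS; ++i) value = (value << 1) | in.get();
  }
  int64_t target(int64_t tot) {
    uint64_t span = high - low + 1;
    return (int64_t)(((value - low + 1) * (uint64_t)tot - 1) / span);
  }
  void consume(int64_t cum_lo, int64_t cum_hi, int64_t tot) {
    uint64_t span = high - low + 1;
    high = low + span * (uint64_t)cum_hi / (uint64_t)tot - 1;
    low  = low + span * (uint64_t)cum_lo / (uint64_t)tot;
    for (;;) {
      if (high < HALF) {
        // nothing
      } else if (low >= HALF) {
        low -= HALF; high -= HALF; value -= HALF;
      } else if (low >= QTR && high < 3 * QTR) {
        low -= QTR; high -= QTR; value -= QTR;
      } else break;
      low <<= 1;
      high = (high << 1) | 1;
      value = (value << 1) | in.get();
    }
  }
};

static std::vector<Model> build_models(const IntegerVector& alphabet_sizes) {
  std::vector<Model> models;
  models.reserve(alphabet_sizes.size());
  for (R_xlen_t i = 0; i < alphabet_sizes.size(); ++i) {
    int a = alphabet_sizes[i];
    if (a < 1) stop("alphabet size must be >= 1");
    models.emplace_back(a);
  }
  return models;
}

// Encode `symbols` (0-based, symbols[i] in [0, alphabet_sizes[ctx[i]]))
// under per-context adaptive models; returns payload bytes with a CRC-32
// of the symbol stream appended (little-endian).
// [[Rcpp::export(name = ".cpp_arith_encode")]]
RawVector cpp_arith_encode(IntegerVector symbols, IntegerVector ctx,
                           IntegerVector alphabet_sizes) {
  if (symbols.size() != ctx.size()) stop("symbols/ctx length mismatch");
  std::vector<Model> models = build_models(alphabet_sizes);
  Encoder enc;
  for (R_xlen_t i = 0; i < symbols.size(); ++i) {
    int c = ctx[i];
    if (c < 0 || c >= (int)models.size()) stop("context index out of range");
    Model& mdl = models[c];
    int s = symbols[i];
    if (s < 0 || s >= mdl.n)
      stop("symbol %d outside context alphabet [0, %d)", s, mdl.n);
    if (mdl.n > 1) {
      int64_t lo = mdl.cum_below(s);
      enc.encode(lo, lo + mdl.freq(s), mdl.total);
      mdl.update(s);
    }
  }
  enc.finish();
  uint32_t crc = crc32_symbols(symbols);
  RawVector out(enc.out.bytes.size() + 4);
  std::copy(enc.out.bytes.begin(), enc.out.bytes.end(), RAW(out));
  for (int b = 0; b < 4; ++b)
    out[enc.out.bytes.size() + b] = (crc >> (8 * b)) & 0xFFu;
  return out;
}

// Decode `n = length(ctx)` symbols and verify the appended CRC-32.
// [[Rcpp::export(name = ".cpp_arith_decode")]]
IntegerVector cpp_arith_decode(RawVector payload, IntegerVector ctx,
                               IntegerVector alphabet_sizes) {
  if (payload.size() < 4) stop("payload too short: missing checksum");
  size_t nbytes = payload.size() - 4;
  std::vector<Model> models = build_models(alphabet_sizes);
  Decoder dec(RAW(payload), nbytes);
  IntegerVector out(ctx.size());
  for (R_xlen_t i = 0; i < ctx.size(); ++i) {
    int c = ctx[i];
    if (c < 0 || c >= (int)models.size()) stop("context index out of range");
    Model& mdl = models[c];
    if (mdl.n == 1) { out[i] = 0; continue; }
    int64_t t = dec.target(mdl.total);
    int s = mdl.find(t);
    if (s >= mdl.n) stop("arithmetic decode failure: corrupt payload");
    int64_t lo = mdl.cum_below(s);
    dec.consume(lo, lo + mdl.freq(s), mdl.total);
    mdl.update(s);
    out[i] = s;
  }
  uint32_t crc = crc32_symbols(out);
  uint32_t stored = 0;
  for (int b = 0; b < 4; ++b)
    stored |= ((uint32_t)payload[nbytes + b]) << (8 * b);
  if (crc != stored)
    stop("entropy decode error: symbol checksum mismatch (truncated or "
         "mismatched payload)");
  return out;
}
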