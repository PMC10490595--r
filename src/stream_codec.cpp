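#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Wire format: a flat sequence of [1-byte type tag][message bytes].
// Tags: 0x60/0x61/0x62 data packet (10/14/16-bit channel values, 31/43/49
// bytes), 0xDE shift update (14 bytes), 0xC0 configuration (8 bytes).
// Data packet: header byte = (packet_id << 4) | min(dropped, 15), then 24
// two's-complement values, MSB-first, bit-contiguous across byte boundaries.

static const int N_CH = 24;

static int data_tag(int bits) {
  return bits == 10 ? 0x60 : (bits == 14 ? 0x61 : 0x62);
}
static int payload_bytes(int bits) {
  return (N_CH * bits + 7) / 8;
}

static int bitlength_ll(long long x) {
  int k = 0;
  while (x > 0) { x >>= 1; ++k; }
  return k;
}

static int select_shift(double A, int bits, double headroom) {
  long long target = (long long)std::ceil(A * headroom);
  int s = bitlength_ll(target) - (bits - 1);
  if (s < 0) s = 0;
  if (s > 15) s = 15;
  return s;
}

class BitWriter {
public:
  std::vector<unsigned char>& buf;
  int bitpos; // bits filled in current byte
  BitWriter(std::vector<unsigned char>& b) : buf(b), bitpos(0) {}
  void put(unsigned int value, int nbits) {
    for (int i = nbits - 1; i >= 0; --i) {
      if (bitpos == 0) buf.push_back(0);
      int bit = (value >> i) & 1u;
      buf.back() |= bit << (7 - bitpos);
      bitpos = (bitpos + 1) % 8;
    }
  }
  void align() { bitpos = 0; }
};

static void write_config(std::vector<unsigned char>& out, int gain_code,
                         int rate_code, int bitlen_code, int filter_mask,
                         int battery_mV) {
  out.push_back(0xC0);
  out.push_back((unsigned char)gain_code);
  out.push_back((unsigned char)rate_code);
  out.push_back((unsigned char)bitlen_code);
  out.push_back((unsigned char)filter_mask);
  out.push_back((unsigned char)((battery_mV >> 8) & 0xFF));
  out.push_back((unsigned char)(battery_mV & 0xFF));
  out.push_back(0);
  out.push_back(0);
}

static void write_shift_update(std::vector<unsigned char>& out, int ref_id,
                               const int* s) {
  out.push_back(0xDE);
  out.push_back((unsigned char)ref_id);
  out.push_back(0); // flags
  for (int k = 0; k < N_CH / 2; ++k)
    out.push_back((unsigned char)((s[2 * k] << 4) | s[2 * k + 1]));
}

// [[Rcpp::export]]
List cpp_encode_stream(IntegerMatrix counts, int bit_length, int ups,
                       double lambda, double headroom, int gain_code,
                       int rate_code, int filter_mask, int battery_mV) {
  const int T = counts.nrow();
  if (counts.ncol() != N_CH) stop("expected 24 channels");
  if (bit_length != 10 && bit_length != 14 && bit_length != 16)
    stop("bit_length must be 10, 14 or 16");
  const int bits = bit_length;
  const int qmin = -(1 << (bits - 1));
  const int qmax = (1 << (bits - 1)) - 1;
  const int bitlen_code = bits == 10 ? 0 : (bits == 14 ? 1 : 2);

  std::vector<unsigned char> out;
  out.reserve(16 + (size_t)T * (2 + payload_bytes(bits)));
  write_config(out, gain_code, rate_code, bitlen_code, filter_mask, battery_mV);

  std::vector<long long> r(N_CH, 0);
  std::vector<double> A(N_CH, 0.0);
  std::vector<int> s(N_CH, 0);
  IntegerVector clipped(N_CH);
  int n_updates = (T + ups - 1) / ups;
  IntegerMatrix shift_hist(n_updates > 0 ? n_updates : 1, N_CH);
  int upd = 0;

  for (int t = 0; t < T; ++t) {
    int pid = t & 0x0F;
    if (t % ups == 0) {
      for (int c = 0; c < N_CH; ++c)
        s[c] = select_shift(A[c], bits, headroom);
      write_shift_update(out, pid, s.data());
      for (int c = 0; c < N_CH; ++c) shift_hist(upd, c) = s[c];
      ++upd;
    }
    out.push_back((unsigned char)data_tag(bits));
    out.push_back((unsigned char)(pid << 4)); // dropped = 0 at production
    BitWriter bw(out);
    for (int c = 0; c < N_CH; ++c) {
      long long x = counts(t, c);
      long long d = x - r[c];
      long long q;
      if (s[c] == 0) q = d;
      else {
        long long half = 1LL << (s[c] - 1);
        q = d >= 0 ? (d + half) >> s[c] : -((-d + half) >> s[c]);
      }
      if (q < qmin) { q = qmin; ++clipped[c]; }
      else if (q > qmax) { q = qmax; ++clipped[c]; }
      r[c] += q << s[c];
      double ad = d >= 0 ? (double)d : (double)(-d);
      A[c] = (1.0 - lambda) * A[c] + lambda * ad;
      bw.put((unsigned int)(q & ((1LL << bits) - 1)), bits);
    }
    bw.align();
  }

  RawVector stream(out.size());
  std::copy(out.begin(), out.end(), stream.begin());
  return List::create(_["stream"] = stream, _["shifts"] = shift_hist,
                      _["clipped"] = clipped, _["n_frames"] = T);
}

class BitReader {
public:
  const unsigned char* p;
  int bitpos;
  BitReader(const unsigned char* ptr) : p(ptr), bitpos(0) {}
  unsigned int get(int nbits) {
    unsigned int v = 0;
    for (int i = 0; i < nbits; ++i) {
      int bit = (*p >> (7 - bitpos)) & 1;
      v = (v << 1) | bit;
      if (++bitpos == 8) { bitpos = 0; ++p; }
    }
    return v;
  }
};

// [[Rcpp::export]]
List cpp_decode_stream(RawVector stream) {
  const unsigned char* buf = RAW(stream);
  const size_t len = stream.size();

  // first pass: count data packets, find bit length from config
  int bits = -1;
  size_t pos = 0;
  int n_packets = 0;
  while (pos < len) {
    unsigned char tag = buf[pos++];
    if (tag == 0xC0) {
      if (pos + 8 > len) stop("truncated configuration message");
      int code = buf[pos + 2];
      if (code < 0 || code > 2) stop("unknown bit-length code");
      bits = code == 0 ? 10 : (code == 1 ? 14 : 16);
      pos += 8;
    } else if (tag == 0xDE) {
      if (pos + 14 > len) stop("truncated shift update");
      pos += 14;
    } else if (tag == 0x60 || tag == 0x61 || tag == 0x62) {
      int pbits = tag == 0x60 ? 10 : (tag == 0x61 ? 14 : 16);
      if (bits == -1) bits = pbits;
      if (pbits != bits) stop("data packet width disagrees with configuration");
      size_t sz = 1 + payload_bytes(pbits);
      if (pos + sz > len) stop("truncated data packet");
      pos += sz;
      ++n_packets;
    } else stop("unknown message tag");
  }
  if (bits == -1) stop("stream contains no configuration or data");

  IntegerMatrix counts(n_packets, N_CH);
  IntegerMatrix shift_at(n_packets, N_CH);
  std::vector<long long> r(N_CH, 0);
  std::vector<int> s(N_CH, 0);
  std::vector<int> pending(N_CH, 0);
  bool have_pending = false, synced = false;
  int gain_code = -1, rate_code = -1, filter_mask = 0, battery = 0;
  long long total_dropped = 0;
  int last_pid = -1;
  pos = 0;
  int t = 0;
  while (pos < len) {
    unsigned char tag = buf[pos++];
    if (tag == 0xC0) {
      gain_code = buf[pos];
      rate_code = buf[pos + 1];
      filter_mask = buf[pos + 3];
      battery = (buf[pos + 4] << 8) | buf[pos + 5];
      pos += 8;
    } else if (tag == 0xDE) {
      for (int k = 0; k < N_CH / 2; ++k) {
        pending[2 * k] = buf[pos + 2 + k] >> 4;
        pending[2 * k + 1] = buf[pos + 2 + k] & 0x0F;
      }
      have_pending = true;
      synced = true;
      pos += 14;
    } else { // data packet
      if (!synced) stop("decoder unsynchronized: data before any shift update");
      if (have_pending) {
        s = pending;
        have_pending = false;
      }
      unsigned char header = buf[pos];
      last_pid = header >> 4;
      total_dropped += header & 0x0F;
      BitReader br(buf + pos + 1);
      for (int c = 0; c < N_CH; ++c) {
        unsigned int u = br.get(bits);
        long long q = (long long)u;
        if (q >= (1LL << (bits - 1))) q -= (1LL << bits);
        r[c] += q << s[c];
        counts(t, c) = (int)r[c];
        shift_at(t, c) = s[c];
      }
      pos += 1 + payload_bytes(bits);
      ++t;
    }
  }

  return List::create(
    _["counts"] = counts, _["bit_length"] = bits,
    _["gain_code"] = gain_code, _["rate_code"] = rate_code,
    _["filter_mask"] = filter_mask, _["battery_mV"] = battery,
    _["n_packets"] = n_packets, _["total_dropped"] = (double)total_dropped,
    _["last_packet_id"] = last_pid, _["shift_at"] = shift_at);
}
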