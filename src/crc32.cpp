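#include <Rcpp.h>
using namespace Rcpp;

// CRC-32 (IEEE 802.3, reflected polynomial 0xEDB88320) over a raw vector.
// Needed for PNG chunk checksums; kept in C++ because label maps can be
// megabytes and a byte loop in R is wasteful.

static uint32_t crc_table[256];
static bool crc_table_ready = false;

static void make_crc_table() {
  for (uint32_t n = 0; n < 256; n++) {
    uint32_t c = n;
    for (int k = 0; k < 8; k++)
      c = (c & 1) ? 0xEDB88320u ^ (c >> 1) : c >> 1;
    crc_table[n] = c;
  }
  crc_table_ready = true;
}

// [[Rcpp::export(name = ".crc32_raw")]]
double crc32_raw(RawVector data) {
  if (!crc_table_ready) make_crc_table();
  uint32_t c = 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < data.size(); i++)
    c = crc_table[(c ^ data[i]) & 0xFFu] ^ (c >> 8);
  c ^= 0xFFFFFFFFu;
  return (double)c;  // returned as double: R has no unsigned 32-bit integer
}
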