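#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <zlib.h>

/* CRC-32 (ISO 3309 / ITU-T V.42) of a raw vector, as used in PNG chunks.
   Returned as double because R has no unsigned 32-bit integer. */
SEXP C_crc32(SEXP data)
{
    uLong crc = crc32(0L, Z_NULL, 0);
    crc = crc32(crc, RAW(data), (uInt) XLENGTH(data));
    return ScalarReal((double) crc);
}

static const R_CallMethodDef CallEntries[] = {
    {"C_crc32", (DL_FUNC) &C_crc32, 1},
    {NULL, NULL, 0}
};

void R_init_intakevol(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
    R_forceSymbols(dll, TRUE);
}
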