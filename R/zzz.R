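#' @import data.table
NULL

.datatable.aware <- TRUE

utils::globalVariables(c(
  ".", ".N", ".I", "contig", "pos", "start", "end", "support", "fwd",
  "rev", "qsum", "rank", "payload", "type", "row", "dup", "pairId",
  "mapped", "keystr", "slot", "keep", "filter", "rfProb", "qual",
  "masked", "normalDepth", "tumorDepth", "ratio", "gcBin", "gc",
  "zygosity", "hap", "vcfPos", "expectedAF", "dp", "dpBin", "key",
  "altFrac", "aafBin", "wstart", "wend", "grp", "grpLocal", "anchor",
  "len", "distNearest", "idx", "clipLen", "boundary", "side"))
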