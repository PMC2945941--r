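#' @importFrom data.table := setDF setnames fread fwrite
#' @importFrom utils packageVersion
NULL

.datatable.aware <- TRUE

utils::globalVariables(c(
  "L", "anc", "desc", "count", "pr", "m", "mb", "block", "pattern",
  "revcomp", "rho_rec", "rho_fast", "reason_rec", "reason_fast", "cb",
  "..LL", "f", "key"))
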