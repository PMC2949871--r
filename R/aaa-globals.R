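# Shared constants (sourced first).

GAP_CHARS <- c("-", ".")

# one-letter amino-acid alphabet
AA1 <- c("A","R","N","D","C","Q","E","G","H","I",
         "L","K","M","F","P","S","T","W","Y","V")

HYDRO_SET <- c("A", "V", "L", "I", "M", "F", "W", "C")
NONHYDRO_SET <- setdiff(AA1, HYDRO_SET)

BASES <- c("T", "C", "A", "G")

MOTIF_REGEX <- "P.[DE]..[KR]"
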