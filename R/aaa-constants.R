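# Shared constants (file sorts first so every module sees them at load time)

# the 20 proteinogenic amino acids, one-letter code
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# characters removed under pairwise deletion / treated as gaps in logos
AMBIGUOUS <- c("-", "X", "?")
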