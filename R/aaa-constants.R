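# package-wide constants (file name keeps them first in the collation order)

# evoked-release variable order used throughout the 3-D analyses
EVOKED_VARS <- c("RRP", "Pv", "A")
ALL_VARS <- c("A", "RRP", "Pv", "F")
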