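# shared internal constants and sequence helpers

.BASES <- c("A", "C", "G", "T")

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
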