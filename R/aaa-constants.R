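## The 20 standard amino acids, alphabetical one-letter order. This order is
## the canonical axis ordering for every 20 x 20 matrix in the package.
AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

## characters legal in an input alignment: residues, gap, unknown
ALLOWED_CHARS <- c(AA_ALPHABET, "-", "X")
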