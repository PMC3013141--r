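# Shared constants and small internal helpers.

# One-letter codes in the column order emitted by PSI-BLAST ASCII matrices.
PSSM_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# AAindex1 value order: first data line A..I, second data line L..V.
AAINDEX_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                      "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA_LETTERS <- sort(PSSM_ALPHABET)

# Placeholder residue used when a window runs past a sequence terminus.
PAD_RESIDUE <- "X"
PAD_DISORDER <- 0.5

AAINDEX_CLUSTERS <- c("alpha-and-turn-propensities", "beta-propensity",
                      "composition", "hydrophobicity", "physicochemical")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_hx <- function(..., call. = FALSE) stop(..., call. = call.)

assert_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != round(x)) {
    stop_hx(sprintf("`%s` must be a single positive integer", name))
  }
  as.integer(x)
}

split_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
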