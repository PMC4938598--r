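# internal helpers shared across modules

AUTOSOMES <- as.character(1:22)

# strip a leading "chr" prefix and normalize to character
norm_chrom <- function(x) sub("^chr", "", as.character(x))

# round half away from zero (display convention for percent frequencies);
# base round() is half-to-even
round_half_away <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# order chromosomes numerically ("1" < "2" < ... < "22")
chrom_order <- function(chrom) order(as.integer(chrom))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bprscan <- function(...) stop(..., call. = FALSE)

# 1-based inclusive <-> BED 0-based half-open
to_bed_coords <- function(start, end) list(start = start - 1L, end = end)
from_bed_coords <- function(start, end) list(start = start + 1L, end = end)
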