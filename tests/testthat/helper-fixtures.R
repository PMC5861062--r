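# Hand-worked 30-column toy alignment for block extraction: 4 rows, used
# with b1=3, b2=4, b3=2, b4=3, gaps disallowed.
# Column types (H = all 4 agree, C = 3 agree, N = 2/2 split, G = has gap):
#   1:H 2:H 3:C 4:N 5:N 6:N 7:H 8:C 9:N 10:N 11:H 12:H 13:G 14:H 15:C
#   16:N 17:N 18:N 19:C 20:N 21:H 22:H 23:H 24:N 25:N 26:N 27:C 28:H 29:C 30:C
# Worked by hand before implementation: the nonconserved runs {4-6},
# {16-18}, {24-26} exceed b3=2 and are rejected; candidate segments
# [1-3], [7-15], [19-23], [27-30]; trimming to highly conserved flanks
# leaves [1-2] (2 retained < b4, dropped), [7-14] (gap column 13 excluded,
# 7 retained, kept), [21-23] (kept), [28-28] (dropped).
# Expected retained columns: 7 8 9 10 11 12 14 21 22 23.
toyMSA <- function() {
  types <- c("H","H","C","N","N","N","H","C","N","N","H","H","G","H","C",
             "N","N","N","C","N","H","H","H","N","N","N","C","H","C","C")
  rows <- matrix("A", 4, 30)
  for (j in seq_along(types)) {
    rows[, j] <- switch(types[j],
      H = c("A", "A", "A", "A"),
      C = c("A", "A", "A", "C"),
      N = c("A", "A", "C", "C"),
      G = c("A", "-", "A", "A"))
  }
  Biostrings::AAStringSet(c(r1 = paste(rows[1, ], collapse = ""),
                            r2 = paste(rows[2, ], collapse = ""),
                            r3 = paste(rows[3, ], collapse = ""),
                            r4 = paste(rows[4, ], collapse = "")))
}
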