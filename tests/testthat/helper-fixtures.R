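# Printed reference sequences of the mutant panel (hyphenation expanded,
# bold/underline markup dropped, BrG bracketed).
table1_expected_sequences <- c(
  "Qref"      = "GGCTAGGGTCAGGGTGGGTCAG",
  "3'delQ"    = "GGCTAGGGTCAGGGTGGGTCA",
  "2BrQ"      = "G[BrG]CTAGGGTCAGGGTGGGTCAG",
  "6BrQ"      = "GGCTA[BrG]GGTCAGGGTGGGTCAG",
  "7BrQ"      = "GGCTAG[BrG]GTCAGGGTGGGTCAG",
  "8BrQ"      = "GGCTAGG[BrG]TCAGGGTGGGTCAG",
  "16BrQ"     = "GGCTAGGGTCAGGGT[BrG]GGTCAG",
  "5'TQ"      = "TGGCTAGGGTCAGGGTGGGTCAG",
  "Q-5T"      = "GGCTTGGGTCAGGGTGGGTCAG",
  "Q-5I"      = "GGCTIGGGTCAGGGTGGGTCAG",
  "Q-5X"      = "GGCTXGGGTCAGGGTGGGTCAG",
  "Q-11T"     = "GGCTAGGGTCTGGGTGGGTCAG",
  "Q-11I"     = "GGCTAGGGTCIGGGTGGGTCAG",
  "Q-11X"     = "GGCTAGGGTCXGGGTGGGTCAG",
  "Q-5I-11I"  = "GGCTIGGGTCIGGGTGGGTCAG",
  "Q-3T-10T"  = "GGTTAGGGTTAGGGTGGGTCAG",
  "Q-3A"      = "GGATAGGGTCAGGGTGGGTCAG",
  "Q-3X"      = "GGXTAGGGTCAGGGTGGGTCAG"
)

# Reported melting parameters for the three conformer-locked 3-3-1 / 3-1-1
# pairs (means over triplicate melts): Tm (degC), dH, -TdS30, dG30, ddG30
# (kcal/mol).
table2_expected <- tibble::tribble(
  ~name,         ~Tm,  ~dH,   ~mTdS, ~dG30, ~ddG30,
  "5'TQ",        44.1, -53.7, 51.3,  -2.4,  NA,
  "5'TQ-311-T",  61.5, -72.9, 65.9,  -6.9,  -4.5,
  "16BrQ",       49.3, -53.2, 50.0,  -3.2,  NA,
  "14BrQ-311-T", 59.2, -72.3, 65.9,  -6.4,  -3.2,
  "2BrQ",        47.7, -53.9, 50.9,  -3.0,  NA,
  "2BrQ-311-T",  65.5, -71.4, 63.8,  -7.5,  -4.5
)

qref_seq <- function() parse_sequence("GGCTAGGGTCAGGGTGGGTCAG", "Qref")
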