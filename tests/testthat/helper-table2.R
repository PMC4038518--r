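# Published per-dose ET-score rows of the operating-characteristics table,
# keyed by summary-table scenario label.
printed_et_rows <- list(
  A = c(0.12, 0.19, 0.34, 0.48, 0.76, 1.05),
  B = c(0.08, 0.14, 0.28, 0.42, 0.70, 0.98),
  C = c(0.00, 0.06, 0.09, 0.10, 0.16, 0.32),
  D = c(0.44, 0.63, 0.80, 1.01, 1.16, 1.29),
  E = c(0.16, 0.40, 0.50, 0.66, 0.83, 1.12),
  F = c(0.11, 0.34, 0.45, 0.60, 0.78, 1.06),
  G = c(0.19, 0.45, 0.57, 0.73, 0.90, 1.17),
  H = c(0.08, 0.24, 0.32, 0.43, 0.55, 0.75)
)

# dose marked as the target (true MTD) in each published scenario block
printed_mtd <- c(A = 4, B = 4, C = 6, D = 1, E = 3, F = 3, G = 2, H = 4)
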