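# Default lineage gating rules. A cell's score for a label is
# mean(normalized positive genes) - mean(normalized negative genes);
# the best-scoring label with score >= threshold wins, ties broken by
# the order below.
CD8_T:
  positive: [PTPRC, CD3E, CD8A]
  negative: [CD4, TRDC, CD19, CD14]
  threshold: 0.5
CD4_T:
  positive: [PTPRC, CD3E, CD4]
  negative: [CD8A, TRDC, CD19, CD14]
  threshold: 0.5
gd_T:
  positive: [PTPRC, CD3E, TRDC]
  negative: [CD19, CD14]
  threshold: 0.5
B:
  positive: [PTPRC, CD19]
  negative: [CD3E, CD14]
  threshold: 0.5
myeloid:
  positive: [PTPRC, CD14, CD68, ITGAX]
  negative: [CD3E, CD19]
  threshold: 0.5
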