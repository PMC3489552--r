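# Assay configuration: SIS spike concentration (fmol/uL), decision
# thresholds, and a column map adapting vendor export headers to the
# canonical field names.
sis_conc: 50
p_threshold: 1.0e-5
cv_threshold: 0.2
column_map:
  peptide_id: "Peptide Sequence"
  transition_id: "Fragment Ion"
  label: "Isotope Label"
  sample_id: "Sample Name"
  theoretical_conc: "Analyte Concentration"
  replicate: "Replicate Name"
  peak_area: "Area"
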