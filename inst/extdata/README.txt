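synthetic_complexes.csv — a synthetic, hand-written ligand-receptor complex
table in the minimal CellPhoneDB-style layout read_complex_table() expects
(multi-subunit complexes joined by '+'). For format illustration and tests
only; not derived from any curated database release.
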