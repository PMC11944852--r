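file: adgat_reference_table.csv
md5: 9e6006d3f4a3ce3c9d7c6b0ac1439a6f
n_rows: 101
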