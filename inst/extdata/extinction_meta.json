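{
  "units": "cm^-1 M^-1",
  "log_base": "decadic",
  "wavelength_units": "nm",
  "species": {
    "HbO2": "extinction_HbO2.tsv",
    "HbH": "extinction_HbH.tsv",
    "beta_carotene": "extinction_beta_carotene.tsv",
    "patent_blue_dye": "extinction_patent_blue_dye.tsv"
  },
  "notes": "Hb and beta-carotene tables are smooth interpolants of the public Prahl compilation; the patent blue dye table is a synthetic approximation (no published curve)."
}
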