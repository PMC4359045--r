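Drop-in slot for the external supplementary compilations used by the
full scaling reproduction (not shipped with the package):

  fmr_table_s4.csv      columns: species, clade (bat|bird), mass (g),
                        fmr (kJ/day)
  growth_table_s3.csv   columns: species, clade (bat|bird), model
                        (logistic|gompertz|von_bertalanffy), A (g),
                        K (1/day)
  mammal_supertree.nwk  time-calibrated mammal supertree (Newick)
  bird_supertree.nwk    time-calibrated bird supertree (Newick)

With these four files present, the acceptance test
"supplementary growth/FMR compilations reproduce the published scaling
slopes" runs the published growth/FMR regressions.
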