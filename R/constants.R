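# Anion molar masses (g/mol). The analysis mixes mg/L and mM bases; the
# canonical internal unit is mg/L of the free anion, and these masses define
# the mg/L <-> mM boundary conversions (1.0 g/L sulfate <-> 10.41 mM).
.MOLAR_MASS <- c(
  sulfate    = 96.06,
  lactate    = 89.07,
  propionate = 73.07,
  acetate    = 59.04,
  citrate    = 189.10,
  sulfide    = 33.07   # as HS-
)

.ANALYTES <- names(.MOLAR_MASS)
.ZONES <- c("inlet", "middle", "effluent")
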