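# Physical constants in eV-based units (CODATA 2018).
# All rate arithmetic in the package is done in eV, Angstrom, s and K.
.kB_eV_per_K <- 8.617333262e-5
.hbar_eV_s <- 6.582119569e-16
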