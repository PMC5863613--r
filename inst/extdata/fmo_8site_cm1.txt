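# 8-site FMO (Chlorobaculum tepidum) Frenkel exciton Hamiltonian, cm^-1.
# Literature values (site energies include the eighth bacteriochlorophyll);
# whitespace-delimited full matrix, diagonal = site energies.
12505.0   -94.8     5.5    -5.9     7.1   -15.1   -12.2    39.5
  -94.8 12425.0    29.8     7.6     1.6    13.1     5.7     7.9
    5.5    29.8 12195.0   -58.9    -1.2    -9.3     3.4     1.4
   -5.9     7.6   -58.9 12375.0   -64.1   -17.4   -62.3    -1.6
    7.1     1.6    -1.2   -64.1 12600.0    89.5    -4.6     4.4
  -15.1    13.1    -9.3   -17.4    89.5 12515.0    35.1    -9.1
  -12.2     5.7     3.4    -62.3    -4.6    35.1 12465.0   -11.1
   39.5     7.9     1.4    -1.6     4.4    -9.1   -11.1 12700.0
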