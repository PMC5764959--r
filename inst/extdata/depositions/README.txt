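Deposited coordinate files are not redistributed with this package.
To run the deposited-structure checks (analysis/04_structure_checks.R and
the corresponding acceptance test), download from the Protein Data Bank:

  6eu6.pdb  - membrane (Amt) domain of the ammonium sensor
  2b2h.pdb  - Archaeoglobus fulgidus Amt1

and place them in this directory.
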