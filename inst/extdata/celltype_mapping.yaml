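# Mapping from deconvolution cell types (CIBERSORTx-style 22-type panel,
# dotted column names) to model variables. Types not listed under any
# variable still count toward the immune total and toward clustering, but
# do not enter the dynamical model. Edit and pass to load_cell_mapping()
# to change the pooling.
version: 1
variables:
  TN: [T.cells.CD4.naive, T.cells.CD4.memory.resting]
  Th: [T.cells.CD4.memory.activated, T.cells.follicular.helper]
  TC: [T.cells.CD8, NK.cells.activated]
  Tr: [T.cells.regulatory.Tregs]
  DN: [Dendritic.cells.resting]
  "D": [Dendritic.cells.activated]
  "M": [Macrophages.M1, Macrophages.M2]
# naive macrophages top up the conserved capacity M0 = MN + M
naive_macrophages: [Macrophages.M0]
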