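# Steady-state balance assumptions used to derive a unique parameter set
# per cluster. For every equation the production flux equals the loss flux
# at the cluster steady state; these entries close the resulting balance:
#   delta    -- fixed first-order decay/death rate (1/day)
#   turnover -- fixed per-capita total loss rate at steady state (1/day)
#   production / loss -- nonnegative shares (summing to 1) apportioning the
#                        balanced flux among the equation's terms
#   alpha_NC -- fraction of dying cancer cells entering the necrotic pool
# Shares default to uniform within each flux group and fixed rates to
# 1/day for the fast species (cytokines, immune cells). Cancer is the
# slow species: its per-capita turnover is 0.05/day and its death flux is
# dominated by intrinsic turnover rather than immune-mediated killing,
# which keeps tumor growth on the months-to-years scale and monotone from
# small-tumor initial conditions (see the methods vignette). Entries
# under `clusters` override the defaults per cluster.
version: 1
default:
  H:
    delta: 1.0
    production: {"N": 0.2, "M": 0.2, "Th": 0.2, "TC": 0.2, "Tr": 0.2}
  mu1:
    delta: 1.0
    production: {Th: 0.3333333333333333, M: 0.3333333333333333, D: 0.3333333333333333}
  mu2:
    delta: 1.0
    production: {M: 0.3333333333333333, D: 0.3333333333333333, Tr: 0.3333333333333333}
  Igamma:
    delta: 1.0
    production: {Th: 0.3333333333333333, TC: 0.3333333333333333, M: 0.3333333333333333}
  Gbeta:
    delta: 1.0
    production: {M: 0.5, Tr: 0.5}
  Th:
    turnover: 1.0
    production: {D: 0.3333333333333333, M: 0.3333333333333333, mu1: 0.3333333333333333}
    loss: {mu2: 0.3333333333333333, Tr: 0.3333333333333333, natural: 0.3333333333333333}
  TC:
    turnover: 1.0
    production: {Th: 0.5, D: 0.5}
    loss: {mu2: 0.3333333333333333, Tr: 0.3333333333333333, natural: 0.3333333333333333}
  Tr:
    turnover: 1.0
    production: {Th: 0.3333333333333333, mu2: 0.3333333333333333, Gbeta: 0.3333333333333333}
    loss: {mu1: 0.5, natural: 0.5}
  TN:
    delta: 1.0
  D:
    turnover: 1.0
    production: {H: 0.5, C: 0.5}
    loss: {H: 0.3333333333333333, C: 0.3333333333333333, natural: 0.3333333333333333}
  M:
    delta: 1.0
    production: {mu2: 0.3333333333333333, Igamma: 0.3333333333333333, Th: 0.3333333333333333}
  C:
    turnover: 0.05
    production: {base: 0.5, mu1: 0.5}
    loss: {Gbeta: 0.3, Igamma: 0.05, TC: 0.15, natural: 0.5}
  "N":
    alpha_NC: 0.5
clusters: {}
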