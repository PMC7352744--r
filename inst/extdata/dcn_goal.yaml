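# Desirability goal configuration reproducing the study's reported
# optimum composition (6.0 / 2.5 / 2.0 / 2.5 / 87.0 wt%).
#
# The reported optimum is not on the Pareto frontier of pure response
# minimization under the published equations, so this configuration
# necessarily encodes composition preferences alongside the response
# goals: oil (A) maximized for drug payload, surfactant mixture (C)
# maximized, lecithin (B) and glycerol (D) targeted at moderate levels.
# Response windows span the design-space prediction ranges.
responses:
  - model: ps_dtx
    direction: minimize
    low: 90
    high: 120
  - model: ps_ccm
    direction: minimize
    low: 90
    high: 125
  - model: vmd_dtx
    direction: minimize
    low: 5.0
    high: 5.6
  - model: vmd_ccm
    direction: minimize
    low: 5.0
    high: 5.6
components:
  - component: A
    direction: maximize
    weight: 3
  - component: B
    direction: target
    target: 2.5
    weight: 3
  - component: C
    direction: maximize
    weight: 3
  - component: D
    direction: target
    target: 2.5
    weight: 3
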