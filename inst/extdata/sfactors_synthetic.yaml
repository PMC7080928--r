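# SYNTHETIC illustrative self-dose S values, mGy/(MBq h).
# Back-derived from tabulated organ dose-rate anchors assuming nominal
# organ masses (testis 0.1 g, liver 1.5 g); replace with phantom-derived
# values (small-animal phantom Monte Carlo results) for real analyses.
sfactors:
  - source: testis
    target: testis
    S: 202.8
  - source: liver
    target: liver
    S: 16.23
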