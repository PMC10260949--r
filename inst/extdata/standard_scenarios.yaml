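# Standard three-scenario SSB levy analysis.
# Every value below is also the packaged default; sections may be
# deleted and the run is unchanged. Values shown here define the run
# completely, so re-running with the same config and baseline
# byte-reproduces all output tables.

levy:
  band_rates:        # GBP per litre by sugar band
    mid: 0.18        # 5-8 g sugar / 100 ml
    high: 0.24       # > 8 g sugar / 100 ml
  band_sales_shares: # shares of levied sales volume; pooled rate 0.23
    mid: 0.16666666666666666
    high: 0.83333333333333334

price:
  sugar_content: 93      # g sugar per litre of SSB
  baseline_price: 0.61   # GBP per litre mean consumer price

pass_throughs: [0.8, 1.0, 1.2]

effect:
  base_effect: 6.7           # % intake decrease per 10 % price increase
  responsiveness_ratio: 1.65 # high- vs low-deprivation responsiveness
  # sec_multipliers omitted: calibrated against the baseline so the
  # intake-weighted mean multiplier is exactly 1

serving_size: 250  # grams per serving

scenarios:
  - label: levy
    trade: none
  - label: levy+soft
    trade: soft
  - label: levy+hard
    trade: hard

psa:
  iterations: 10000
  seed: 1
  # distributions omitted: package defaults (see ?default_psa_distributions)
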