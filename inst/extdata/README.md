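# Bundled example data

- `capercaillie_sign_counts.csv` — published per-design, per-sex counts of
  sexed Capercaillie sign observations from winter surveys in the Jura
  massif (subjective long-term survey 2007-2015; systematic transect survey
  2016-2017). Used in examples of observation-based sex-ratio estimation.
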