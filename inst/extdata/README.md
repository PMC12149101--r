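# Reference fixtures

Verbatim transcriptions of published provincial results for China's 31
provinces and municipalities, 2014-2019, used as arithmetic reference
fixtures (the underlying yearbook panel behind them is not publicly
deposited, so only the printed result tables can be checked):

- `reported_efficiency_2014_2019.csv` — comprehensive (CCR) efficiency per
  province and year, with the printed per-year summary rows transcribed in
  `reported_efficiency_2014_2019_summary.csv`.
- `reported_dea_2019.csv` — 2019 comprehensive / pure technical / scale
  efficiency and returns-to-scale labels (`-` = constant returns); printed
  mean row in `reported_dea_2019_summary.csv`.
- `reported_malmquist_2014_2019.csv` — per-province geometric-mean Malmquist
  components over 2014-2019 (effch, techch, sech, pech, tfpch) and the
  printed productivity rank.

`verify_fixtures()` recomputes every arithmetic relationship these tables
imply (summary rows, effectiveness counts, product identities, ranks) with
the package's own functions.
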