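# Public LOAEL databases

Place the two public chronic oral rat LOAEL tables here to enable the
real-data acceptance checks:

- `mazzatorta.csv` — the Nestlé database (567 LOAEL values, 445 unique
  structures)
- `swiss.csv` — the Swiss FSVO pesticide-evaluation database (493
  values, 381 structures)

Both are distributed publicly alongside their original publications as
CSV files with a SMILES column and a LOAEL column; the acceptance tests
detect the column names case-insensitively and read doses as mg/kg
bw/day unless the LOAEL column name mentions `mmol`.  Without these
files the corresponding acceptance tests report a failure explaining
what is missing; all other tests are self-contained.
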