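# Stock configuration file schema

Stock files use the same `key; value` dialect as the case files: one pair per
line, split on the first semicolon; values are numbers, quoted text,
`c(...)` vectors or `seq(a, b, by = s)` sequences. Lines starting with `#`
are comments. Copy a packaged file and edit it to define a new stock.

| key            | unit        | allowed range        | meaning |
|----------------|-------------|----------------------|---------|
| name           | —           | non-empty text       | stock identifier |
| ages           | yr          | `0:A`, A >= 2        | model ages; last age is the plus group |
| years          | calendar yr | contiguous, >= 2     | projection years |
| M              | 1/yr        | > 0                  | natural mortality (base value) |
| Linf           | cm          | > 0                  | von Bertalanffy asymptotic length |
| k              | 1/yr        | > 0                  | von Bertalanffy growth rate |
| t0             | yr          | any                  | theoretical age at length zero |
| w_alpha        | kg/cm^b     | > 0                  | length-weight coefficient |
| w_beta         | —           | ~2.5-3.5             | length-weight exponent |
| mat_a50        | yr          | > 0                  | age at 50% maturity (logistic) |
| mat_slope      | 1/yr        | > 0                  | maturity logistic slope |
| h              | —           | (0.2, 1]             | Beverton-Holt steepness |
| R0             | numbers     | > 0                  | unfished recruitment |
| sigma_R        | —           | > 0                  | SD of log recruitment deviations |
| cv_length      | —           | > 0                  | CV of length-at-age |
| length_bins    | cm          | strictly increasing  | interior bin edges; end bins open |
| fleets         | —           | positive integers    | fleet ids; one block of keys per id |

Per-fleet keys, prefixed `fleet<id>_`:

| key        | unit | allowed range       | meaning |
|------------|------|---------------------|---------|
| kind       | —    | "fishery"/"survey"  | fleet role |
| sel_a50    | yr   | > 0                 | age at 50% selectivity (logistic) |
| sel_slope  | 1/yr | > 0                 | selectivity logistic slope |
| q          | —    | > 0 (surveys only)  | catchability scaler |
| timing     | —    | [0, 1]              | fraction of year elapsed at survey observation |
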