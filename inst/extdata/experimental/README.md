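# Experimental cross-link tables (drop-in location)

The published experimental cross-link lists (horse myoglobin 2V1H; human
serum albumin repeats AO6-1/2/3/6) and the synthetic per-protein link lists
(1TIG, 1K40, 1KOY, 1HRE, ...) are distributed as journal supporting
information and are not shipped with this package.

To run the reproduction checks in `tests/testthat/test-acceptance.R`, place
the tables here as tab-separated files in the package's cross-link dialect
(`protein  res_i  res_j  reagent  confidence`, author numbering):

    2v1h_xlinks.tsv   ao6-2_xlinks.tsv   ao6-6_xlinks.tsv
    1tig_xlinks.tsv   1k40_xlinks.tsv    1koy_xlinks.tsv   1hre_xlinks.tsv

and the deposited myoglobin structure as `2v1h.pdb` (needed for the
violation census).
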