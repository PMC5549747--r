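Drop-in location for the original whole-proteome paired datasets
(space-separated text, one record per line: `id cds protein`), one file
per organism:

    ecoli.txt
    mjannaschii.txt
    scerevisiae.txt

These files are third-party data and are not bundled. When present (and
the package is reinstalled), the whole-proteome reproduction checks in
tests/testthat/test-acceptance.R run against them; otherwise those checks
report the datasets as unavailable.
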