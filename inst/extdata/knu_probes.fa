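>WT
GGTAAGAGAAACATAGAAACCTTCCATGTTTGGCAATTTCATCTTGGAACTTGATTCACTCTCTCTTGTCTTCTTTGTGCATCACAAGAACAACAA
>minus5
AGAGGGTAAGAGAAACATAGAAACCTTCCATGTTTGGCAATTTCATCTTGGAACTTACTCTCTCTTGTCTTCTTTGTGCATCACAAGAACAACAAA
>minus10
GAAAGAGGGTAAGAGAAACATAGAAACCTTCCATGTTTGGCAATTTCATCTTGGACTCTCTCTTGTCTTCTTTGTGCATCACAAGAACAACAAATA
>plus5
AGAGAAACATAGAAACCTTCCATGTTTGGCAATTTCATCTTGGAAGTCAGCTTGATTCACTCTCTCTTGTCTTCTTTGTGCATCACAAGAACAACA
>plus10
AAACATAGAAACCTTCCATGTTTGGCAATTTCATCTTGGAAGTCAGTAGCTCTTGATTCACTCTCTCTTGTCTTCTTTGTGCATCACAAGAACAAC
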