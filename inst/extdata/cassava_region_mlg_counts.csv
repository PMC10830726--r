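marker_type,region,category,n
snp,Western South America,C1,943
snp,Western South America,C2,523
snp,Western South America,C3-C5,606
snp,Western South America,C6+,841
snp,Eastern South America,C1,399
snp,Eastern South America,C2,287
snp,Eastern South America,C3-C5,413
snp,Eastern South America,C6+,412
snp,Central/North America & Caribbean,C1,74
snp,Central/North America & Caribbean,C2,67
snp,Central/North America & Caribbean,C3-C5,108
snp,Central/North America & Caribbean,C6+,202
snp,Asia,C1,138
snp,Asia,C2,61
snp,Asia,C3-C5,81
snp,Asia,C6+,74
snp,Africa,C1,13
snp,Africa,C2,6
silico,Western South America,C1,947
silico,Western South America,C2,546
silico,Western South America,C3-C5,624
silico,Western South America,C6+,850
silico,Eastern South America,C1,400
silico,Eastern South America,C2,301
silico,Eastern South America,C3-C5,400
silico,Eastern South America,C6+,410
silico,Central/North America & Caribbean,C1,70
silico,Central/North America & Caribbean,C2,71
silico,Central/North America & Caribbean,C3-C5,104
silico,Central/North America & Caribbean,C6+,206
silico,Asia,C1,138
silico,Asia,C2,66
silico,Asia,C3-C5,78
silico,Asia,C6+,72
silico,Africa,C1,13
silico,Africa,C2,6
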