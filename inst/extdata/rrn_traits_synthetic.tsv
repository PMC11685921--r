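genus	mean_copies
SynGenus01	1.8
SynGenus02	2.1
SynGenus03	2.4
SynGenus04	1.5
SynGenus05	2.0
SynGenus06	4.6
SynGenus07	5.2
SynGenus08	5.9
SynGenus09	4.1
SynGenus10	6.3
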