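# species labels for the published Phaenoglyphis CO1 consensus barcodes
record_id	species
P_belizini	Phaenoglyphis belizini
P_evenhuisi	Phaenoglyphis evenhuisi
P_longicornis	Phaenoglyphis longicornis
P_salicis	Phaenoglyphis salicis
P_stricta	Phaenoglyphis stricta
P_villosa	Phaenoglyphis villosa
P_xanthochroa	Phaenoglyphis xanthochroa
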