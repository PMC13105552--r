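stratum,invitees,completers,positives,colonoscopies,detected_naa,detected_aa,detected_crc,total_cost_usd,crc_deaths_averted
overall,17780462,10364955,1582606,615912,114102,59954,5708,95231764,19026
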