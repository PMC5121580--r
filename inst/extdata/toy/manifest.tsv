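sample_id	class	temperature	file
untreated_01	untreated	NA	untreated_01.tsv
untreated_02	untreated	NA	untreated_02.tsv
untreated_03	untreated	NA	untreated_03.tsv
untreated_04	untreated	NA	untreated_04.tsv
untreated_05	untreated	NA	untreated_05.tsv
castor_01	castor	NA	castor_01.tsv
castor_02	castor	NA	castor_02.tsv
castor_03	castor	NA	castor_03.tsv
castor_04	castor	NA	castor_04.tsv
castor_05	castor	NA	castor_05.tsv
glycerol_01	glycerol	NA	glycerol_01.tsv
glycerol_02	glycerol	NA	glycerol_02.tsv
glycerol_03	glycerol	NA	glycerol_03.tsv
glycerol_04	glycerol	NA	glycerol_04.tsv
glycerol_05	glycerol	NA	glycerol_05.tsv
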