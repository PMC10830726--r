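accession_id,biological_status,country,common_names,collection_date,shape_central_leaf,petiole_color,color_first_expanded_leaf,number_leaf_lobes,color_root_pulp
GTM901,landrace,GTM,Guacamota-101,1978,lanceolate,green,light-green,7,white
GTM902,landrace,GTM,Guacamota-101,1985,ovoid,green,light-green,7,white
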