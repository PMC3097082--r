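(Dasiphora_fruticosa,Fragaria_vesca,Rosa_majalis,Sanguisorba_officinalis,Comarum_palustre,Sibbaldia_cuneata,Chamaerhodos_mongholica,((Potentilla_lignosa,(Potentilla_anserina,Potentilla_stenophylla,(Potentilla_microphylla,Potentilla_peduncularis)0.99)1.0)1.0,((Potentilla_biflora,((Potentilla_articulata,Potentilla_micrantha)0.98,(Potentilla_sterilis,Potentilla_alba)0.99,Potentilla_alchemilloides,Potentilla_caulescens,Potentilla_grammopetala,Potentilla_nitida))0.86,((Potentilla_erecta,Potentilla_indica,Potentilla_reptans)1.0,(Potentilla_dickinsii,((Potentilla_fragarioides,Potentilla_stolonifera)1.0,((Horkelia_fusca,Horkeliella_purpurascens,Ivesia_gordonii,Ivesia_kingii,Comarella_multifoliolata,(Horkelia_californica,Horkelia_bolanderi)0.96)1.0,(Potentilla_norvegica,(Potentilla_uniflora,Potentilla_subvahliana,Potentilla_gorodkovii,(Potentilla_villosa,Potentilla_pulvinaris)0.99)0.96,(Potentilla_chinensis,Potentilla_discolor)0.99,Potentilla_crantzii,Potentilla_recta,Potentilla_thuringiaca,Potentilla_tanacetifolia,Potentilla_kurdica,Potentilla_chrysantha,Potentilla_caucasica,Potentilla_tabernaemontani,Potentilla_neumanniana,Potentilla_multifida,Potentilla_pedersenii,Potentilla_rubricaulis,Potentilla_argentea,Potentilla_nepalensis,Potentilla_argyrophylla,Potentilla_atrosanguinea,Potentilla_pimpinelloides,Potentilla_hyparctica,Potentilla_crebridens,Potentilla_gracilis,Potentilla_hippiana,Potentilla_nivea,Potentilla_tollii,Potentilla_flabellifolia,Potentilla_fragiformis,Potentilla_grandiflora,Potentilla_montenegrina,Potentilla_thurberi,Potentilla_elegans)1.0)0.95)0.99)0.98)1.0)1.0)1.0);
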