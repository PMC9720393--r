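species_id,latin_name,guild,rice_associated,RG,RM,RC,RD
alopecurus_japonicus,Alopecurus japonicus,grass,NA,3,2,2,2
beckmannia_syzigachne,Beckmannia syzigachne,grass,NA,3,3,3,3
cynodon_dactylon,Cynodon dactylon,grass,NA,0,2,1,0
digitaria_sanguinalis,Digitaria sanguinalis,grass,NA,1,3,3,1
eleusine_indica,Eleusine indica,grass,NA,0,3,1,2
leptochloa_chinensis,Leptochloa chinensis,grass,NA,3,3,3,3
sclerochloa_dura,Sclerochloa dura,grass,NA,1,1,0,0
alopecurus_aequalis,Alopecurus aequalis,grass,NA,3,2,3,3
echinochloa_crusgalli,Echinochloa crusgalli,grass,NA,3,3,3,3
panicum_bisulcatum,Panicum bisulcatum,grass,NA,0,2,1,1
polypogon_fugax,Polypogon fugax,grass,NA,1,3,3,2
setaria_viridis,Setaria viridis,grass,NA,1,3,1,1
cyperus_difformis,Cyperus difformis,sedge,NA,3,3,3,3
cyperus_iria,Cyperus iria,sedge,NA,3,3,3,3
fimbristylis_miliacea,Fimbristylis miliacea,sedge,NA,1,2,1,0
heleocharis_yokoscensis,Heleocharis yokoscensis,sedge,NA,0,3,3,3
juncellus_serotinus,Juncellus serotinus,sedge,NA,0,0,1,0
kyllinga_brevifolia,Kyllinga brevifolia,sedge,NA,0,0,0,1
scirpus_juncoides,Scirpus juncoides,sedge,NA,2,2,3,2
scirpus_triangulatus,Scirpus triangulatus,sedge,NA,3,2,3,3
scirpus_wallichii,Scirpus wallichii,sedge,NA,0,1,3,3
scirpus_yagara,Scirpus yagara,sedge,NA,1,1,0,2
ajuga_ciliate,Ajuga ciliate,broadleaf,NA,0,1,0,0
najas_foveolate,Najas foveolate,broadleaf,NA,0,2,0,0
najas_minor,Najas minor,broadleaf,NA,3,3,3,3
acalypha_australis,Acalypha australis,broadleaf,NA,1,0,0,1
astragalus_sinicus,Astragalus sinicus,broadleaf,NA,2,0,0,0
glycine_soja,Glycine soja,broadleaf,NA,1,0,0,0
medicago_polymorpha,Medicago polymorpha,broadleaf,NA,1,0,1,0
vicia_gigantea,Vicia gigantea,broadleaf,NA,1,0,1,0
vicia_hirsuta,Vicia hirsuta,broadleaf,NA,2,0,0,0
aeschynomene_indica,Aeschynomene indica,broadleaf,NA,1,0,1,0
carpesium_abrotanoides,Carpesium abrotanoides,broadleaf,NA,0,2,0,0
eclipta_prostrata,Eclipta prostrata,broadleaf,NA,2,2,1,0
lapsana_apogonoides,Lapsana apogonoides,broadleaf,NA,3,3,1,1
hemistepta_lyrate,Hemistepta lyrate,broadleaf,NA,1,3,3,3
chenopodium_album,Chenopodium album,broadleaf,NA,1,3,3,3
polygonum_aviculare,Polygonum aviculare,broadleaf,NA,2,3,3,0
polygonum_lapathifolium,Polygonum lapathifolium,broadleaf,NA,2,3,2,2
polygonum_nepalense,Polygonum nepalense,broadleaf,NA,0,1,1,0
polygonum_posumbu,Polygonum posumbu,broadleaf,NA,0,3,0,0
polygonum_viscosum,Polygonum viscosum,broadleaf,NA,2,2,0,0
rumex_dentatus,Rumex dentatus,broadleaf,NA,0,3,2,0
ludwigia_prostrata,Ludwigia prostrata,broadleaf,NA,3,3,3,3
geranium_carolinianum,Geranium carolinianum,broadleaf,NA,1,0,1,0
clematis_hexapetala,Clematis hexapetala,broadleaf,NA,3,3,3,2
ammannia_baccifera,Ammannia baccifera,broadleaf,NA,3,3,3,3
ammannia_multiflora,Ammannia multiflora,broadleaf,NA,3,2,2,3
rotala_indica,Rotala indica,broadleaf,NA,3,3,3,3
galium_aparine,Galium aparine,broadleaf,NA,1,1,2,3
cnidium_monnieri,Cnidium monnieri,broadleaf,NA,1,0,0,0
capsella_bursa_pastoris,Capsella bursa-pastoris,broadleaf,NA,3,2,0,2
rorippa_indica,Rorippa indica,broadleaf,NA,1,1,2,1
myosoton_aquaticum,Myosoton aquaticum,broadleaf,NA,3,3,3,3
lindernia_procumbens,Lindernia procumbens,broadleaf,NA,3,3,3,3
mazus_japonicus,Mazus japonicus,broadleaf,NA,3,3,3,3
veronica_peregrina,Veronica peregrina,broadleaf,NA,1,1,0,3
veronica_undulata,Veronica undulata,broadleaf,NA,0,1,0,2
monochoria_vaginalis,Monochoria vaginalis,broadleaf,NA,3,3,3,3
alisma_plantago_aquatica,Alisma plantago-aquatica,broadleaf,NA,0,1,1,2
trigonotis_peduncularis,Trigonotis peduncularis,broadleaf,NA,0,0,1,1
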