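species,common_name,sightings,jacobs_index,monocot_prop
elephant,Elephant,14,-0.87,0.23
giraffe,Giraffe,128,0.24,0.05
buffalo,Buffalo,1,0.32,0.78
eland,Eland,34,0.18,0.50
zebra,Zebra,498,0.16,0.92
wildebeest,Wildebeest,118,0.27,0.81
waterbuck,Waterbuck,20,0.18,0.84
warthog,Warthog,15,0.11,0.91
lesser_kudu,Lesser kudu,16,-0.20,0.34
grants_gazelle,Grant's gazelle,96,-0.56,0.65
impala,Impala,137,-0.73,0.40
gerenuk,Gerenuk,2,-0.73,0.00
thomsons_gazelle,Thomson's gazelle,85,-0.62,0.75
olive_baboon,Olive baboon,2,-0.89,0.20
steenbok,Steenbok,6,-0.86,0.34
black_backed_jackal,Black-backed jackal,9,-1.00,0.06
kirks_dikdik,Kirk's dik-dik,57,-0.88,0.17
vervet_monkey,Vervet monkey,16,-1.00,0.07
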