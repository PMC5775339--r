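taxon,common_name,group,subgroup,origin
polar_cod,Polar cod (Boreogadus saida),fish,fish,arctic
capelin,Capelin (Mallotus villosus),fish,atlantic_fish,atlantic
atlantic_herring,Atlantic herring (Clupea harengus),fish,atlantic_fish,atlantic
atlantic_cod,Atlantic cod (Gadus morhua),fish,atlantic_fish,atlantic
haddock,Haddock (Melanogrammus aeglefinus),fish,atlantic_fish,atlantic
glacier_lanternfish,Glacier lanternfish (Benthosema glaciale),fish,other_fish,mesopelagic
white_barracudina,White barracudina (Arctozenus risso),fish,other_fish,mesopelagic
daubed_shanny,Daubed shanny (Leptoclinus maculatus),fish,other_fish,intermediate
snake_blenny,Snake blenny (Lumpenus lampretaeformis),fish,other_fish,intermediate
rockfish,Rockfish (Sebastes spp.),fish,other_fish,intermediate
shorthorn_sculpin,Shorthorn sculpin (Myoxocephalus scorpius),fish,other_fish,intermediate
threespot_eelpout,Threespot eelpout (Lycodes rossi),fish,other_fish,intermediate
unidentified_fish,Unidentified fish,fish,unidentified_fish,unidentified
thysanoessa_inermis,Krill (Thysanoessa inermis),crustacea,krill,intermediate
thysanoessa_longicaudata,Krill (Thysanoessa longicaudata),crustacea,krill,intermediate
themisto_libellula,Amphipod (Themisto libellula),crustacea,amphipod,arctic
themisto_abyssorum,Amphipod (Themisto abyssorum),crustacea,amphipod,intermediate
pandalus_borealis,Northern prawn (Pandalus borealis),crustacea,shrimp,intermediate
pasiphaea_tarda,Crimson pasiphaeid (Pasiphaea tarda),crustacea,shrimp,mesopelagic
unidentified_crustacea,Unidentified Crustacea,crustacea,unidentified_crustacea,unidentified
nereis,Polychaetes (Nereis spp.),other,polychaete,intermediate
limacina_helicina,Pteropod (Limacina helicina),other,pteropod,intermediate
parasagitta_elegans,Chaetognath (Parasagitta elegans),other,chaetognath,intermediate
cephalopods,Cephalopods,other,cephalopod,intermediate
trawler_waste,Trawler waste,other,waste,intermediate
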