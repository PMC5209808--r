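disease_id,disease_name,category,diagnostics,vaccines,pharmaceuticals
peste_des_petits_ruminants,Peste des petits ruminants,epizootic,-5,-10,20
african_swine_fever,African swine fever,epizootic,-50,40,40
rift_valley_fever,Rift valley fever,epizootic,29,18,40
foot_and_mouth_disease,Foot and mouth disease,epizootic,-32,-20,40
african_horse_sickness,African horse sickness,epizootic,-18,20,10
contagious_bovine_pleuropneumonia,Contagious bovine pleuropneumonia,epizootic,9,30,25
classical_swine_fever,Classical swine fever,epizootic,-23,-50,40
lumpy_skin_disease,Lumpy skin disease,epizootic,27,-5,40
bluetongue,Bluetongue,epizootic,-27,-15,40
orthopox,Orthopox,epizootic,18,40,15
poultry_coccidiosis,Poultry coccidiosis,food_producing_complex,9,5,-35
paratuberculosis,Paratuberculosis,food_producing_complex,0,0,40
liver_fluke,Liver fluke,food_producing_complex,-9,40,-25
nematodes,Nematodes,food_producing_complex,-5,40,-65
bovine_viral_diarrhoea_virus,Bovine viral diarrhoea virus,food_producing_complex,-27,-10,40
porcine_circo_virus_type_2,Porcine circo virus type 2,food_producing_complex,20,-40,40
small_ruminant_mastitis,Small ruminant mastitis,food_producing_complex,-23,-5,-50
varroa_mite,Varroa mite,food_producing_complex,40,40,-10
staphylococcus_aureus_mastitis,Staphylococcus aureus mastitis,food_producing_complex,14,0,-30
theileria,Theileria,food_producing_complex,27,40,-30
nipah_virus,Nipah virus,zoonotic,0,0,0
bovine_tuberculosis,Bovine tuberculosis,zoonotic,-18,10,40
non_tse_tse_transmitted_animal_trypanosomiasis,Non tse-tse transmitted animal trypanosomiasis,zoonotic,32,40,15
cryptosporidiosis,Cryptosporidiosis,zoonotic,0,40,-45
salmonellosis,Salmonellosis,zoonotic,-23,-30,-35
leishmaniosis,Leishmaniosis,zoonotic,-14,35,-20
brucellosis,Brucellosis,zoonotic,-5,20,40
leptospirosis,Leptospirosis,zoonotic,-5,5,-60
hepatitis_e_virus,Hepatitis E virus,zoonotic,-32,40,40
anthrax,Anthrax,zoonotic,36,5,-45
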