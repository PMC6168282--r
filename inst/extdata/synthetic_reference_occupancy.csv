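species,study,occupancy,diet_class
snow_leopard,study_01,0.21,carnivore
snow_leopard,study_02,0.27,carnivore
jaguar,study_03,0.45,carnivore
puma,study_03,0.52,carnivore
puma,study_04,0.48,carnivore
ocelot,study_03,0.38,carnivore
leopard,study_05,0.41,carnivore
leopard,study_06,0.35,carnivore
tiger,study_06,0.18,carnivore
dhole,study_06,0.22,carnivore
golden_cat,study_05,0.30,carnivore
serval,study_07,0.44,carnivore
caracal,study_07,0.26,carnivore
african_wild_dog,study_07,0.15,carnivore
spotted_hyena,study_07,0.58,carnivore
maned_wolf,study_08,0.33,carnivore
pampas_cat,study_08,0.24,carnivore
wolverine,study_09,0.19,carnivore
lynx,study_09,0.36,carnivore
red_fox_eur,study_09,0.49,carnivore
pine_marten,study_09,0.42,carnivore
raccoon_ref,study_04,0.81,omnivore
coati,study_03,0.62,omnivore
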