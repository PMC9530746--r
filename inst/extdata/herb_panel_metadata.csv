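sample_id,name,label
herb01,Platycladi Cacumen,cold
herb02,Kochiae Fructus,cold
herb03,Ecliptae Herba,cold
herb04,Isatidis Folium,cold
herb05,Rhei Radix et Rhizoma,cold
herb06,Asparagi Radix,cold
herb07,Fritillariae Cirrhosae Bulbus,cold
herb08,Bupleuri Radix,cold
herb09,Gardeniae Fructus,cold
herb10,Rhizoma Anemarrhenae with Peel,cold
herb11,Sargassum,cold
herb12,Lophatheri Herba,cold
herb13,Trichosanthis Fructus,cold
herb14,Kansui Radix,cold
herb15,Dried Rehmannia Root,cold
herb16,Dianthi Herba,cold
herb17,Fraxini Cortex,cold
herb18,Arnebiae Radix,cold
herb19,Trachelospermi Caulis et Folium,cold
herb20,Aloe,cold
herb21,Puerariae Lobatae Radix,cold
herb22,Taraxaci Herba,cold
herb23,Menthae Haplocalycis Herba,cold
herb24,Alizaris Radix,cold
herb25,Plantaginis Semen,cold
herb26,Lonicerae Japonicae Flos,cold
herb27,Stephaniae Tetrandrae Radix,cold
herb28,Phellodendri Chinensis Cortex,cold
herb29,Coptidis Rhizome,cold
herb30,Gentianae Radix et Rhizoma,cold
herb31,Curculiginis Rhizoma,hot
herb32,Pinelliae Rhizoma,hot
herb33,Magnoliae Officinalis Cortex,hot
herb34,Euodiae Fructus,hot
herb35,Arisaematis Rhizoma,hot
herb36,Ephedrae Herba,hot
herb37,Chuanxiong Rhizoma,hot
herb38,Zingiberis Rhizoma,hot
herb39,Corydalis Rhizoma,hot
herb40,Chaenomelis Fructus,hot
herb41,Aucklandiae Radix,hot
herb42,Eucommiae Cortex,hot
herb43,Santali Albi Lignum,hot
herb44,Epimedii Folium,hot
herb45,Roasted Corydalis,hot
herb46,Nardostachyos Radix et Rhizoma,hot
herb47,Fructus Piperis Alba,hot
herb48,Mustard Seeds,hot
herb49,Carthami Flos,hot
herb50,Asari Radix et Rhizoma,hot
herb51,Notopterygii Rhizoma et Radix,hot
herb52,Cinnamomi Cortex,hot
herb53,Atractylodis Rhizome,hot
herb54,Alpiniae Katsumadai Semen,hot
herb55,Piperis Longi Fructus,hot
herb56,Ligustici Rhizoma et Radix,hot
herb57,Psoraleae Fructus,hot
herb58,Aconiti Lateralis Radix Praeparata,hot
herb59,Citri Reticulatae Pericarpium,hot
herb60,Alpiniae Officinarum Rhizoma,hot
herb61,Clematidis Radix et Rhizoma,hot
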