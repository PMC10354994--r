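scope,subclass,name,archetype,route,product_type
prevention,Amino acid-peptide,AG126,new_entity,Unspecified,drug
prevention,Amino acid-peptide,AG1288,new_entity,Unspecified,drug
prevention,Amino acid-peptide,Anti-Toll-like receptor 4 (TLR4) monoclonal antibody,new_entity,Intravenous,biologic
prevention,Amino acid-peptide,Etanercept,repurposed,Unspecified,biologic
prevention,Amino acid-peptide,Histone deacetylase inhibitors (nanosuspension),new_entity,Vaginal,drug
prevention,Amino acid-peptide,IMD-0560,new_entity,Vaginal,drug
prevention,Amino acid-peptide,Melatonin,repurposed,Oral,dietary_supplement
prevention,Amino acid-peptide,NS-398,new_entity,Intravenous,drug
prevention,Amino acid-peptide,Rytvela,new_entity,Unspecified,drug
prevention,Amino acid-peptide,SB 202190,new_entity,Unspecified,drug
prevention,Amino acid-peptide,SB 239063,new_entity,Unspecified,drug
prevention,Amino acid-peptide,Super-repressor (SR) IkB-alpha (exosome delivery),new_entity,Injection,biologic
prevention,Amino acid-peptide,Synthetic TLR4,new_entity,Intravenous,biologic
prevention,Amino acid-peptide,Vaginal progesterone (nanosuspension),new_entity,"Vaginal, rectal, topical",drug
prevention,Antibiotics,Sirolimus,repurposed,Oral,drug
prevention,Anti-depressant,Rolipram,new_entity,"Oral, injectable",drug
prevention,Cell therapy,Exosome-based protein therapeutics,new_entity,Injectable,biologic
prevention,Cell therapy,Pen-NBD (cell-penetrating peptide delivery),new_entity,Intravenous,biologic
prevention,Disease-modifying anti-rheumatic drugs,Sulfasalazine,repurposed,Oral,drug
prevention,Enzyme inhibitors (statins),Simvastatin,repurposed,Oral,drug
prevention,Herbal,Abeliophyllum distichum Nakai leaf extract,new_entity,Oral,dietary_supplement
prevention,Herbal,Astragali radix extract,repurposed,Oral,dietary_supplement
prevention,Herbal,Cucurbita moschata extract,repurposed,Oral,dietary_supplement
prevention,Herbal,Parthenolide,new_entity,"Oral; intravenous",dietary_supplement
prevention,Immunosuppressant,Tocilizumab,repurposed,"Intravenous, subcutaneous",biologic
prevention,Opioid receptor antagonist,(+)-Naloxone,new_entity,"Intravenous, intramuscular, intraperitoneal, oral",drug
prevention,Opioid receptor antagonist,(+)-Naltrexone,new_entity,"Intravenous, intramuscular, intraperitoneal, oral",drug
prevention,Organic compound,U-0126,new_entity,Subcutaneous,drug
prevention,Polyphenol,Gallic acid,repurposed,Oral,dietary_supplement
prevention,Polyphenol,Honokial,repurposed,Oral,dietary_supplement
prevention,Polyphenol,Nobiletin,repurposed,Oral,dietary_supplement
prevention,Polyphenol,Resveratrol,repurposed,Oral,dietary_supplement
prevention,Probiotics,Microbiome therapeutics,new_entity,Unspecified,biologic
prevention,Small molecule,Sc514,new_entity,Unspecified,drug
prevention,Small molecule,TPCA-1,new_entity,Unspecified,drug
prevention,Unclassified,Replens gel,repurposed,Vaginal,drug
management,Amino acid-peptide,15d-PGJ2,new_entity,Intravenous,drug
management,Amino acid-peptide,Azapeptide analogues,new_entity,Subcutaneous,drug
management,Amino acid-peptide,BRL 37344,new_entity,Unspecified,drug
management,Amino acid-peptide,Butaprost,new_entity,Unspecified,drug
management,Amino acid-peptide,CyPPA,new_entity,Injectable,drug
management,Amino acid-peptide,Exedine-4,repurposed,"Subcutaneous, intravenous",biologic
management,Amino acid-peptide,Leptin,repurposed,"Oral, subcutaneous",biologic
management,Amino acid-peptide,N-acetylcysteine (nanoparticle delivery),new_entity,Intravenous,drug
management,Amino acid-peptide,PDC113.824,new_entity,Injectable,drug
management,Amino acid-peptide,SCH-772984,new_entity,Unspecified,drug
management,Amino acid-peptide,SKF-86002,new_entity,Unspecified,drug
management,Amino acid-peptide,Surfactant protein A,new_entity,Injection,biologic
management,Anti-depressant,Rolipram,new_entity,"Oral, injectable",drug
management,Anti-convulsant,Retigabine,repurposed,Oral,drug
management,Anti-malarial,Chloroquine/hydroxychloroquine,repurposed,"Intravenous, oral",drug
management,Herbal,Carvacrol,new_entity,Unspecified,dietary_supplement
management,Herbal,"Ananas comosus, ethyl acetate fraction",repurposed,Oral,dietary_supplement
management,Herbal,Curcuma aeruginosa rhizome,repurposed,Unspecified,dietary_supplement
management,Herbal,Pimpinella anisum extract,repurposed,Oral,dietary_supplement
management,Herbal,Paeoniflorin,new_entity,Intravenous,dietary_supplement
management,Hydrogen sulfide donors,GYY4137,new_entity,Intravenous,drug
management,Muscle relaxant,Botulinum toxin A,repurposed,"Intramuscular, intravenous",biologic
management,Organic compound,"1,10-Phenatroline",new_entity,Unspecified,drug
management,Organic compound,Alpha-bisabolol,repurposed,Unspecified,drug
management,Organic compound,Citral,repurposed,"Oral, intravenous",drug
management,Organic compound,OXznl,new_entity,Injectable,drug
management,Polyphenol,"Galetin 3,6-dimethyl ether",repurposed,"Intravenous, oral",dietary_supplement
management,Polyphenol,Resveratrol,new_entity,Unspecified,dietary_supplement
management,Polyphenol,Scutellaria baicalensis root extract,repurposed,Oral,dietary_supplement
management,Polyphenol,Tannic acid,repurposed,"Oral, vaginal, topical",dietary_supplement
management,Proton-pump inhibitors,Esomeprazole,repurposed,"Oral, intravenous",drug
management,Proton-pump inhibitors,Lansoprazole,repurposed,"Oral, intravenous",drug
management,Proton-pump inhibitors,Omeprazole,repurposed,"Oral, intravenous",drug
management,Proton-pump inhibitors,Pantoprazole,repurposed,"Oral, intravenous",drug
management,Proton-pump inhibitors,Rabeprazole,repurposed,"Oral, intravenous",drug
management,Thalidomide analogue,4APDPMe,new_entity,"Intravenous, intramuscular",drug
management,Thalidomide analogue,4NO2DPDMe,new_entity,"Intravenous, intramuscular",drug
management,Tocolytic,AS603831,new_entity,"Oral, intravenous",drug
management,Tocolytic,AS604872,new_entity,Oral,drug
management,Tocolytic,HC067047,new_entity,Intraperitoneal,drug
management,Tocolytic,Hydrozone sulfanilide oxytocin antagonists,new_entity,Intravenous,drug
management,Tocolytic,Indomethacin (nanoparticle delivery),new_entity,Oral,drug
management,Tocolytic,PGN-1473,new_entity,Intrauterine,drug
management,Tocolytic,PGN-9856,new_entity,Injectable,drug
management,Tocolytic,Salbutamol (nanoparticle delivery),repurposed,Unspecified,drug
management,Tocolytic,SAR-150640,new_entity,Parenteral,drug
management,Tocolytic,THG113.31,new_entity,"Intravenous, topical",drug
management,Uricosuric agent,Benzbromarone,repurposed,Oral,drug
management,Vascular agents,Amiloride,repurposed,"Oral, intraperitoneal",drug
management,Vascular agents,Isradipine,repurposed,Oral,drug
management,Vascular agents,LDD175,new_entity,Injectable,drug
management,Vascular agents,Levosimendan,repurposed,"Intravenous, oral",drug
management,Vascular agents,MONNA,new_entity,Unspecified,drug
management,Vascular agents,Nebivolol,repurposed,Oral,drug
management,Vascular agents,Nifedipine (nanoparticle delivery),new_entity,"Intravenous, oral, rectal",drug
management,Vascular agents,Pinacidil,repurposed,Oral,drug
management,Vascular agents,S-Nitrocysteine,new_entity,Injectable,drug
management,Vascular agents,ZD-7288,new_entity,Unspecified,drug
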