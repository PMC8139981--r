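{
  "snapshot": "bathymet-panel-derived-1.0",
  "note": "Pathway-block module definitions assembled from the shipped energy-metabolism marker panel. Module completeness is the flat percentage of a module's KOs present in a genome; users analysing real genomes should supply their own KEGG module snapshot in this same format.",
  "modules": [
    {"module_id": "mod_rtca", "label": "Reductive citrate (rTCA) cycle markers", "kos": ["K15230", "K15231"]},
    {"module_id": "mod_cbb", "label": "Calvin-Benson-Bassham cycle markers", "kos": ["K00855", "K01601", "K01602"]},
    {"module_id": "mod_3hp", "label": "3-hydroxypropionate bi-cycle markers", "kos": ["K08691", "K14468", "K14470", "K09709"]},
    {"module_id": "mod_hphb", "label": "Hydroxypropionate-hydroxybutyrate cycle markers", "kos": ["K15039", "K15016", "K14534"]},
    {"module_id": "mod_co_ox", "label": "Aerobic CO oxidation (coxSML)", "kos": ["K03518", "K03519", "K03520"]},
    {"module_id": "mod_h2_ox", "label": "Hydrogen oxidation (hoxH)", "kos": ["K00436"]},
    {"module_id": "mod_methane_ox", "label": "Methane oxidation markers", "kos": ["K16158", "K10944", "K10945", "K10946"]},
    {"module_id": "mod_com_biosyn", "label": "Coenzyme M biosynthesis", "kos": ["K05979", "K06034", "K08097", "K13039"]},
    {"module_id": "mod_c1_methanogenesis", "label": "C1 metabolism / methanogenesis markers", "kos": ["K00320", "K00200", "K00201", "K00202", "K00672", "K03390", "K14083", "K00577"]},
    {"module_id": "mod_nitrification", "label": "Nitrification (amoCAB + nxr)", "kos": ["K10944", "K10945", "K10946", "K00370", "K00371"]},
    {"module_id": "mod_n_fixation", "label": "Nitrogen fixation (nifHDK)", "kos": ["K02588", "K02586", "K02591"]},
    {"module_id": "mod_dnra", "label": "Dissimilatory nitrate reduction to ammonium (nirBD)", "kos": ["K00362", "K00363"]},
    {"module_id": "mod_denitrification", "label": "Denitrification", "kos": ["K00368", "K15864", "K04561", "K02305", "K00376", "K00374", "K02567", "K02568"]},
    {"module_id": "mod_assim_nitrate", "label": "Assimilatory nitrate reduction", "kos": ["K00367", "K00372"]},
    {"module_id": "mod_dissim_sulfate", "label": "Dissimilatory sulfate reduction (aprAB + dsrB)", "kos": ["K00394", "K00395", "K11181"]},
    {"module_id": "mod_sox", "label": "Thiosulfate oxidation SOX system", "kos": ["K17222", "K17223", "K17224", "K17225", "K17226", "K17227"]}
  ]
}
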