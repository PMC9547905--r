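{
  "metabolites": [
    {
      "id": "ser",
      "name": "L-serine",
      "compartment": "c"
    },
    {
      "id": "palmcoa",
      "name": "palmitoyl-CoA",
      "compartment": "c"
    },
    {
      "id": "3ksa",
      "name": "3-ketosphinganine",
      "compartment": "c"
    },
    {
      "id": "sphinganine",
      "name": "sphinganine",
      "compartment": "c"
    },
    {
      "id": "dhcer",
      "name": "dihydroceramide",
      "compartment": "c"
    },
    {
      "id": "cer",
      "name": "ceramide",
      "compartment": "c"
    },
    {
      "id": "sphingosine",
      "name": "sphingosine",
      "compartment": "c"
    },
    {
      "id": "sa1p",
      "name": "sphinganine-1-phosphate",
      "compartment": "c"
    },
    {
      "id": "c1p",
      "name": "ceramide-1-phosphate",
      "compartment": "c"
    },
    {
      "id": "sm",
      "name": "sphingomyelin",
      "compartment": "c"
    },
    {
      "id": "s1p",
      "name": "sphingosine-1-phosphate",
      "compartment": "c"
    },
    {
      "id": "glccer",
      "name": "glucosylceramide",
      "compartment": "c"
    },
    {
      "id": "laccer",
      "name": "lactosylceramide",
      "compartment": "c"
    },
    {
      "id": "galcer",
      "name": "galactosylceramide",
      "compartment": "c"
    },
    {
      "id": "hexadecenal",
      "name": "hexadecenal",
      "compartment": "c"
    },
    {
      "id": "pethanolamine",
      "name": "phosphoethanolamine",
      "compartment": "c"
    }
  ],
  "reactions": [
    {
      "id": "SPT",
      "stoichiometry": {
        "ser": -1,
        "palmcoa": -1,
        "3ksa": 1
      },
      "reversible": false,
      "lb": 0,
      "ub": 1000,
      "pseudo": false,
      "label": "A",
      "gene_rule": "(SPTLC1 and SPTLC2) or (SPTLC1 and SPTLC3)"
    },
    {
      "id": "KSR",
      "stoichiometry": {
        "3ksa": -1,
        "sphinganine": 1
      },
      "reversible": false,
      "lb": 0,
      "ub": 1000,
      "pseudo": false,
      "label": "B",
      "gene_rule": "KDSR"
    },
    {
      "id": "CERS_DN",
      "stoichiometry": {
        "sphinganine": -1,
        "dhcer": 1
      },
      "reversible": false,
      "lb": 0,
      "ub": 1000,
      "pseudo": false,
      "label": "C",
      "gene_rule": "CERS1 or CERS2 or CERS3 or CERS4 or CERS5 or CERS6"
    },
    {
      "id": "DES",
      "stoichiometry": {
        "dhcer": -1,
        "cer": 1
      },
      "reversible": false,
      "lb": 0,
      "ub": 1000,
      "pseudo": false,
      "label": "D",
      "gene_rule": "DEGS1"
    },
    {
      "id": "SPHK_SA",
      "stoichiometry": {
        "sphinganine": -1,
        "sa1p": 1
      },
      "reversible": false,
      "lb": 0,
      "ub": 1000,
      "pseudo": false,
      "label": "I",
      "gene_rule": "SPHK1 or SPHK2"
    },
    {
      "id": "CDASE",
      "stoichiometry": {
        "cer": -1,
        "sphingosine": 1
      },
      "reversible": false,
      "lb": 0,
      "ub": 1000,
      "pseudo": false,
      "label": "E",
      "gene_rule": "ACER1 or ACER2 or ASAH1 or ASAH2"
    },
    {
      "id": "CERS_SALV",
      "stoichiometry": {
        "sphingosine": -1,
        "cer": 1
      },
      "reversible": false,
      "lb": 0,
      "ub": 1000,
      "pseudo": false,
      "label": "C",
      "gene_rule": "CERS1 or CERS2 or CERS3 or CERS4 or CERS5 or CERS6"
    },
    {
      "id": "CERK",
      "stoichiometry": {
        "cer": -1,
        "c1p": 1
      },
      "reversible": false,
      "lb": 0,
      "ub": 1000,
      "pseudo": false,
      "label": "F",
      "gene_rule": "CERK"
    },
    {
      "id": "SMS",
      "stoichiometry": {
        "cer": -1,
        "sm": 1
      },
      "reversible": true,
      "lb": -1000,
      "ub": 1000,
      "pseudo": false,
      "label": "G",
      "gene_rule": "SGMS1 or SGMS2"
    },
    {
      "id": "SMASE",
      "stoichiometry": {
        "sm": -1,
        "cer": 1
      },
      "reversible": false,
      "lb": 0,
      "ub": 1000,
      "pseudo": false,
      "label": "H",
      "gene_rule": "SMPD1 or SMPD2 or SMPD3 or ENPP7"
    },
    {
      "id": "SPHK",
      "stoichiometry": {
        "sphingosine": -1,
        "s1p": 1
      },
      "reversible": false,
      "lb": 0,
      "ub": 1000,
      "pseudo": false,
      "label": "I",
      "gene_rule": "SPHK1 or SPHK2"
    },
    {
      "id": "SGPP",
      "stoichiometry": {
        "s1p": -1,
        "sphingosine": 1
      },
      "reversible": false,
      "lb": 0,
      "ub": 1000,
      "pseudo": false,
      "label": "J",
      "gene_rule": "SGPP1 or SGPP2 or PLPP2"
    },
    {
      "id": "SGPL",
      "stoichiometry": {
        "s1p": -1,
        "hexadecenal": 1,
        "pethanolamine": 1
      },
      "reversible": false,
      "lb": 0,
      "ub": 1000,
      "pseudo": false,
      "label": "K",
      "gene_rule": "SGPL1"
    },
    {
      "id": "UGCG",
      "stoichiometry": {
        "cer": -1,
        "glccer": 1
      },
      "reversible": false,
      "lb": 0,
      "ub": 1000,
      "pseudo": false,
      "gene_rule": "UGCG"
    },
    {
      "id": "GCDASE",
      "stoichiometry": {
        "glccer": -1,
        "cer": 1
      },
      "reversible": false,
      "lb": 0,
      "ub": 1000,
      "pseudo": false,
      "gene_rule": "GBA or GBA2"
    },
    {
      "id": "LACCS",
      "stoichiometry": {
        "glccer": -1,
        "laccer": 1
      },
      "reversible": false,
      "lb": 0,
      "ub": 1000,
      "pseudo": false,
      "gene_rule": "B4GALT5 or B4GALT6"
    },
    {
      "id": "CGT",
      "stoichiometry": {
        "cer": -1,
        "galcer": 1
      },
      "reversible": false,
      "lb": 0,
      "ub": 1000,
      "pseudo": false,
      "gene_rule": "UGT8"
    },
    {
      "id": "GALCDASE",
      "stoichiometry": {
        "galcer": -1,
        "cer": 1
      },
      "reversible": false,
      "lb": 0,
      "ub": 1000,
      "pseudo": false,
      "gene_rule": "GALC"
    },
    {
      "id": "EX_ser",
      "stoichiometry": {
        "ser": 1
      },
      "reversible": false,
      "lb": 0,
      "ub": 1000,
      "pseudo": true
    },
    {
      "id": "EX_palmcoa",
      "stoichiometry": {
        "palmcoa": 1
      },
      "reversible": false,
      "lb": 0,
      "ub": 1000,
      "pseudo": true
    },
    {
      "id": "DM_sa1p",
      "stoichiometry": {
        "sa1p": -1
      },
      "reversible": false,
      "lb": 0,
      "ub": 1000,
      "pseudo": true
    },
    {
      "id": "DM_c1p",
      "stoichiometry": {
        "c1p": -1
      },
      "reversible": false,
      "lb": 0,
      "ub": 1000,
      "pseudo": true
    },
    {
      "id": "DM_sm",
      "stoichiometry": {
        "sm": -1
      },
      "reversible": false,
      "lb": 0,
      "ub": 1000,
      "pseudo": true
    },
    {
      "id": "DM_laccer",
      "stoichiometry": {
        "laccer": -1
      },
      "reversible": false,
      "lb": 0,
      "ub": 1000,
      "pseudo": true
    },
    {
      "id": "DM_hexadecenal",
      "stoichiometry": {
        "hexadecenal": -1
      },
      "reversible": false,
      "lb": 0,
      "ub": 1000,
      "pseudo": true
    },
    {
      "id": "DM_pethanolamine",
      "stoichiometry": {
        "pethanolamine": -1
      },
      "reversible": false,
      "lb": 0,
      "ub": 1000,
      "pseudo": true
    }
  ],
  "objective": [
    {
      "rxn": "DM_c1p",
      "weight": 1
    },
    {
      "rxn": "DM_sm",
      "weight": 1
    },
    {
      "rxn": "DM_laccer",
      "weight": 1
    },
    {
      "rxn": "DM_hexadecenal",
      "weight": 1
    }
  ]
}
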