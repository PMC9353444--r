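# Synthetic stand-in functional taxonomy: 132 molecular-function classes
# partitioned into 16 groups. Class names follow Uniprot-style molecular
# function keywords; the partition is fixed and closed (no free text).
class	group
Actin-binding	actin-binding and motor protein
Actin capping	actin-binding and motor protein
Motor protein	actin-binding and motor protein
Myosin	actin-binding and motor protein
Kinesin	actin-binding and motor protein
Dynein	actin-binding and motor protein
Antibiotic	antimicrobial
Antimicrobial peptide	antimicrobial
Defensin	antimicrobial
Bacteriolytic enzyme	antimicrobial
Antiviral protein	antimicrobial
Fungicide	antimicrobial
Cytokine	cytokine
Chemokine	cytokine
Interleukin	cytokine
Interferon	cytokine
Tumor necrosis factor	cytokine
Lymphokine	cytokine
Oxidoreductase	enzyme
Isomerase	enzyme
Ligase	enzyme
Lyase	enzyme
Dioxygenase	enzyme
Monooxygenase	enzyme
Oxidase	enzyme
Reductase	enzyme
Dehydrogenase	enzyme
Peroxidase	enzyme
Decarboxylase	enzyme
Dehydratase	enzyme
Epimerase	enzyme
Mutase	enzyme
Racemase	enzyme
Aldolase	enzyme
Synthase	enzyme
Carboxylase	enzyme
Deaminase	enzyme
Dismutase	enzyme
Growth factor	growth factor
Mitogen	growth factor
Neurotrophic factor	growth factor
Angiogenic factor	growth factor
Morphogen	growth factor
Hormone	hormone
Peptide hormone	hormone
Neuropeptide	hormone
Neurohormone	hormone
Incretin	hormone
Hydrolase	hydrolase
Protease	hydrolase
Serine protease	hydrolase
Cysteine protease	hydrolase
Aspartyl protease	hydrolase
Metalloprotease	hydrolase
Threonine protease	hydrolase
Carboxypeptidase	hydrolase
Aminopeptidase	hydrolase
Dipeptidase	hydrolase
Esterase	hydrolase
Lipase	hydrolase
Phospholipase	hydrolase
Glycosidase	hydrolase
Nuclease	hydrolase
Endonuclease	hydrolase
Exonuclease	hydrolase
Phosphatase	hydrolase
Ion channel	ion channel
Calcium channel	ion channel
Chloride channel	ion channel
Potassium channel	ion channel
Sodium channel	ion channel
Ligand-gated ion channel	ion channel
Voltage-gated channel	ion channel
Porin	ion channel
Protease inhibitor	protein metabolism regulator
Serine protease inhibitor	protein metabolism regulator
Cysteine protease inhibitor	protein metabolism regulator
Metalloprotease inhibitor	protein metabolism regulator
Chaperone	protein metabolism regulator
Co-chaperone	protein metabolism regulator
Proteasome component	protein metabolism regulator
Autophagy regulator	protein metabolism regulator
Receptor	receptor
G-protein coupled receptor	receptor
Receptor tyrosine kinase	receptor
Cytokine receptor	receptor
Chemokine receptor	receptor
Hormone receptor	receptor
Pattern recognition receptor	receptor
Scavenger receptor	receptor
Transmembrane receptor	receptor
Olfactory receptor	receptor
Transcription regulator	transcription regulator
Activator	transcription regulator
Repressor	transcription regulator
DNA-binding protein	transcription regulator
Sigma factor	transcription regulator
Homeobox protein	transcription regulator
Zinc finger transcription factor	transcription regulator
Chromatin regulator	transcription regulator
Transducer	transducer
G-protein	transducer
GTPase	transducer
Guanine nucleotide exchange factor	transducer
GTPase-activating protein	transducer
Adapter protein	transducer
Calmodulin-binding protein	transducer
Second messenger enzyme	transducer
Transferase	transferase
Kinase	transferase
Serine/threonine-protein kinase	transferase
Tyrosine-protein kinase	transferase
Acyltransferase	transferase
Glycosyltransferase	transferase
Methyltransferase	transferase
Aminotransferase	transferase
Nucleotidyltransferase	transferase
Phosphorylase	transferase
Translation regulator	translation regulator
Initiation factor	translation regulator
Elongation factor	translation regulator
Release factor	translation regulator
Ribosomal protein	translation regulator
Ribonucleoprotein	translation regulator
Vasoactive	vasoactive
Vasoconstrictor	vasoactive
Vasodilator	vasoactive
Natriuretic peptide	vasoactive
Endothelin	vasoactive
Storage protein	other
Structural protein	other
Toxin	other
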