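set	K	k
REACTOME_TRANSMEMBRANE_TRANSPORT_OF_SMALL_MOLECULES	413	9
GO_MOVEMENT_OF_CELL_OR_SUBCELLULAR_COMPONENT	1275	18
GO_PROTEIN_LOCALIZATION	1805	21
GO_REGULATION_OF_INTRACELLULAR_SIGNAL_TRANSDUCTION	1656	20
GO_LOCOMOTION	1114	16
GO_REGULATION_OF_MRNA_CATABOLIC_PROCESS	26	4
GO_ION_TRANSPORT	1262	17
GO_BIOLOGICAL_ADHESION	1032	15
GO_CATION_TRANSPORT	796	13
GO_MOTOR_ACTIVITY	131	6
GO_NEUROGENESIS	1402	17
GO_POSITIVE_REGULATION_OF_CATABOLIC_PROCESS	395	9
GO_SMALL_MOLECULE_METABOLIC_PROCESS	1767	19
GO_REGULATION_OF_CELL_ADHESION	629	11
GO_REGULATION_OF_NUCLEAR_TRANSCRIBED_MRNA_CATABOLIC_PROCESS_DEADENYLATION_DEPENDENT_DECAY	15	3
GO_SECONDARY_ACTIVE_TRANSMEMBRANE_TRANSPORTER_ACTIVITY	233	7
GO_POSITIVE_REGULATION_OF_MRNA_METABOLIC_PROCESS	45	4
GO_ENZYME_LINKED_RECEPTOR_PROTEIN_SIGNALING_PATHWAY	689	11
GO_HYDROLASE_ACTIVITY_ACTING_ON_ACID_ANHYDRIDES	820	12
GO_REGULATION_OF_IMMUNE_SYSTEM_PROCESS	1403	16
GO_INTRACELLULAR_SIGNAL_TRANSDUCTION	1572	17
GO_ACTIVE_TRANSMEMBRANE_TRANSPORTER_ACTIVITY	356	8
GO_CELL_MOTILITY	835	12
GO_METAL_ION_TRANSPORT	582	10
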