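panel	gene	subgroup	product
cobamide	cobG	aerobic_adenosylation	precorrin-3B synthase
cobamide	cobF	aerobic_adenosylation	precorrin-6A synthase
cobamide	cobA	aerobic_adenosylation	uroporphyrinogen-III C-methyltransferase
cobamide	cbiT	anaerobic_adenosylation	cobalt-precorrin-6B C15-methyltransferase
cobamide	cbiE	anaerobic_adenosylation	cobalt-precorrin-7 C5-methyltransferase
cobamide	cysG	tetrapyrrole_precursor	siroheme synthase
cobamide	cbiB	nucleotide_loop_assembly	adenosylcobinamide-phosphate synthase
cobamide	cobC	nucleotide_loop_assembly	alpha-ribazole-5-phosphate phosphatase
cobamide	cobD	aminopropanol_phosphate	threonine-phosphate decarboxylase
cobamide	cobQ	corrin_ring	adenosylcobyric acid synthase
cobamide	cobU	nucleotide_loop_assembly	adenosylcobinamide kinase
cobamide	cobS	nucleotide_loop_assembly	adenosylcobalamin-5'-phosphate synthase
cobamide	cobT	nucleotide_loop_assembly	nicotinate-nucleotide dimethylbenzimidazole phosphoribosyltransferase
cobamide	cbiK	corrin_ring	sirohydrochlorin cobaltochelatase
cobamide	bluB	lower_ligand	5,6-dimethylbenzimidazole synthase
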