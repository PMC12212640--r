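name	kind	description	endpoint_group
TUMOR_STAGE	categorical	AJCC pathological tumor stage	
TP53_Mutation_status	categorical	TP53 mutation present (1) or absent (0)	
KRAS_mutation_status	categorical	KRAS mutation present (1) or absent (0)	
Agent	categorical	treatment agents received, '|'-separated	
AGE	numeric	age at diagnosis, years	
SEX	categorical	sex	
PFS_months	event_time	progression-free survival, months	PFS
PFS_event	event_indicator	PFS event indicator (1 = progression/death)	PFS
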