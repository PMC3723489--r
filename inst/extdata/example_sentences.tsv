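doc_id	expected	text
14699432	POSITIVE	Our findings support the notion that CSF tau and Abeta(1-42) may be useful biomarkers in the early identification of AD in MCI subjects.
intro-1	POSITIVE	Early cognitive deficit characteristic of early Alzheimer's disease seems to be produced by the soluble forms of beta-Amyloid protein.
intro-2	POSITIVE	These findings suggest that there may be apolipoprotein E (apoE) isoform-specific differences of tau regulation in AD.
19221423	POSITIVE	These data suggested that GHE could be a potential agent for preventing or retarding the development or progression of Alzheimer's disease.
21681798	POSITIVE	These results suggest that some SAD may involve alternative processing of multiple gamma-secretase substrates, raising the possibility that the molecular pathogenesis of SAD might involve gamma-secretase dysfunction.
21673973	NEGATIVE	Taken together these data demonstrate that this transgenic AD model can serve as a powerful tool for the identification of AD therapeutic interventions.
21615354	NEGATIVE	Galantamine reduces behavioral symptoms in patients with mild to moderate AD, leading to reduced caregiver burden.
21982844	NEGATIVE	There is increasing evidence that the consumption of flavonoid-rich foods can beneficially influence normal cognitive function.
22433668	NEGATIVE	Whether T2D can cause late onset Alzheimer's disease (LOAD) remains to be elucidated.
21605039	NEGATIVE	Herein, we discuss the evidence supporting the critical role of tau oligomers in AD, the potential and challenges for targeting them by immunotherapy as a novel approach for AD treatment.
17012946	NEGATIVE	For some forms like vascular dementias, the possibility of prevention is the most valuable approach that should be enforced more aggressively.
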