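mesh_id	name	category
D000086382	COVID-19	disease
D003643	Death	disease
D011014	Pneumonia	disease
D007249	Inflammation	disease
D005334	Fever	disease
D009369	Neoplasms	disease
D012128	Respiratory Distress Syndrome	disease
D003371	Cough	disease
D003920	Diabetes Mellitus	disease
D006973	Hypertension	disease
D015047	Zoonoses	disease
D045169	Severe Acute Respiratory Syndrome	disease
D018352	Coronavirus Infections	disease
D007239	Infections	disease
D013577	Syndrome	disease
D014777	Virus Diseases	disease
D012140	Respiratory Tract Diseases	disease
D006333	Heart Failure	disease
D051436	Renal Insufficiency	disease
D013927	Thrombosis	disease
D010100	Oxygen	chemical
D006886	Hydroxychloroquine	chemical
C000606551	Remdesivir	chemical
D012694	Serine	chemical
D002738	Chloroquine	chemical
D008055	Lipids	chemical
D017963	Azithromycin	chemical
D009584	Nitrogen	chemical
D000450	Aldosterone	chemical
D014801	Vitamin D	chemical
D006854	Heparin	chemical
D003907	Dexamethasone	chemical
D007328	Insulin	chemical
D002118	Calcium	chemical
D008775	Interferons	chemical
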