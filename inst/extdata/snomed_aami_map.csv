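code,class,description
284470004,S,Premature atrial contraction
63593006,S,Supraventricular premature beats
427172004,V,Premature ventricular contractions
17338001,V,Ventricular premature beats
164884008,V,Ventricular ectopic beats
426761007,SVTA,Supraventricular tachycardia
49260003,IVR,Idioventricular rhythm
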