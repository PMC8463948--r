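text,criterion1,criterion2
"Normal sinus rhythm",0,0
"Sinus tachycardia",0,0
"*** ACUTE MI ***",1,1
"Possible anterior infarct, age undetermined",1,1
"ST elevation, consider acute injury",1,1
"Marked ST depression",0,1
"Nonspecific ST abnormality",0,1
"Nonspecific T wave abnormality",0,1
"Sinus bradycardia with nonspecific T wave abnormality",0,1
"Atrial fibrillation with rapid ventricular response",0,0
"Left ventricular hypertrophy",0,0
"acute mi suspected - inferior leads",1,1
"Old inferior infarct",1,1
"st elevation in V1-V4",1,1
"Low voltage QRS",0,0
"Right bundle branch block",0,0
"ST depression and T wave abnormality",0,1
"LVH with secondary ST abnormality",0,1
"Normal ECG",0,0
"Anterolateral infarct, probably old",1,1
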