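name,a,b,c,d,expected_status,note
counterexample-1,3,0,4,11,not_attainable,constructed: selected arm has zero nonevents at baseline (no legal move)
counterexample-2,9,1,10,90,not_attainable,constructed: one legal toggle leaves p far below alpha (path exhausted)
counterexample-3,9,35,8,8,not_attainable,constructed: 8 toggles all move p away from the boundary (path exhausted)
empirical-1-finearts-hf,910,1262,1028,1646,not_attainable,FINEARTS-HF adverse events by LVEF group (910/2172 vs 1028/2674)
empirical-2-ischemia,1594,638,282,58,not_attainable,ISCHEMIA angina-free at 48 months (1594/2232 vs 282/340)
fresco,188,90,109,29,not_attainable,FRESCO deaths (188/278 treatment vs 109/138 placebo)
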