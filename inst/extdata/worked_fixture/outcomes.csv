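video_id,surgeon_id,vascular_injury,cvs_score,parkland_grade
W01.F01,W01,FALSE,3,1
W01.F02,W01,FALSE,2,1
W02.F03,W02,TRUE,1,2
W02.F04,W02,TRUE,0,1
W03.F05,W03,FALSE,4,1
W03.F06,W03,FALSE,2,1
W04.F07,W04,FALSE,2,1
W04.F08,W04,FALSE,1,2
W05.F09,W05,FALSE,5,1
W05.F10,W05,FALSE,3,1
W06.F11,W06,TRUE,1,2
W06.F12,W06,FALSE,2,1
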