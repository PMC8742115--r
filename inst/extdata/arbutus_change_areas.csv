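scenario,period,class,C,E,total_C,total_E
LGM,past,0.03-0.1,28,242,70,2441
LGM,past,0.1-0.2,17,431,70,2441
LGM,past,0.2-0.4,16,517,70,2441
LGM,past,0.4-0.6,8,342,70,2441
LGM,past,>0.6,1,309,70,2441
MH,past,0.03-0.1,120,750,266,2243
MH,past,0.1-0.2,65,382,266,2243
MH,past,0.2-0.4,43,490,266,2243
MH,past,0.4-0.6,20,329,266,2243
MH,past,>0.6,18,292,266,2243
RCP45-2050,future,0.03-0.1,196,675,1154,1356
RCP45-2050,future,0.1-0.2,157,290,1154,1356
RCP45-2050,future,0.2-0.4,291,242,1154,1356
RCP45-2050,future,0.4-0.6,250,99,1154,1356
RCP45-2050,future,>0.6,260,50,1154,1356
RCP45-2070,future,0.03-0.1,206,664,1208,1303
RCP45-2070,future,0.1-0.2,171,277,1208,1303
RCP45-2070,future,0.2-0.4,305,228,1208,1303
RCP45-2070,future,0.4-0.6,259,91,1208,1303
RCP45-2070,future,>0.6,267,43,1208,1303
RCP85-2050,future,0.03-0.1,228,642,1295,1215
RCP85-2050,future,0.1-0.2,175,273,1295,1215
RCP85-2050,future,0.2-0.4,332,201,1295,1215
RCP85-2050,future,0.4-0.6,280,70,1295,1215
RCP85-2050,future,>0.6,280,29,1295,1215
RCP85-2070,future,0.03-0.1,264,606,1413,1097
RCP85-2070,future,0.1-0.2,202,246,1413,1097
RCP85-2070,future,0.2-0.4,365,168,1413,1097
RCP85-2070,future,0.4-0.6,296,53,1413,1097
RCP85-2070,future,>0.6,286,24,1413,1097
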