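lane,replicate,conc,conc_unit,band_0,band_1
1,1,0,uM,1026.37117840153,0
2,1,0.00121,uM,938.066094751336,9.34435174443665
3,1,0.00279525693710062,uM,984.248772927158,23.4753327642665
4,1,0.00645740606975963,uM,945.32250706363,47.7027787496828
5,1,0.014917445547249,uM,861.061698022906,111.449845197637
6,1,0.0344612340080732,uM,686.320672702379,212.62094740731
7,1,0.0796099201835657,uM,581.392540520749,425.999733549703
8,1,0.183909241037305,uM,377.105711299203,625.013221308444
9,1,0.424854199840031,uM,222.933080686742,762.821864567083
10,1,0.981468305255521,uM,107.184260766207,926.548370490461
11,1,2.26731908166106,uM,49.6396547377874,969.798005067126
12,1,5.2378011501105,uM,21.7699068763906,921.886250943338
13,1,12.1,uM,9.79197264511287,979.943522708159
14,2,0,uM,988.772675934959,0
15,2,0.00121,uM,871.713553127,10.1259824504699
16,2,0.00279525693710062,uM,1045.51707677165,21.8633110806148
17,2,0.00645740606975963,uM,979.051252576309,50.0803945780758
18,2,0.014917445547249,uM,899.983435453431,103.174379871389
19,2,0.0344612340080732,uM,747.633946237795,211.271947185356
20,2,0.0796099201835657,uM,624.324856704172,399.506276791943
21,2,0.183909241037305,uM,390.371192424198,573.771286629116
22,2,0.424854199840031,uM,219.853153392857,772.842973190256
23,2,0.981468305255521,uM,102.374486035472,897.7257638279
24,2,2.26731908166106,uM,54.5158768867294,939.947624600624
25,2,5.2378011501105,uM,22.6341675244211,963.291839145219
26,2,12.1,uM,10.8921130493241,907.85538329395
27,3,0,uM,1090.40286226197,0
28,3,0.00121,uM,992.981705083668,9.04885552198742
29,3,0.00279525693710062,uM,1009.47248917748,23.9193393701272
30,3,0.00645740606975963,uM,1034.88442744546,48.1843734363862
31,3,0.014917445547249,uM,867.0093797201,110.57007335205
32,3,0.0344612340080732,uM,784.831483709634,227.504211837527
33,3,0.0796099201835657,uM,595.527352050375,396.947280574915
34,3,0.183909241037305,uM,403.497697185951,645.183349664439
35,3,0.424854199840031,uM,223.702167640912,746.053827300009
36,3,0.981468305255521,uM,116.334382627534,910.20335543213
37,3,2.26731908166106,uM,52.1891898654903,904.069386495136
38,3,5.2378011501105,uM,21.5949885261829,1086.96135459563
39,3,12.1,uM,10.1909230563265,1024.73558880906
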