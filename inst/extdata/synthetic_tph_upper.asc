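ncols 12
nrows 12
xllcorner 500000
yllcorner 4199640
cellsize 30
NODATA_value -9999
140.034155154722498 83.049483786910358 66.839022463024961 71.858792893745658 87.405421869479710 75.197762803522735 0.000000000000000 0.000000000000000 0.000000000000000 0.000000000000000 0.000000000000000 205.304094299823475
188.565680562619320 112.686746353415586 90.311821450662279 98.095129977315125 119.733356976904346 100.347581064761584 0.000000000000000 0.000000000000000 0.000000000000000 0.000000000000000 0.000000000000000 267.934958467356410
246.13805279090175 150.51478061664525 117.55502354681845 125.43207446305770 145.74501344472554 110.59667656103993 0.00000000000000 0.00000000000000 0.00000000000000 0.00000000000000 0.00000000000000 336.20446681205561
250.82061909125187 156.28340058268853 119.68680696645572 126.11094814671338 145.41881129339563 107.95545761923138 0.00000000000000 0.00000000000000 0.00000000000000 0.00000000000000 0.00000000000000 329.36141126558039
194.372377265012659 127.141015766071078 94.056951550546700 94.192148193212745 101.752506096893654 72.003951234637825 75.702838180910618 0.000000000000000 0.000000000000000 0.000000000000000 0.000000000000000 246.505676010846400
174.375220802122186 118.931616406340510 87.840566512462203 86.417305258734046 91.355494975038738 66.448469367940390 69.357827843728728 0.000000000000000 0.000000000000000 0.000000000000000 0.000000000000000 218.365027408220527
146.562584947037607 102.117503527875428 75.401073196659297 73.323147359606878 80.389014601053461 69.966464700738214 73.723310986127416 0.000000000000000 0.000000000000000 0.000000000000000 169.438357218519911 194.772375614624764
138.144852458779951 93.843547898004331 69.236823696182171 67.418218859721890 74.988583824365193 67.774456029498040 71.177209309126170 0.000000000000000 0.000000000000000 0.000000000000000 169.352450427047756 191.506234547080112
177.841518509565873 123.411894890175958 93.367225110485180 90.811722889127722 95.258460425680141 76.989425252265633 79.057163988366682 102.829362603214960 0.000000000000000 0.000000000000000 217.811260110150528 246.787992227029065
238.42913897002776 156.27748155065461 121.97052601816094 122.60945604428970 133.22354594187172 101.95010592492454 102.87188114406163 139.12317561276112 0.00000000000000 290.19458588823852 307.41780902237451 343.63883455736573
146.657484445438826 97.361123368820131 76.944954671352264 78.495231079328022 83.611192516761051 62.496811076599286 61.210061372921167 81.126366332616840 0.000000000000000 0.000000000000000 182.619505263909076 208.636775078404838
143.023579928732744 87.244341169067269 69.764235480344297 73.303793483086054 84.892888128288178 67.823498943887742 65.701212755548013 0.000000000000000 0.000000000000000 0.000000000000000 0.000000000000000 208.668741545000927
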