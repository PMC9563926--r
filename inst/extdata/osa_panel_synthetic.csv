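mz,formula,name,prior_direction,source,detectable
53.3587,,,,synthetic,TRUE
55.4958,,,,synthetic,FALSE
56.8394,,,,synthetic,TRUE
58.4996,,,,synthetic,FALSE
59.2189,,,,synthetic,TRUE
61.6614,,,,synthetic,FALSE
64.583,,,,synthetic,TRUE
64.8967,,,,synthetic,FALSE
67.692,,,,synthetic,TRUE
68.3166,,,,synthetic,FALSE
70.8203,,,,synthetic,TRUE
73.8812,,,,synthetic,FALSE
75.1132,,,,synthetic,TRUE
76.7473,,,,synthetic,FALSE
77.1987,,,,synthetic,TRUE
77.689,,,,synthetic,FALSE
81.0328,C5H5O,,increased,reported,TRUE
93.6874,,,,synthetic,FALSE
93.7872,,,,synthetic,TRUE
94.286,,,,synthetic,FALSE
95.0494,C6H7O,,increased,reported,TRUE
101.0598,C5H9O2,,increased,reported,TRUE
101.6572,,,,synthetic,TRUE
101.6856,,,,synthetic,FALSE
101.912,,,,synthetic,TRUE
104.2819,,,,synthetic,FALSE
106.6682,,,,synthetic,TRUE
108.0931,,,,synthetic,FALSE
109.1265,,,,synthetic,TRUE
109.9268,,,,synthetic,FALSE
112.4355,,,,synthetic,TRUE
114.1382,,,,synthetic,FALSE
115.2415,,,,synthetic,TRUE
118.7868,,,,synthetic,FALSE
118.8563,,,,synthetic,TRUE
123.5499,,,,synthetic,FALSE
125.0958,C8H13O,2-butylfuran,increased,reported,TRUE
125.5073,,,,synthetic,FALSE
127.6063,,,,synthetic,TRUE
128.0701,C6H10NO2,,increased,reported,TRUE
130.8366,,,,synthetic,FALSE
142.6836,,,,synthetic,TRUE
146.9596,,,,synthetic,FALSE
152.0699,C8H10NO2,,increased,reported,TRUE
152.9156,,,,synthetic,TRUE
153.3842,,,,synthetic,FALSE
154.5261,,,,synthetic,TRUE
155.0416,,,,synthetic,FALSE
155.5478,,,,synthetic,TRUE
157.0981,,,,synthetic,FALSE
157.1512,,,,synthetic,TRUE
160.6101,,,,synthetic,FALSE
161.4301,,,,synthetic,TRUE
165.0145,,,,synthetic,FALSE
168.5227,,,,synthetic,TRUE
169.0867,C9H13O3,,increased,reported,TRUE
169.1739,,,,synthetic,FALSE
169.9199,,,,synthetic,FALSE
173.2577,,,,synthetic,TRUE
175.1117,C12H15O,,increased,reported,TRUE
176.0547,,,,synthetic,FALSE
176.7807,,,,synthetic,TRUE
179.0746,,,,synthetic,FALSE
179.6106,,,,synthetic,TRUE
182.2919,,,,synthetic,FALSE
183.9589,,,,synthetic,TRUE
184.3453,,,,synthetic,FALSE
190.8481,,,,synthetic,TRUE
191.1184,,,,synthetic,FALSE
193.049,,,,synthetic,TRUE
194.2806,,,,synthetic,FALSE
194.9607,,,,synthetic,TRUE
195.1379,C12H19O2,4-(hexyloxy)phenol,increased,reported,TRUE
196.2678,,,,synthetic,FALSE
197.0112,,,,synthetic,TRUE
200.5119,,,,synthetic,FALSE
203.6888,,,,synthetic,FALSE
207.869,,,,synthetic,TRUE
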