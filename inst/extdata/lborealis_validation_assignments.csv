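lon,lat,pc_value,probability,range_percent,footnote
-86.10,37.19,20.43,0.52,0.41,
-77.04,38.91,34.10,0.94,0.76,
-82.60,38.41,97.99,0.00,0.01,b
-96.18,36.10,52.52,1.00,0.21,
-84.23,30.91,38.45,0.99,0.72,
-76.87,38.78,28.79,0.80,0.71,
-82.60,34.92,23.99,0.34,0.71,a
-97.04,32.90,15.29,0.74,0.22,
-77.14,38.97,26.38,0.51,0.65,
-95.23,38.97,42.70,0.95,0.59,
-99.11,29.89,50.33,0.95,0.29,
-84.44,33.71,92.99,0.00,0.03,b
-75.48,41.39,17.40,0.32,0.44,a
-96.76,46.88,31.58,1.00,0.75,
-90.56,42.59,41.69,0.01,0.62,b
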