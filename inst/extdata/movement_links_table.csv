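from_node,to_node,euclid_km,lcp_km,ratio,effective_resistance,centrality_score,centrality_class,outside_forest_km
1,2,131.41,179.91,0.73,13.08,6.71,least,57.66
1,3,66.31,113.88,0.58,12.07,8.60,least,79.72
1,4,223.90,272.80,0.82,22.42,5.22,least,112.19
1,7,158.72,193.24,0.82,12.99,6.55,least,77.17
1,8,65.12,77.13,0.84,8.91,14.50,moderate,11.08
1,9,60.48,107.27,0.56,14.15,9.87,moderate,43.62
1,19,11.78,13.55,0.87,2.98,18.00,high,12.97
2,3,42.53,47.80,0.89,8.68,10.14,moderate,33.94
2,4,51.38,91.40,0.56,11.20,6.60,least,51.40
2,5,81.28,110.56,0.74,16.50,5.33,least,78.76
2,7,34.14,42.31,0.81,4.31,13.82,moderate,25.96
2,8,91.50,110.94,0.82,8.97,6.19,least,49.89
2,9,165.66,220.99,0.75,14.82,4.95,least,98.86
2,18,184.02,231.19,0.80,18.85,5.54,least,78.15
3,4,137.18,182.17,0.75,19.08,4.56,least,105.85
3,5,159.36,186.72,0.85,23.06,4.48,least,116.65
3,7,98.84,110.82,0.89,10.26,6.72,least,71.86
3,8,94.27,105.06,0.90,10.06,7.47,least,86.06
3,18,169.40,288.75,0.59,21.19,5.06,least,125.41
4,5,7.77,25.06,0.31,12.88,12.06,moderate,22.82
4,7,42.95,50.72,0.85,11.27,9.61,moderate,29.75
5,7,36.81,51.94,0.71,14.45,5.94,least,39.50
5,9,218.68,246.28,0.89,25.96,3.49,least,102.29
5,10,101.01,118.56,0.85,17.78,6.88,least,82.87
5,11,90.70,128.34,0.71,19.89,7.91,least,97.12
5,12,134.21,234.51,0.57,34.18,7.06,least,137.78
5,18,227.87,256.48,0.89,29.37,3.61,least,81.58
6,10,108.65,120.50,0.90,10.66,11.76,moderate,47.12
6,11,119.95,159.36,0.75,10.56,5.68,least,55.77
6,15,49.83,56.71,0.88,6.07,16.19,moderate,36.21
6,16,52.77,78.35,0.67,11.69,9.49,moderate,41.35
7,8,60.66,72.10,0.84,8.02,8.15,least,20.46
7,9,134.23,164.45,0.82,13.35,5.23,least,67.73
7,10,46.17,54.38,0.85,5.22,22.21,high,23.50
7,12,185.99,221.25,0.84,24.82,8.94,moderate,112.86
7,18,146.42,174.65,0.84,16.92,5.95,least,47.02
8,9,32.11,39.46,0.81,10.03,8.28,least,28.48
8,10,46.73,60.57,0.77,7.38,14.41,moderate,29.93
8,12,271.95,310.84,0.87,28.61,7.40,least,157.36
9,10,59.51,65.76,0.90,10.05,16.65,moderate,34.93
9,18,13.81,19.01,0.73,10.35,16.48,moderate,12.92
10,11,35.04,45.38,0.77,4.88,26.57,high,12.76
10,15,84.06,107.58,0.78,7.54,14.15,moderate,41.34
10,16,49.20,72.48,0.68,6.43,11.84,moderate,30.78
10,18,61.02,75.96,0.80,12.58,11.69,moderate,14.00
11,12,128.15,174.39,0.73,20.03,7.43,least,85.90
11,14,106.17,113.68,0.93,10.22,17.45,moderate,54.62
11,15,59.80,74.83,0.80,6.16,10.97,moderate,38.76
11,16,101.12,124.46,0.81,9.74,8.02,least,49.76
12,13,25.30,120.09,0.21,82.30,11.02,moderate,59.33
12,14,55.40,92.31,0.60,19.77,10.66,moderate,34.66
12,15,122.51,164.03,0.75,19.38,6.82,least,72.21
13,14,89.69,156.86,0.57,65.47,15.89,moderate,52.96
13,17,125.73,210.24,0.60,114.84,9.50,moderate,105.44
14,15,55.03,65.27,0.84,5.72,26.04,high,33.78
14,17,124.01,150.52,0.82,67.26,12.64,moderate,102.29
15,16,81.05,117.65,0.69,10.01,9.87,moderate,63.97
16,18,33.62,46.26,0.73,14.31,15.93,moderate,35.45
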