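node_id,name,centrality_score,centrality_rank,area_km2
1,Similipal,43.72,moderate,"2,750.00"
2,Jada,38.64,moderate,905.54
3,Siddhamath,32.51,least,341.46
4,Garjanpahar,28.02,least,431.88
5,Debrigarh,37.38,least,423.69
6,Lakhari valley,30.56,least,196.27
7,Khalasuni,55.56,moderate,696.55
8,Anantapur,42.2,least,234.45
9,Kapilash,41.48,least,317.87
10,Satkosia,77.07,high,"1,440.2"
11,Subarnagir,51.01,moderate,474.2
12,Sunabeda,38.67,moderate,"1,256.45"
13,Hattigam,27.21,least,115.47
14,Karlapat,50.35,moderate,171.58
15,Kothagarh,51.02,moderate,699.53
16,Barabara,36.57,least,868.53
17,Dharamagarh,20.07,least,541.99
18,Chandaka,41.12,moderate,182.68
19,Kuldiha,18,least,232.83
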