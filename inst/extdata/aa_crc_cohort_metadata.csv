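sample_id,specimen,age,sex,stage,location,differentiation,msi,n_aberrations
268,07-2378,94,F,1,R,Moderately,S,30
283,07-5430,54,M,1,R,well diff,S,35
308,09-1574,48,M,2,L,Moderately,S,10
270,07-3920,51,M,2,L,Moderately,S,99
269,07-3698,53,M,2,L,Moderately,S,65
267,07-1361,66,M,2,R,Moderately,H,63
272,07-4027,65,F,3,L,Moderately,S,30
277,07-5330,72,F,3,R,Moderately,S,31
275,07-4855,87,F,3,R,Moderately,S,26
285,08-2842,52,F,4,R,Moderately,S,13
287,08-3072,73,M,4,R,Moderately,S,8
2,05-3518,65,M,1,R,Moderately,S,2
1,05-3429,65,F,2,L,Moderately,S,13
5,05-4671,71,M,2,L,Moderately,S,29
14,06-4708,65,M,3,L,well diff,S,27
282,08-2321,55,F,3,R,Poorly,S,36
7,05-5288,73,F,3,R,Moderately,S,8
273,07-4527,71,M,3,R,Moderately,S,37
13,06-4383,53,M,3,R,Moderately,S,5
8,05-5581,61,M,3,R,Moderately,S,10
4,05-4211,57,M,3,R,Moderately,S,5
12,06-2689,53,F,4,R,Moderately,S,88
11,06-0477,51,F,2,L,Moderately,L,33
10,05-5770,69,F,2,L,Moderately,L,13
307,09-1637,53,F,3,R,Moderately,L,10
279,07-5443,60,M,3,R,Moderately,L,6
9,05-5659,54,F,2,R,Moderately,H,4
6,05-5026,83,F,3,R,Moderately,H,14
3,05-4203,68,F,3,R,Moderately,H,9
15,06-5215,64,M,3,R,Moderately,H,5
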