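version,level,ec_per_block,n_blocks
1,L,7,1
1,M,10,1
1,Q,13,1
1,H,17,1
2,L,10,1
2,M,16,1
2,Q,22,1
2,H,28,1
3,L,15,1
3,M,26,1
3,Q,18,2
3,H,22,2
4,L,20,1
4,M,18,2
4,Q,26,2
4,H,16,4
5,L,26,1
5,M,24,2
5,Q,18,4
5,H,22,4
6,L,18,2
6,M,16,4
6,Q,24,4
6,H,28,4
7,L,20,2
7,M,18,4
7,Q,18,6
7,H,26,5
8,L,24,2
8,M,22,4
8,Q,22,6
8,H,26,6
9,L,30,2
9,M,22,5
9,Q,20,8
9,H,24,8
10,L,18,4
10,M,26,5
10,Q,24,8
10,H,28,8
11,L,20,4
11,M,30,5
11,Q,28,8
11,H,24,11
12,L,24,4
12,M,22,8
12,Q,26,10
12,H,28,11
13,L,26,4
13,M,22,9
13,Q,24,12
13,H,22,16
14,L,30,4
14,M,24,9
14,Q,20,16
14,H,24,16
15,L,22,6
15,M,24,10
15,Q,30,12
15,H,24,18
16,L,24,6
16,M,28,10
16,Q,24,17
16,H,30,16
17,L,28,6
17,M,28,11
17,Q,28,16
17,H,28,19
18,L,30,6
18,M,26,13
18,Q,28,18
18,H,28,21
19,L,28,7
19,M,26,14
19,Q,26,21
19,H,26,25
20,L,28,8
20,M,26,16
20,Q,30,20
20,H,28,25
21,L,28,8
21,M,26,17
21,Q,28,23
21,H,30,25
22,L,28,9
22,M,28,17
22,Q,30,23
22,H,24,34
23,L,30,9
23,M,28,18
23,Q,30,25
23,H,30,30
24,L,30,10
24,M,28,20
24,Q,30,27
24,H,30,32
25,L,26,12
25,M,28,21
25,Q,30,29
25,H,30,35
26,L,28,12
26,M,28,23
26,Q,28,34
26,H,30,37
27,L,30,12
27,M,28,25
27,Q,30,34
27,H,30,40
28,L,30,13
28,M,28,26
28,Q,30,35
28,H,30,42
29,L,30,14
29,M,28,28
29,Q,30,38
29,H,30,45
30,L,30,15
30,M,28,29
30,Q,30,40
30,H,30,48
31,L,30,16
31,M,28,31
31,Q,30,43
31,H,30,51
32,L,30,17
32,M,28,33
32,Q,30,45
32,H,30,54
33,L,30,18
33,M,28,35
33,Q,30,48
33,H,30,57
34,L,30,19
34,M,28,37
34,Q,30,51
34,H,30,60
35,L,30,19
35,M,28,38
35,Q,30,53
35,H,30,63
36,L,30,20
36,M,28,40
36,Q,30,56
36,H,30,66
37,L,30,21
37,M,28,43
37,Q,30,59
37,H,30,70
38,L,30,22
38,M,28,45
38,Q,30,62
38,H,30,74
39,L,30,24
39,M,28,47
39,Q,30,65
39,H,30,77
40,L,30,25
40,M,28,49
40,Q,30,68
40,H,30,81
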