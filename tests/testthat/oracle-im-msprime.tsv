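S	pi_sum
26	5.247368
29	6.994737
21	5.742105
23	7.457895
39	9.805263
29	5.489474
21	5.331579
26	6.536842
26	6.084211
20	3.373684
21	4.794737
45	15.068421
38	8.436842
20	5.363158
42	10.000000
22	5.626316
33	12.394737
20	5.247368
47	10.031579
33	6.126316
26	5.657895
13	3.042105
35	8.910526
23	4.247368
19	3.978947
15	5.173684
34	10.705263
32	8.073684
19	3.552632
34	5.647368
31	7.031579
41	11.973684
31	7.768421
31	9.884211
33	9.326316
38	12.815789
23	4.963158
27	8.968421
31	8.110526
29	7.231579
30	7.689474
27	5.663158
28	5.936842
25	6.531579
16	4.173684
36	7.342105
21	5.784211
22	5.094737
39	9.194737
40	12.068421
23	7.894737
30	7.810526
36	11.394737
24	7.621053
20	6.015789
19	4.036842
40	12.289474
21	4.689474
20	4.084211
18	3.815789
39	9.226316
31	10.500000
31	8.868421
21	6.142105
50	16.415789
28	6.263158
18	5.584211
52	22.615789
30	6.821053
32	10.205263
26	5.847368
14	4.826316
32	9.994737
17	4.115789
31	7.931579
17	3.284211
19	4.694737
17	4.442105
16	4.521053
16	3.100000
22	6.147368
40	13.284211
28	6.915789
40	12.194737
23	4.984211
31	8.384211
34	8.431579
19	5.684211
29	8.152632
26	6.836842
26	5.468421
37	7.542105
50	14.678947
20	4.278947
20	5.294737
19	4.315789
11	2.805263
22	5.884211
29	8.378947
17	3.868421
45	12.305263
30	8.973684
25	3.163158
14	2.900000
31	9.236842
29	7.531579
25	6.894737
26	7.873684
39	9.357895
18	4.357895
29	6.784211
29	8.021053
47	16.036842
25	7.626316
23	5.900000
31	6.868421
16	4.168421
22	4.263158
35	13.936842
41	12.168421
30	7.310526
33	9.342105
14	4.036842
29	6.905263
22	4.736842
35	10.889474
32	9.531579
43	11.552632
35	9.815789
17	3.473684
28	4.857895
19	4.494737
24	6.426316
26	6.478947
27	7.100000
22	6.736842
32	8.794737
17	3.900000
24	5.484211
31	8.489474
31	7.221053
23	6.600000
22	6.305263
36	8.415789
40	8.736842
23	6.015789
30	7.200000
37	11.363158
37	11.694737
44	7.047368
19	4.073684
32	7.952632
29	4.552632
30	10.031579
22	5.157895
21	5.184211
15	4.594737
40	6.878947
32	7.952632
22	3.726316
36	11.657895
25	5.426316
25	6.515789
47	14.910526
27	5.957895
45	15.405263
26	8.131579
40	9.284211
24	5.357895
18	4.778947
25	8.089474
17	2.857895
42	15.510526
22	5.689474
36	10.642105
40	17.105263
46	12.815789
33	8.500000
34	9.868421
16	3.426316
26	7.578947
28	5.784211
38	8.636842
26	7.794737
22	5.547368
46	8.457895
32	6.052632
27	6.194737
28	8.431579
22	4.636842
30	8.857895
24	4.321053
37	7.542105
30	9.226316
27	5.578947
40	10.647368
15	3.326316
29	7.526316
52	11.542105
40	11.621053
26	9.531579
28	5.305263
32	5.757895
31	6.052632
25	4.363158
18	4.163158
26	7.800000
13	2.878947
34	11.531579
20	3.115789
49	10.100000
20	5.131579
30	9.105263
23	7.115789
24	7.400000
29	6.847368
21	4.157895
26	8.005263
28	6.542105
23	5.868421
33	9.205263
27	5.894737
20	4.068421
28	7.326316
29	7.626316
38	11.184211
32	6.557895
34	8.926316
28	7.705263
17	4.342105
43	13.510526
35	13.521053
27	7.800000
14	4.342105
35	6.663158
17	3.668421
26	7.684211
22	5.663158
18	3.073684
25	7.026316
26	7.521053
34	5.500000
17	3.731579
21	4.336842
30	6.552632
33	10.152632
24	6.626316
24	4.189474
21	4.389474
39	10.021053
29	8.173684
45	14.168421
19	4.605263
24	5.257895
36	9.442105
34	7.731579
29	6.078947
40	9.242105
22	5.989474
35	9.036842
26	4.273684
34	8.489474
37	10.415789
21	5.494737
25	7.721053
27	7.373684
26	6.889474
30	8.684211
47	17.610526
16	3.515789
36	10.847368
25	7.036842
37	8.505263
29	9.073684
32	10.389474
28	8.942105
31	8.436842
28	8.152632
58	20.073684
19	5.131579
17	5.000000
32	11.905263
19	6.378947
33	4.800000
41	12.284211
14	3.278947
20	6.221053
28	5.736842
32	9.636842
20	4.457895
30	9.252632
33	8.247368
23	3.947368
17	3.568421
26	5.963158
37	10.752632
23	7.315789
43	12.447368
30	7.494737
24	3.468421
29	7.194737
33	10.268421
17	3.442105
20	4.078947
47	18.605263
25	7.063158
34	11.736842
25	7.421053
22	4.542105
29	7.152632
21	3.763158
27	6.052632
18	3.673684
22	8.042105
18	4.715789
35	10.194737
25	5.331579
25	6.547368
17	4.315789
25	5.763158
26	5.531579
49	15.057895
37	8.310526
27	7.394737
28	6.478947
16	3.963158
32	7.126316
20	5.126316
22	5.531579
34	7.278947
20	4.689474
28	9.963158
31	7.578947
33	6.094737
33	8.547368
39	12.936842
27	8.373684
28	6.642105
20	5.705263
38	14.621053
33	5.631579
23	5.163158
20	6.105263
26	4.857895
24	6.321053
23	4.215789
23	6.663158
31	8.626316
23	5.900000
30	7.094737
24	5.884211
32	7.894737
25	3.721053
18	3.221053
28	7.015789
39	10.157895
33	8.768421
24	7.815789
31	8.821053
33	9.552632
24	7.247368
21	4.484211
28	6.873684
34	7.784211
25	6.852632
18	6.031579
28	8.615789
31	10.600000
28	4.784211
15	3.978947
30	8.836842
38	9.378947
21	4.936842
21	5.684211
39	11.263158
21	4.878947
22	5.363158
39	9.131579
21	5.852632
25	5.842105
30	6.000000
42	13.468421
24	7.315789
26	8.421053
24	6.484211
31	7.442105
33	9.531579
32	10.015789
40	13.247368
30	10.431579
40	11.736842
34	8.342105
48	13.247368
34	10.500000
27	4.752632
33	6.510526
18	5.463158
31	7.089474
18	4.442105
28	9.610526
27	7.436842
37	10.684211
23	5.200000
24	6.742105
17	4.357895
33	8.331579
15	4.847368
20	6.694737
28	8.221053
19	3.542105
22	4.405263
28	4.736842
33	11.131579
20	5.668421
20	5.110526
33	11.268421
42	15.463158
44	12.726316
22	2.894737
35	8.563158
32	7.210526
20	5.257895
28	7.705263
31	6.336842
20	2.900000
24	4.010526
36	10.578947
29	4.642105
24	7.989474
26	8.605263
30	8.205263
10	2.152632
31	8.605263
18	4.126316
25	6.094737
29	7.173684
33	7.015789
36	11.636842
32	9.515789
25	6.715789
27	7.147368
23	6.494737
23	5.247368
22	4.184211
30	7.100000
44	10.642105
34	7.684211
40	15.326316
37	7.042105
27	7.884211
12	3.700000
26	6.173684
42	10.689474
33	7.378947
28	9.294737
14	3.036842
24	6.500000
28	6.642105
20	4.568421
29	6.878947
26	6.989474
15	3.426316
38	10.236842
15	3.010526
24	5.568421
43	12.305263
24	6.526316
32	6.173684
33	8.184211
31	10.226316
23	6.563158
27	6.789474
30	8.773684
15	3.494737
32	7.089474
19	4.126316
15	4.468421
17	4.084211
24	6.778947
24	8.110526
20	4.073684
33	8.121053
19	3.684211
21	4.442105
8	1.784211
18	3.752632
30	6.873684
22	5.221053
22	4.652632
29	7.242105
17	4.642105
31	8.142105
31	10.584211
23	5.305263
25	6.100000
23	4.773684
25	6.978947
20	5.394737
28	6.968421
33	9.394737
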